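# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed; keeps every derived
# seed a valid 32-bit integer.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spatial dims of a 3-D or 4-D array.
spatial_dim <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stopf("expected a 3-D or 4-D array")
  }
  d[1:3]
}

# View a 4-D (x,y,z,t) array as a voxels-by-time matrix without copying the
# layout (t is the slowest-varying dimension, so this is a pure reshape).
as_voxel_matrix <- function(data4d) {
  d <- dim(data4d)
  matrix(data4d, nrow = prod(d[1:3]), ncol = d[4])
}

# Inverse of as_voxel_matrix().
as_volume_series <- function(mat, sdim) {
  array(mat, dim = c(sdim, ncol(mat)))
}
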