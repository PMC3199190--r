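#' Specification of a synthetic fMRI dataset
#'
#' Describes a simulated acquisition: grid shape, volume count, TR,
#' autoregressive noise structure, polynomial scanner drift and
#' HRF-convolved block activation. Defaults mirror a typical 1.5 T
#' acquisition (64x64x22 voxels of 3.75 mm, 80 volumes at TR 2 s); tests and
#' examples use reduced shapes.
#'
#' @param shape Integer length-3 grid size `(nx, ny, nz)`.
#' @param nt Number of volumes.
#' @param tr Repetition time in seconds.
#' @param voxel_size Voxel size in mm (scalar or length 3).
#' @param ar_coeffs AR noise coefficients: a numeric vector `a_1..a_p` used
#'   for every voxel, or an array of shape `c(shape, p)` for spatially
#'   varying coefficients. Must be stationary everywhere.
#' @param trend_coeffs Polynomial drift coefficients for degrees 0..3,
#'   evaluated on normalized time in `[-1, 1]`.
#' @param activation_amplitude Activation strength as a multiple of
#'   `noise_sd` (>= 0; 0 gives pure-null data).
#' @param active_region Logical 3-D array (or voxel index vector) marking the
#'   truly active voxels; must lie inside `mask`.
#' @param noise_sd Standard deviation of the AR innovations (> 0).
#' @param mask Optional logical 3-D brain mask (default all-true).
#' @param rician If `TRUE`, magnitude (Rician) noise is emulated by taking
#'   the modulus of the signal plus complex Gaussian noise. Off by default:
#'   the pipeline itself never assumes Rician noise.
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   datasets.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(64, 64, 22), nt = 80, tr = 2,
                           voxel_size = c(3.75, 3.75, 3.75),
                           ar_coeffs = c(0.3, 0.1, 0.05, 0.02),
                           trend_coeffs = c(0, 0, 0, 0),
                           activation_amplitude = 0,
                           active_region = NULL,
                           noise_sd = 1,
                           mask = NULL,
                           rician = FALSE,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("`shape` must be 3 positive integers")
  if (nt < 2L) stopf("`nt` must be at least 2")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stopf("`noise_sd` must be positive")
  if (activation_amplitude < 0) stopf("`activation_amplitude` must be >= 0")
  if (length(trend_coeffs) > 4L) stopf("drift polynomial is at most cubic")
  trend_coeffs <- c(trend_coeffs, numeric(4L - length(trend_coeffs)))
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  if (is.null(active_region)) {
    active_region <- array(FALSE, dim = shape)
  } else if (!is.array(active_region)) {
    idx <- as.integer(active_region)
    active_region <- array(FALSE, dim = shape)
    active_region[idx] <- TRUE
  }
  if (!identical(dim(active_region), dim(mask))) {
    stopf("`active_region` shape must match `shape`")
  }
  if (any(active_region & !mask)) stopf("`active_region` must lie inside `mask`")
  # stationarity of every voxel's AR polynomial
  if (is.array(ar_coeffs) && length(dim(ar_coeffs)) == 4L) {
    p <- dim(ar_coeffs)[4]
    cmat <- matrix(ar_coeffs, ncol = p)
    bad <- !apply(cmat, 1L, ar_is_stationary)
    if (any(bad)) stopf("%d voxel(s) have non-stationary AR coefficients", sum(bad))
  } else {
    ar_coeffs <- as.numeric(ar_coeffs)
    if (!ar_is_stationary(ar_coeffs)) stopf("`ar_coeffs` are not stationary")
  }
  structure(
    list(shape = shape, nt = as.integer(nt), tr = tr,
         voxel_size = voxel_size, ar_coeffs = ar_coeffs,
         trend_coeffs = trend_coeffs,
         activation_amplitude = activation_amplitude,
         active_region = active_region, noise_sd = noise_sd,
         mask = mask, rician = isTRUE(rician), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# TRUE iff the AR(p) process y_t = sum a_k y_{t-k} + e_t is stationary:
# all roots of z^p - a_1 z^(p-1) - ... - a_p lie strictly inside the unit
# circle.
ar_is_stationary <- function(coeffs, limit = 1) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) == 0L || all(coeffs == 0)) return(TRUE)
  if (any(!is.finite(coeffs))) return(FALSE)
  roots <- polyroot(c(rev(-coeffs), 1))
  all(Mod(roots) < limit)
}

#' Generate a synthetic fMRI dataset with known truth
#'
#' Each voxel series is a polynomial drift plus (inside the active region)
#' an HRF-convolved block activation of amplitude
#' `activation_amplitude * noise_sd`, plus AR(p)-filtered Gaussian noise with
#' innovation standard deviation `noise_sd`. The AR recursion is started
#' from a 100-sample burn-in so the noise is stationary from the first
#' volume.
#'
#' @param spec A [synthetic_spec()].
#' @param paradigm A `paradigm`; required when `activation_amplitude > 0`.
#' @return A list with `dataset` (an [fmri_dataset()]) and `truth` (3-D
#'   logical array marking the active region).
#' @export
generate_synthetic <- function(spec, paradigm = NULL) {
  if (!inherits(spec, "synthetic_spec")) stopf("`spec` must be a synthetic_spec")
  sdim <- spec$shape
  nt <- spec$nt
  nv <- prod(sdim)
  burn <- 100L

  # per-voxel coefficient matrix (nv x p)
  if (is.array(spec$ar_coeffs) && length(dim(spec$ar_coeffs)) == 4L) {
    cmat <- matrix(spec$ar_coeffs, nrow = nv)
  } else {
    p <- length(spec$ar_coeffs)
    cmat <- matrix(spec$ar_coeffs, nrow = nv, ncol = max(p, 1L), byrow = TRUE)
    if (p == 0L) cmat <- matrix(0, nrow = nv, ncol = 1L)
  }
  p <- ncol(cmat)

  noise <- with_seed(spec$seed, {
    innov <- matrix(stats::rnorm(nv * (nt + burn), sd = spec$noise_sd),
                    nrow = nv)
    y <- ar_simulate(innov, cmat)
    y <- y[, (burn + 1L):(burn + nt), drop = FALSE]
    if (spec$rician) {
      imag <- matrix(stats::rnorm(nv * nt, sd = spec$noise_sd), nrow = nv)
      list(real = y, imag = imag)
    } else {
      list(real = y, imag = NULL)
    }
  })

  tn <- seq(-1, 1, length.out = nt)
  trend <- drop(outer(tn, 0:3, `^`) %*% spec$trend_coeffs)
  signal <- matrix(trend, nrow = nv, ncol = nt, byrow = TRUE)

  if (spec$activation_amplitude > 0) {
    if (is.null(paradigm)) stopf("an active spec needs a paradigm")
    reg <- activation_regressor(paradigm, nt, spec$tr)
    act <- spec$activation_amplitude * spec$noise_sd * reg
    idx <- which(as.vector(spec$active_region))
    signal[idx, ] <- signal[idx, ] +
      matrix(act, nrow = length(idx), ncol = nt, byrow = TRUE)
  }

  y <- if (spec$rician) {
    sqrt((signal + noise$real)^2 + noise$imag^2)
  } else {
    signal + noise$real
  }

  ds <- fmri_dataset(as_volume_series(y, sdim), mask = spec$mask,
                     tr = spec$tr, voxel_size = spec$voxel_size)
  list(dataset = ds, truth = spec$active_region)
}

# Paradigm indicator convolved with the HRF, peak-normalized to 1 so
# activation_amplitude is interpretable as a multiple of noise_sd.
activation_regressor <- function(paradigm, nt, tr) {
  ind <- paradigm_indicator_vector(paradigm, nt, tr)
  h <- hrf_double_gamma(seq(0, 32, by = tr))
  reg <- stats::convolve(ind, rev(h), type = "open")[seq_len(nt)]
  mx <- max(abs(reg))
  if (mx == 0) stopf("paradigm produces a zero activation regressor")
  reg / mx
}

# Simulate y_t = sum_k a_k y_{t-k} + e_t rowwise for a matrix of innovations
# (rows = voxels) with per-row coefficients (rows of cmat), zero initial
# state.
ar_simulate <- function(innov, cmat) {
  nt <- ncol(innov)
  p <- ncol(cmat)
  y <- innov
  for (t in seq_len(nt)) {
    kmax <- min(p, t - 1L)
    if (kmax >= 1L) {
      for (k in seq_len(kmax)) {
        y[, t] <- y[, t] + cmat[, k] * y[, t - k]
      }
    }
  }
  y
}

#' Serialize / restore a synthetic specification as JSON
#'
#' Arrays (spatially varying coefficients, masks, active regions) are stored
#' flattened with their dimensions, so a written spec restores bit-identical
#' generator behavior.
#'
#' @param spec A [synthetic_spec()].
#' @param path JSON file path.
#' @return `write_synthetic_spec()`: `path`, invisibly;
#'   `read_synthetic_spec()`: the restored `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stopf("JSON serialization needs the 'jsonlite' package")
  }
  enc <- function(x) {
    if (is.array(x)) list(dim = dim(x), values = as.vector(x)) else x
  }
  obj <- lapply(unclass(spec), enc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stopf("JSON serialization needs the 'jsonlite' package")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x$dim)) array(x$values, dim = x$dim) else x
  }
  obj <- lapply(obj, dec)
  synthetic_spec(shape = obj$shape, nt = obj$nt, tr = obj$tr,
                 voxel_size = obj$voxel_size, ar_coeffs = obj$ar_coeffs,
                 trend_coeffs = obj$trend_coeffs,
                 activation_amplitude = obj$activation_amplitude,
                 active_region = array(as.logical(obj$active_region),
                                       dim = dim(obj$active_region)),
                 noise_sd = obj$noise_sd,
                 mask = array(as.logical(obj$mask), dim = dim(obj$mask)),
                 rician = obj$rician, seed = obj$seed)
}
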