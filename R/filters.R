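# Spatial smoothing kernels and mask-aware (normalized) convolution.
#
# All kernels used here are centrally symmetric, so correlation and
# convolution coincide; the code computes zero-padded correlation.

# 1-D zero-padded convolution along spatial axis 1..3 of a 3-D or 4-D array.
conv_axis <- function(arr, k, axis) {
  nd <- length(dim(arr))
  n <- dim(arr)[axis]
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (o in -r:r) {
    w <- k[o + r + 1L]
    if (w == 0) next
    i1 <- max(1L, 1L - o)
    i2 <- min(n, n - o)
    if (i1 > i2) next
    s1 <- i1 + o
    s2 <- i2 + o
    if (nd == 3L) {
      if (axis == 1L) out[i1:i2, , ] <- out[i1:i2, , ] + w * arr[s1:s2, , ]
      else if (axis == 2L) out[, i1:i2, ] <- out[, i1:i2, ] + w * arr[, s1:s2, ]
      else out[, , i1:i2] <- out[, , i1:i2] + w * arr[, , s1:s2]
    } else {
      if (axis == 1L) out[i1:i2, , , ] <- out[i1:i2, , , ] + w * arr[s1:s2, , , ]
      else if (axis == 2L) out[, i1:i2, , ] <- out[, i1:i2, , ] + w * arr[, s1:s2, , ]
      else out[, , i1:i2, ] <- out[, , i1:i2, ] + w * arr[, , s1:s2, ]
    }
  }
  out
}

# Full 2-D zero-padded convolution over axes (x, y); z and t untouched.
conv_xy <- function(arr, k2d) {
  nd <- length(dim(arr))
  n1 <- dim(arr)[1]
  n2 <- dim(arr)[2]
  r1 <- (nrow(k2d) - 1L) %/% 2L
  r2 <- (ncol(k2d) - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (o2 in -r2:r2) {
    j1 <- max(1L, 1L - o2)
    j2 <- min(n2, n2 - o2)
    if (j1 > j2) next
    for (o1 in -r1:r1) {
      w <- k2d[o1 + r1 + 1L, o2 + r2 + 1L]
      if (w == 0) next
      i1 <- max(1L, 1L - o1)
      i2 <- min(n1, n1 - o1)
      if (i1 > i2) next
      if (nd == 3L) {
        out[i1:i2, j1:j2, ] <- out[i1:i2, j1:j2, ] +
          w * arr[(i1 + o1):(i2 + o1), (j1 + o2):(j2 + o2), ]
      } else {
        out[i1:i2, j1:j2, , ] <- out[i1:i2, j1:j2, , ] +
          w * arr[(i1 + o1):(i2 + o1), (j1 + o2):(j2 + o2), , ]
      }
    }
  }
  out
}

# Full 3-D zero-padded convolution (for nonseparable 3-D kernels).
conv_xyz <- function(arr, k3d) {
  nd <- length(dim(arr))
  n3 <- dim(arr)[3]
  r3 <- (dim(k3d)[3] - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (o3 in -r3:r3) {
    j1 <- max(1L, 1L - o3)
    j2 <- min(n3, n3 - o3)
    if (j1 > j2) next
    slab <- k3d[, , o3 + r3 + 1L]
    if (all(slab == 0)) next
    if (nd == 3L) {
      out[, , j1:j2] <- out[, , j1:j2, drop = FALSE] +
        conv_xy(arr[, , (j1 + o3):(j2 + o3), drop = FALSE], slab)
    } else {
      out[, , j1:j2, ] <- out[, , j1:j2, , drop = FALSE] +
        conv_xy(arr[, , (j1 + o3):(j2 + o3), , drop = FALSE], slab)
    }
  }
  out
}

# Apply a perm_kernel to a 3-D or 4-D array (raw convolution, zero padded).
apply_kernel <- function(arr, kernel) {
  stopifnot(inherits(kernel, "perm_kernel"))
  if (!is.null(kernel$sep)) {
    out <- arr
    for (axis in seq_along(kernel$sep)) {
      k1 <- kernel$sep[[axis]]
      if (!is.null(k1) && !(length(k1) == 1L && k1 == 1)) {
        out <- conv_axis(out, k1, axis)
      }
    }
    out
  } else if (kernel$dims == 2L) {
    conv_xy(arr, kernel$kernel)
  } else {
    conv_xyz(arr, kernel$kernel)
  }
}

new_perm_kernel <- function(kernel, sep, dims, fwhm_mm, voxel_size, label,
                            kind = "lowpass") {
  structure(list(kernel = kernel, sep = sep, dims = as.integer(dims),
                 fwhm_mm = fwhm_mm, voxel_size = voxel_size, label = label,
                 kind = kind),
            class = "perm_kernel")
}

#' @export
print.perm_kernel <- function(x, ...) {
  cat(sprintf("<perm_kernel> '%s', %d-D, support %s, sum %.4g\n", x$label,
              x$dims, paste(dim(x$kernel) %||% length(x$kernel), collapse = "x"),
              sum(x$kernel)))
  invisible(x)
}

#' Isotropic Gaussian smoothing kernel
#'
#' Builds a separable Gaussian kernel with `sigma = fwhm / sqrt(8 ln 2)` per
#' axis (in voxel units), truncated at a 3-sigma radius and renormalized to
#' unit sum (the truncation loses < 0.3% of the mass).
#'
#' @param fwhm_mm Full width at half maximum in mm (> 0).
#' @param voxel_size Voxel size in mm (scalar or length 3).
#' @param dims 2 for slicewise smoothing, 3 for volumetric (default).
#' @return A `perm_kernel`.
#' @export
gaussian_kernel <- function(fwhm_mm, voxel_size = c(3.75, 3.75, 3.75), dims = 3L) {
  if (fwhm_mm <= 0) stopf("`fwhm_mm` must be positive")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stopf("`dims` must be 2 or 3")
  if (fwhm_mm < 0.1 * min(voxel_size[seq_len(dims)])) {
    stopf("requested FWHM is below 0.1 voxel; kernel cannot be resolved")
  }
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  sigma_vox <- sigma_mm / voxel_size[seq_len(dims)]
  sep <- lapply(sigma_vox, gauss1d)
  full <- sep[[1]]
  for (i in 2:dims) full <- outer(full, sep[[i]])
  if (dims == 2L) sep <- c(sep, list(NULL))
  new_perm_kernel(full, sep, dims, fwhm_mm, voxel_size,
                  sprintf("gaussian %.3g mm", fwhm_mm))
}

gauss1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Identity (delta) kernel
#'
#' @param dims 2 or 3.
#' @return A `perm_kernel` that leaves data unchanged.
#' @export
delta_kernel <- function(dims = 3L) {
  dims <- as.integer(dims)
  full <- array(1, dim = rep(1L, dims))
  new_perm_kernel(full, rep(list(1), 3L), dims, 0, c(1, 1, 1), "delta")
}

#' Normalized (certainty-weighted) convolution
#'
#' Computes `((c * s) conv f) / (c conv f)`: the convolution of the
#' certainty-weighted signal divided by the convolved certainty. With a 0/1
#' brain-mask certainty this prevents out-of-brain values (e.g. AR
#' parameters near 0) from biasing smoothed estimates at the edge of the
#' brain. Voxels whose smoothed certainty is (numerically) zero are set to 0.
#'
#' @param volume 3-D array (or 4-D array, smoothed volume by volume).
#' @param certainty 3-D array in `[0, 1]`, same spatial shape.
#' @param kernel A `perm_kernel`.
#' @return Array of the same shape as `volume`, with attribute
#'   `"undefined"` marking spatial voxels where the smoothed certainty was
#'   zero.
#' @export
normalized_convolve <- function(volume, certainty, kernel) {
  sdim <- spatial_dim(volume)
  if (!identical(as.integer(dim(certainty)), as.integer(sdim))) {
    stopf("`certainty` shape must match the volume's spatial shape")
  }
  certainty <- array(as.numeric(certainty), dim = sdim)
  if (any(certainty < 0 | certainty > 1)) stopf("certainty must lie in [0, 1]")
  if (all(certainty == 0)) stopf("certainty is zero everywhere")
  den <- apply_kernel(certainty, kernel)
  num <- apply_kernel(volume * as.vector(certainty), kernel)
  eps <- 1e-12 * max(den)
  undef <- den <= eps
  den[undef] <- 1
  out <- num / as.vector(den)
  out[as.vector(undef)] <- 0
  attr(out, "undefined") <- undef
  out
}

#' Mask-aware smoothing of a 4-D dataset
#'
#' Smooths every volume by normalized convolution with the brain mask as
#' certainty and zeroes everything outside the mask. Results inside the mask
#' are invariant to arbitrary data outside it.
#'
#' @param data4d 4-D array (or an [fmri_dataset()]).
#' @param mask 3-D logical array (taken from the dataset if omitted).
#' @param kernel A `perm_kernel`.
#' @return Smoothed 4-D array (or `fmri_dataset`, matching the input type).
#' @export
smooth_dataset <- function(data4d, mask = NULL, kernel) {
  if (inherits(data4d, "fmri_dataset")) {
    out <- data4d
    out$data <- smooth_dataset(data4d$data, mask %||% data4d$mask, kernel)
    return(out)
  }
  if (is.null(mask)) mask <- array(TRUE, dim = spatial_dim(data4d))
  sm <- normalized_convolve(data4d, mask, kernel)
  attr(sm, "undefined") <- NULL
  sm * as.vector(array(as.numeric(mask), dim = dim(mask)))
}

# ---- FFT-based convolution (used by the filter-bank applier, where the
# same data volume is filtered by several large nonseparable kernels) ------

# FFT over the first `nd` dimensions of an array; trailing dimensions are
# carried along. The dimension swaps used are involutions, so the same
# permutation restores the layout.
fft_first <- function(x, nd, inverse = FALSE) {
  d <- dim(x)
  xm <- stats::mvfft(matrix(x, d[1]), inverse = inverse)
  x <- array(xm, d)
  if (nd >= 2L) {
    pr <- c(2L, 1L, seq_along(d)[-(1:2)])
    x <- aperm(x, pr)
    d2 <- dim(x)
    x <- aperm(array(stats::mvfft(matrix(x, d2[1]), inverse = inverse), d2), pr)
  }
  if (nd >= 3L) {
    pr <- c(3L, 2L, 1L, seq_along(d)[-(1:3)])
    x <- aperm(x, pr)
    d3 <- dim(x)
    x <- aperm(array(stats::mvfft(matrix(x, d3[1]), inverse = inverse), d3), pr)
  }
  x
}

# Padded sizes (composite for FFT speed) for spatial dims + kernel radii.
fft_pad_sizes <- function(sdim, rad) {
  vapply(seq_along(rad), function(i) {
    as.integer(stats::nextn(sdim[i] + 2L * rad[i], c(2, 3, 5)))
  }, integer(1))
}

# FFT of a centered kernel laid out for circular correlation on a padded
# grid (kernel element at offset o goes to index (-o mod P) + 1).
kernel_fft <- function(k, P) {
  kd <- dim(k)
  nd <- length(kd)
  rad <- (kd - 1L) %/% 2L
  pos <- lapply(seq_len(nd), function(i) {
    o <- seq_len(kd[i]) - rad[i] - 1L
    ((-o) %% P[i]) + 1L
  })
  kpad <- array(0, dim = P)
  if (nd == 2L) kpad[pos[[1]], pos[[2]]] <- k
  else kpad[pos[[1]], pos[[2]], pos[[3]]] <- k
  fft_first(kpad, nd)
}

# Forward FFT of a zero-padded 4-D (or 3-D) array over its first nd dims.
fft_pad_forward <- function(arr, P, nd) {
  d <- dim(arr)
  pd <- c(P, d[-seq_len(nd)])
  ap <- array(0, dim = pd)
  if (nd == 2L) {
    if (length(d) == 4L) ap[seq_len(d[1]), seq_len(d[2]), , ] <- arr
    else ap[seq_len(d[1]), seq_len(d[2]), ] <- arr
  } else {
    if (length(d) == 4L) ap[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- arr
    else ap[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  }
  fft_first(ap, nd)
}

# Multiply a padded-data FFT by a kernel FFT, invert and crop to the
# original spatial shape.
fft_filter_crop <- function(F, Kf, nd, sdim, out_dim) {
  out <- fft_first(F * as.vector(Kf), nd, inverse = TRUE)
  out <- Re(out) / prod(dim(Kf))
  if (nd == 2L) {
    if (length(out_dim) == 4L) out <- out[seq_len(sdim[1]), seq_len(sdim[2]), , , drop = FALSE]
    else out <- out[seq_len(sdim[1]), seq_len(sdim[2]), , drop = FALSE]
  } else {
    if (length(out_dim) == 4L) out <- out[seq_len(sdim[1]), seq_len(sdim[2]), seq_len(sdim[3]), , drop = FALSE]
    else out <- out[seq_len(sdim[1]), seq_len(sdim[2]), seq_len(sdim[3]), drop = FALSE]
  }
  array(out, dim = out_dim)
}
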