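# CCA spatial filter banks.
#
# 2D mode: one small isotropic Gaussian plus three anisotropic Gaussians with
# long axes at 0, 60 and 120 degrees. Any nonnegative combination is a
# plausible lowpass filter: the small filter alone is a small isotropic
# lowpass, anisotropic combinations give oriented lowpass filters, and equal
# weights on all four reproduce (to a few percent) an isotropic Gaussian
# whose FWHM equals the bank's design size, which is therefore the largest
# filter the CCA can create.
#
# Sizing: long/short axis ratio 3:1, small filter FWHM = fwhm_max/2, and
# the long axis calibrated (numerically, once, on a fine grid; the factor is
# scale invariant) so that the best-fit isotropic Gaussian to the
# equal-weight combination has FWHM exactly fwhm_max. A Gaussian mixture
# with a genuinely small first component cannot match a single wide
# Gaussian in L2 to within a few percent - it is always more peaked - so
# the bank is width-matched, not shape-matched.
.aniso_long_factor <- 2.3423

#' 2D CCA filter bank (four filters)
#'
#' @param fwhm_max_mm Design size: the FWHM of the largest (equal-weight)
#'   isotropic filter the bank can create.
#' @param voxel_size Voxel size in mm (scalar or length 3; only x and y are
#'   used by the 2-D kernels).
#' @return A `filter_bank` with 4 slicewise kernels: `small` (isotropic,
#'   FWHM `fwhm_max/2`) and `aniso0`, `aniso60`, `aniso120` (3:1 elliptical
#'   Gaussians).
#' @export
cca_filter_bank_2d <- function(fwhm_max_mm = 8, voxel_size = c(3.75, 3.75, 3.75)) {
  if (fwhm_max_mm <= 0) stopf("`fwhm_max_mm` must be positive")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  sigma_max <- fwhm_max_mm / sqrt(8 * log(2))
  sigma_l <- .aniso_long_factor * sigma_max
  sigma_s <- sigma_l / 3
  sigma_0 <- 0.5 * sigma_max
  trunc <- 5 * sigma_l
  r <- ceiling(trunc / min(voxel_size[1:2]))

  small <- aniso_gauss2d(sigma_0, sigma_0, 0, r, voxel_size[1:2], trunc)
  kernels <- list(
    new_perm_kernel(small, NULL, 2L, fwhm_max_mm / 2, voxel_size, "small"),
    new_perm_kernel(aniso_gauss2d(sigma_l, sigma_s, 0, r, voxel_size[1:2], trunc),
                    NULL, 2L, NA_real_, voxel_size, "aniso0"),
    new_perm_kernel(aniso_gauss2d(sigma_l, sigma_s, pi / 3, r, voxel_size[1:2], trunc),
                    NULL, 2L, NA_real_, voxel_size, "aniso60"),
    new_perm_kernel(aniso_gauss2d(sigma_l, sigma_s, 2 * pi / 3, r, voxel_size[1:2], trunc),
                    NULL, 2L, NA_real_, voxel_size, "aniso120")
  )
  new_filter_bank(kernels, dims = 2L, fwhm_max_mm = fwhm_max_mm,
                  mode = "cca2d")
}

# Elliptical 2-D Gaussian kernel sampled in mm coordinates, unit sum.
# Truncation is a disc (radius trunc_mm), not the square support: a
# rotation-invariant cutoff keeps the three orientations exact rotations of
# one another on the grid (equal mass and energy to aliasing accuracy).
aniso_gauss2d <- function(sigma_long, sigma_short, theta, r, voxel_xy,
                          trunc_mm = Inf) {
  ix <- (-r):r
  x <- outer(ix * voxel_xy[1], rep(1, 2 * r + 1))
  y <- outer(rep(1, 2 * r + 1), ix * voxel_xy[2])
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  k <- exp(-0.5 * ((u / sigma_long)^2 + (v / sigma_short)^2))
  k[x^2 + y^2 > trunc_mm^2] <- 0
  k / sum(k)
}

#' 3D scale-adaptive CCA filter pair
#'
#' One isotropic 3-D Gaussian at `sigma0 = fwhm_max / (2 sqrt(8 ln 2))` and
#' its derivative with respect to the width parameter sigma, sampled on the
#' same support. Combinations `g + w dg/dsigma` approximate Gaussians of
#' varying width, so the CCA can adapt the amount (but not the orientation)
#' of smoothing per voxel.
#'
#' @inheritParams cca_filter_bank_2d
#' @return A `filter_bank` with 2 volumetric kernels `iso` and `dsigma`
#'   (the derivative kernel sums to ~0 by construction).
#' @export
cca_filters_3d <- function(fwhm_max_mm = 8, voxel_size = c(3.75, 3.75, 3.75)) {
  if (fwhm_max_mm <= 0) stopf("`fwhm_max_mm` must be positive")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  sigma0 <- fwhm_max_mm / (2 * sqrt(8 * log(2)))
  r <- ceiling(6 * sigma0 / min(voxel_size))
  ix <- (-r):r
  g1 <- function(d) exp(-0.5 * (ix * d / sigma0)^2)
  # r^2 on the grid, in mm^2
  xs <- ix * voxel_size[1]
  ys <- ix * voxel_size[2]
  zs <- ix * voxel_size[3]
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  g <- exp(-r2 / (2 * sigma0^2))
  s <- sum(g)
  g <- g / s
  dg <- exp(-r2 / (2 * sigma0^2)) * (r2 / sigma0^3 - 3 / sigma0) / s
  kernels <- list(
    new_perm_kernel(g, NULL, 3L, 2 * sigma0 * sqrt(8 * log(2)) / 2, voxel_size, "iso"),
    new_perm_kernel(dg, NULL, 3L, NA_real_, voxel_size, "dsigma",
                    kind = "derivative")
  )
  new_filter_bank(kernels, dims = 3L, fwhm_max_mm = fwhm_max_mm,
                  mode = "cca3d")
}

new_filter_bank <- function(kernels, dims, fwhm_max_mm, mode) {
  structure(list(kernels = kernels, dims = as.integer(dims),
                 fwhm_max_mm = fwhm_max_mm,
                 labels = vapply(kernels, `[[`, "", "label"),
                 mode = mode),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %s: %d %d-D kernels (%s), design FWHM %.3g mm\n",
              x$mode, length(x$kernels), x$dims,
              paste(x$labels, collapse = ", "), x$fwhm_max_mm))
  invisible(x)
}

#' Weighted combination of the kernels of a filter bank
#'
#' @param bank A `filter_bank`.
#' @param weights Numeric weights, one per kernel.
#' @return The combined kernel array.
#' @export
combine_bank <- function(bank, weights) {
  if (length(weights) != length(bank$kernels)) {
    stopf("need %d weights", length(bank$kernels))
  }
  out <- bank$kernels[[1]]$kernel * weights[1]
  for (i in seq_along(weights)[-1]) {
    out <- out + bank$kernels[[i]]$kernel * weights[i]
  }
  out
}

#' Export a filter bank as plain-text grids
#'
#' Writes each kernel as a TSV grid (slices separated by blank lines for 3-D
#' kernels) for visual inspection.
#'
#' @param bank A `filter_bank`.
#' @param dir Output directory.
#' @export
write_filter_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(bank$kernels)) {
    k <- bank$kernels[[i]]$kernel
    path <- file.path(dir, paste0(bank$labels[i], ".tsv"))
    con <- file(path, "w")
    if (length(dim(k)) == 2L) {
      utils::write.table(k, con, sep = "\t", row.names = FALSE, col.names = FALSE)
    } else {
      for (z in seq_len(dim(k)[3])) {
        utils::write.table(k[, , z], con, sep = "\t", row.names = FALSE,
                           col.names = FALSE)
        writeLines("", con)
      }
    }
    close(con)
  }
  invisible(dir)
}
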