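#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking around
#' 5-6 s and a later, smaller undershoot. Parameter convention: gamma shape
#' `delay/dispersion`, scale `dispersion`, undershoot scaled by
#' `1/undershoot_ratio`.
#'
#' @param time_s Nonnegative, increasing time grid in seconds.
#' @param peak_delay,peak_dispersion Delay (s) and dispersion of the positive
#'   lobe (defaults 6 and 1).
#' @param undershoot_delay,undershoot_dispersion Delay and dispersion of the
#'   undershoot (defaults 16 and 1).
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return Numeric vector of HRF values on `time_s`.
#' @export
hrf_double_gamma <- function(time_s, peak_delay = 6, peak_dispersion = 1,
                             undershoot_delay = 16, undershoot_dispersion = 1,
                             undershoot_ratio = 6) {
  if (any(time_s < 0)) stopf("HRF time grid must be nonnegative")
  if (is.unsorted(time_s)) stopf("HRF time grid must be increasing")
  stats::dgamma(time_s, shape = peak_delay / peak_dispersion,
                scale = peak_dispersion) -
    stats::dgamma(time_s, shape = undershoot_delay / undershoot_dispersion,
                  scale = undershoot_dispersion) / undershoot_ratio
}

#' Temporal design matrix for a block paradigm
#'
#' Convolves the stimulus indicator with the double-gamma HRF and with its
#' temporal derivative on a fine time grid, samples both at the volume
#' acquisition times, then mean-corrects, Euclidean-normalizes and
#' orthogonalizes the two regressors (the derivative is Gram-Schmidt
#' orthogonalized against the HRF regressor). No further regressors and no
#' high-pass or low-pass filtering are used.
#'
#' @param paradigm A `paradigm`.
#' @param nt Number of volumes.
#' @param tr Repetition time in seconds.
#' @param contrast Contrast vector, default `c(1, 0)` (HRF regressor).
#' @param dt Fine-grid step in seconds used for the convolution.
#' @return An object of class `design_matrix`: list with `X` (nt x 2, zero
#'   mean, unit norm, orthogonal columns), `contrast` and `tr`.
#' @export
build_design <- function(paradigm, nt, tr, contrast = c(1, 0), dt = 0.1) {
  ind_vol <- paradigm_indicator_vector(paradigm, nt, tr)
  if (length(unique(ind_vol)) < 2L) {
    stopf("degenerate design: the paradigm indicator is constant (all-on or all-off)")
  }
  # indicator on the fine grid
  steps_per_tr <- max(1L, round(tr / dt))
  dt <- tr / steps_per_tr
  fine_n <- nt * steps_per_tr
  ind_fine <- rep(ind_vol, each = steps_per_tr)

  tgrid <- seq(0, 32, by = dt)
  h <- hrf_double_gamma(tgrid)
  # temporal derivative by central finite differences on the fine grid
  dh <- c(h[2] - h[1], (h[-(1:2)] - h[-((length(h) - 1):length(h))]) / 2,
          h[length(h)] - h[length(h) - 1]) / dt

  conv_fine <- function(kernel) {
    stats::convolve(ind_fine, rev(kernel), type = "open")[seq_len(fine_n)] * dt
  }
  sample_idx <- 1L + (seq_len(nt) - 1L) * steps_per_tr
  r1 <- conv_fine(h)[sample_idx]
  r2 <- conv_fine(dh)[sample_idx]

  r1 <- r1 - mean(r1)
  n1 <- sqrt(sum(r1^2))
  if (n1 < 1e-10 * max(1, max(abs(ind_vol)))) {
    stopf("degenerate design: the HRF regressor is constant (all-on or all-off paradigm)")
  }
  r1 <- r1 / n1
  r2 <- r2 - mean(r2)
  r2 <- r2 - sum(r2 * r1) * r1
  n2 <- sqrt(sum(r2^2))
  if (n2 < 1e-12) stopf("degenerate design: derivative regressor is collinear")
  r2 <- r2 / n2

  structure(list(X = cbind(hrf = r1, derivative = r2),
                 contrast = as.numeric(contrast), tr = tr),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d regressors (TR %.3g s), contrast (%s)\n",
              nrow(x$X), ncol(x$X), x$tr, paste(x$contrast, collapse = ", ")))
  invisible(x)
}

#' Export a design matrix as TSV
#'
#' @param design A `design_matrix`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design$X, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Orthonormal cubic polynomial basis
#'
#' Columns span exactly the polynomials of degree 0..3 on a normalized time
#' axis in `[-1, 1]` (Legendre-like, for conditioning) and are orthonormal.
#'
#' @param nt Number of time points (>= 5).
#' @return nt x 4 matrix with orthonormal columns.
#' @export
trend_basis <- function(nt) {
  if (nt < 5L) stopf("need at least 5 time points for cubic detrending")
  tn <- seq(-1, 1, length.out = nt)
  qr.Q(qr(outer(tn, 0:3, `^`)))
}

#' Cubic detrending
#'
#' Removes the least-squares projection onto polynomials up to degree 3
#' (including the mean). A linear, idempotent projection.
#'
#' @param series Numeric vector, or matrix with time in rows (one series per
#'   column).
#' @return Detrended series of the same shape, orthogonal to all polynomials
#'   of degree <= 3.
#' @export
cubic_detrend <- function(series) {
  v <- is.null(dim(series))
  y <- if (v) matrix(series, ncol = 1L) else series
  P <- trend_basis(nrow(y))
  out <- y - P %*% crossprod(P, y)
  if (v) drop(out) else out
}

#' Remove the fitted BOLD component
#'
#' Subtracts the ordinary-least-squares fit of the design regressors from
#' each series, leaving residuals orthogonal to every column of `X`. Used to
#' build residual data before estimating the null distribution.
#'
#' @param series Numeric vector or matrix with time in rows.
#' @param X Design regressors (nt x k matrix) or a `design_matrix`.
#' @return Residual series of the same shape.
#' @export
remove_bold <- function(series, X) {
  if (inherits(X, "design_matrix")) X <- X$X
  v <- is.null(dim(series))
  y <- if (v) matrix(series, ncol = 1L) else series
  if (nrow(y) != nrow(X)) {
    stopf("series length %d does not match design rows %d", nrow(y), nrow(X))
  }
  qrX <- qr(X)
  out <- y - qr.fitted(qrX, y)
  if (v) drop(out) else out
}

# Rowwise projection-removal for a voxels-by-time matrix against an
# orthonormal temporal basis B (nt x d): M - (M B) B'.
project_out_rows <- function(M, B) {
  M - (M %*% B) %*% t(B)
}
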