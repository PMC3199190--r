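# Voxelwise AR estimation, spatially pooled whitening and whiteness tests.

#' Sample autocorrelations
#'
#' Biased (divide-by-n) sample autocorrelations, the estimator that keeps
#' the Yule-Walker Toeplitz system positive semidefinite.
#'
#' @param series Numeric vector (demeaned internally).
#' @param lags Integer vector of lags (>= 1).
#' @return Autocorrelations at `lags`.
#' @export
sample_autocorr <- function(series, lags) {
  y <- series - mean(series)
  denom <- sum(y^2)
  if (denom == 0) stopf("degenerate (constant) series")
  n <- length(y)
  vapply(lags, function(k) {
    if (k >= n) return(0)
    sum(y[seq_len(n - k)] * y[(k + 1):n]) / denom
  }, numeric(1))
}

# Rowwise biased autocorrelations for a voxels-by-time matrix.
# Returns V x length(lags); rows with zero variance give 0.
autocorr_rows <- function(M, lags) {
  M <- M - rowMeans(M)
  nt <- ncol(M)
  denom <- rowSums(M^2)
  denom[denom == 0] <- Inf
  out <- matrix(0, nrow = nrow(M), ncol = length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    if (k < nt) {
      out[, i] <- rowSums(M[, seq_len(nt - k), drop = FALSE] *
                          M[, (k + 1):nt, drop = FALSE]) / denom
    }
  }
  out
}

#' Yule-Walker AR coefficient estimate
#'
#' Solves the p x p Toeplitz system of biased sample autocorrelations for
#' the AR(p) coefficients of one series.
#'
#' @param series Numeric vector, length > 2p.
#' @param p AR order (>= 1).
#' @return Coefficient vector `a_1..a_p` of
#'   `y_t = sum_k a_k y_(t-k) + e_t`.
#' @export
yule_walker <- function(series, p) {
  p <- as.integer(p)
  if (p < 1L) stopf("`p` must be >= 1")
  if (length(series) <= 2L * p) stopf("series too short for AR(%d)", p)
  if (any(!is.finite(series))) stopf("series has non-finite values")
  r <- sample_autocorr(series, 0:p)  # errors on constant series
  R <- stats::toeplitz(r[seq_len(p)])
  if (p > 1L && abs(det(R)) < 1e-12) stopf("degenerate series: singular Yule-Walker system")
  drop(solve(R, r[2:(p + 1)]))
}

# Vectorized Levinson-Durbin over rows: rmat is V x p (lags 1..p).
# Returns V x p coefficient matrix.
levinson_rows <- function(rmat) {
  p <- ncol(rmat)
  V <- nrow(rmat)
  a <- matrix(0, V, p)
  a[, 1] <- rmat[, 1]
  if (p == 1L) return(a)
  err <- 1 - rmat[, 1]^2
  for (k in 2:p) {
    acc <- rmat[, k]
    for (j in seq_len(k - 1L)) acc <- acc - a[, j] * rmat[, k - j]
    kap <- acc / pmax(err, 1e-12)
    anew <- a
    for (j in seq_len(k - 1L)) anew[, j] <- a[, j] - kap * a[, k - j]
    anew[, k] <- kap
    a <- anew
    err <- err * (1 - kap^2)
  }
  a
}

#' Per-voxel AR coefficient field
#'
#' Estimates AR(p) coefficients at every in-mask voxel by the Yule-Walker
#' equations (biased autocorrelations, solved by Levinson recursion);
#' out-of-mask voxels get zero coefficients.
#'
#' @param data4d 4-D array or voxels-by-time matrix.
#' @param mask 3-D logical array (or logical vector for matrix input).
#' @param p AR order.
#' @return An `ar_field`: list with `coeffs` (4-D array `c(shape, p)` or
#'   V x p matrix), `order` and `shape`.
#' @export
estimate_ar_field <- function(data4d, mask, p = 4L) {
  p <- as.integer(p)
  is4d <- length(dim(data4d)) == 4L
  M <- if (is4d) as_voxel_matrix(data4d) else data4d
  mvec <- as.vector(mask)
  rmat <- matrix(0, nrow(M), p)
  rmat[mvec, ] <- autocorr_rows(M[mvec, , drop = FALSE], seq_len(p))
  cmat <- matrix(0, nrow(M), p)
  cmat[mvec, ] <- levinson_rows(rmat[mvec, , drop = FALSE])
  shape <- if (is4d) dim(data4d)[1:3] else NULL
  new_ar_field(cmat, p, shape)
}

new_ar_field <- function(cmat, p, shape) {
  coeffs <- if (is.null(shape)) cmat else array(cmat, dim = c(shape, p))
  structure(list(coeffs = coeffs, order = as.integer(p), shape = shape),
            class = "ar_field")
}

# V x p coefficient matrix view of an ar_field.
ar_coef_matrix <- function(field) {
  if (is.null(field$shape)) field$coeffs
  else matrix(field$coeffs, ncol = field$order)
}

#' @export
print.ar_field <- function(x, ...) {
  cat(sprintf("<ar_field> AR(%d)%s\n", x$order,
              if (is.null(x$shape)) "" else
                sprintf(" over %s grid", paste(x$shape, collapse = "x"))))
  invisible(x)
}

#' Spatial pooling of AR parameters
#'
#' Smooths each AR coefficient volume with a Gaussian kernel by normalized
#' convolution, using the brain mask as certainty (so near-zero out-of-brain
#' parameters cannot drag down estimates at the brain edge). This variance
#' pooling compensates for the high variance of AR estimates from short
#' (~80-sample) series.
#'
#' @param field An `ar_field` with volumetric coefficients.
#' @param mask 3-D logical array.
#' @param fwhm_mm Gaussian FWHM in mm (default 8).
#' @param voxel_size Voxel size in mm.
#' @return Smoothed `ar_field` (zero outside the mask).
#' @export
smooth_ar_field <- function(field, mask, fwhm_mm = 8,
                            voxel_size = c(3.75, 3.75, 3.75)) {
  if (is.null(field$shape)) stopf("smoothing needs a volumetric ar_field")
  if (fwhm_mm <= 0) stopf("`fwhm_mm` must be positive")
  kernel <- gaussian_kernel(fwhm_mm, voxel_size, dims = 3L)
  out <- field$coeffs
  mnum <- as.vector(array(as.numeric(mask), dim = dim(mask)))
  for (k in seq_len(field$order)) {
    sm <- normalized_convolve(array(field$coeffs[, , , k], dim = field$shape),
                              mask, kernel)
    attr(sm, "undefined") <- NULL
    out[, , , k] <- sm * mnum
  }
  new_ar_field(matrix(out, ncol = field$order), field$order, field$shape)
}

# Shrink non-stationary coefficient vectors radially: voxels whose
# characteristic roots reach modulus >= limit are scaled so the largest root
# has modulus `target`. Prevents divergent null data from rare unstable
# estimates.
enforce_stationarity <- function(cmat, limit = 0.99, target = 0.98) {
  for (v in seq_len(nrow(cmat))) {
    a <- cmat[v, ]
    if (all(a == 0)) next
    mx <- max(Mod(polyroot(c(rev(-a), 1))))
    if (mx >= limit) {
      rho <- target / mx
      cmat[v, ] <- a * rho^seq_along(a)
    }
  }
  cmat
}

#' Whitening transform
#'
#' `e_t = y_t - sum_k a_k y_(t-k)` with `y_(t<=0) = 0`; output has the same
#' length as the input, and the first p samples are only partially whitened
#' under this zero-initial-condition convention.
#'
#' @param series Numeric vector.
#' @param coeffs AR coefficients `a_1..a_p`.
#' @return The innovation series.
#' @export
whiten_series <- function(series, coeffs) {
  drop(whiten_rows(matrix(series, nrow = 1L),
                   matrix(coeffs, nrow = 1L)))
}

#' Inverse whitening transform
#'
#' Simulates the AR model `y_t = sum_k a_k y_(t-k) + e_t` with the given
#' innovations and zero initial state; the exact algebraic inverse of
#' [whiten_series()] for any coefficients, used to re-impose the estimated
#' temporal correlation on permuted innovations.
#'
#' @param innovations Numeric vector.
#' @param coeffs Stationary AR coefficients.
#' @return The simulated series.
#' @export
inverse_whiten <- function(innovations, coeffs) {
  if (!ar_is_stationary(coeffs)) stopf("`coeffs` are not stationary")
  drop(inverse_whiten_rows(matrix(innovations, nrow = 1L),
                           matrix(coeffs, nrow = 1L)))
}

# Rowwise whitening: M (V x nt), cmat (V x p).
whiten_rows <- function(M, cmat) {
  nt <- ncol(M)
  E <- M
  for (k in seq_len(ncol(cmat))) {
    if (k >= nt) break
    E[, (k + 1):nt] <- E[, (k + 1):nt] -
      M[, seq_len(nt - k), drop = FALSE] * cmat[, k]
  }
  E
}

# Rowwise inverse whitening (AR simulation with innovations E).
inverse_whiten_rows <- function(E, cmat) {
  nt <- ncol(E)
  p <- ncol(cmat)
  Y <- E
  for (t in seq_len(nt)) {
    for (k in seq_len(min(p, t - 1L))) {
      Y[, t] <- Y[, t] + cmat[, k] * Y[, t - k]
    }
  }
  Y
}

# Compose two whitening operators: the product of the AR polynomials
# (1 - sum a_k B^k)(1 - sum b_k B^k). Input/output are "a" conventions
# (V x p matrices); output has order pa + pb.
compose_ar <- function(cmat_new, cmat_old) {
  pa <- ncol(cmat_new)
  pb <- ncol(cmat_old)
  A <- cbind(1, -cmat_new)
  B <- cbind(1, -cmat_old)
  C <- matrix(0, nrow(A), pa + pb + 1L)
  for (i in seq_len(pa + 1L)) {
    for (j in seq_len(pb + 1L)) {
      C[, i + j - 1L] <- C[, i + j - 1L] + A[, i] * B[, j]
    }
  }
  -C[, -1L, drop = FALSE]
}

#' Iterated voxelwise whitening with spatial pooling
#'
#' Repeats (default 3 times): estimate AR(p) per voxel on the current
#' residuals, smooth the coefficient field by normalized convolution,
#' whiten. The accumulated whitening operator is the polynomial product of
#' the per-iteration AR polynomials, truncated back to order p (a warning is
#' issued when the truncated tail exceeds `1e-6`); the returned whitened
#' data are the final residual innovations.
#'
#' @param data4d 4-D array of detrended, BOLD-removed residuals (or a
#'   voxels-by-time matrix).
#' @param mask 3-D logical array (or logical vector).
#' @param p AR order (default 4; configurable 1..8).
#' @param iters Number of whitening passes (default 3).
#' @param fwhm_mm FWHM of the coefficient smoothing, or `NULL`/0 to disable.
#' @param voxel_size Voxel size in mm.
#' @return List with `whitened` (same shape as input) and `ar_field` (the
#'   accumulated order-p operator, stationarity-enforced).
#' @export
iterative_whiten <- function(data4d, mask, p = 4L, iters = 3L, fwhm_mm = 8,
                             voxel_size = c(3.75, 3.75, 3.75)) {
  p <- as.integer(p)
  if (p < 1L || p > 8L) stopf("`p` must be in 1..8")
  if (iters < 1L) stopf("`iters` must be >= 1")
  is4d <- length(dim(data4d)) == 4L
  M <- if (is4d) as_voxel_matrix(data4d) else data4d
  shape <- if (is4d) dim(data4d)[1:3] else NULL
  mvec <- as.vector(mask)

  acc <- NULL
  for (it in seq_len(iters)) {
    field <- estimate_ar_field(if (is4d) as_volume_series(M, shape) else M,
                               mask, p)
    if (!is.null(fwhm_mm) && fwhm_mm > 0 && !is.null(shape)) {
      field <- smooth_ar_field(field, mask, fwhm_mm, voxel_size)
    }
    cmat <- enforce_stationarity(ar_coef_matrix(field))
    M <- whiten_rows(M, cmat)
    acc <- if (is.null(acc)) cmat else compose_ar(cmat, acc)
  }

  if (ncol(acc) > p) {
    tail_max <- max(abs(acc[, (p + 1L):ncol(acc), drop = FALSE]))
    if (tail_max > 1e-6) {
      warning(sprintf(
        "accumulated AR operator truncated from order %d to %d (max dropped coefficient %.2g)",
        ncol(acc), p, tail_max), call. = FALSE)
    }
    acc <- acc[, seq_len(p), drop = FALSE]
  }
  acc <- enforce_stationarity(acc)
  acc[!mvec, ] <- 0
  list(whitened = if (is4d) as_volume_series(M, shape) else M,
       ar_field = new_ar_field(acc, p, shape))
}

#' Ljung-Box portmanteau statistic
#'
#' `Q = N (N + 2) * sum_(k=1..h) r(k)^2 / (N - k)`, asymptotically
#' chi-square with `h - p` degrees of freedom when the autocorrelations come
#' from residuals of an AR(p) whitening.
#'
#' @param autocorr Autocorrelations at lags `1..h` (at least `h` values;
#'   extra lags are ignored).
#' @param nt Series length `N`.
#' @param h Number of lags tested.
#' @return The Q statistic.
#' @export
ljung_box_q <- function(autocorr, nt, h) {
  if (h < 1L) stopf("`h` must be >= 1")
  if (nt <= h) stopf("`nt` must exceed `h`")
  if (length(autocorr) < h) stopf("need autocorrelations up to lag %d", h)
  r <- autocorr[seq_len(h)]
  nt * (nt + 2) * sum(r^2 / (nt - seq_len(h)))
}

#' @rdname ljung_box_q
#' @param p Order of the AR model used for whitening (0 for raw series).
#' @param level Test level (default 0.05).
#' @return `ljung_box_critical()`: the chi-square critical value with
#'   `h - p` degrees of freedom.
#' @export
ljung_box_critical <- function(h, p = 0L, level = 0.05) {
  if (h <= p) {
    stopf("h (%d) must exceed the AR order p (%d): the degrees of freedom otherwise become zero or negative",
          h, p)
  }
  stats::qchisq(1 - level, df = h - p)
}

#' Map of voxels failing the whiteness test
#'
#' Applies the Ljung-Box test voxelwise for each lag count in `h_range`,
#' flagging voxels with `Q` above the chi-square critical value with `h - p`
#' degrees of freedom at level 0.05, and reports the mean flagged count
#' across the tested lag counts. When `smooth_fwhm_mm` is given, the
#' per-lag autocorrelation volumes are first pooled by normalized
#' convolution (matching how the whitening itself pools AR parameters), so
#' Q is computed from smoothed autocorrelations.
#'
#' @param data4d 4-D array of (whitened) residual series.
#' @param mask 3-D logical array.
#' @param p AR order used for the whitening (0 if none).
#' @param h_range Lag counts to test; defaults to `(p+1):10`.
#' @param smooth_fwhm_mm FWHM for autocorrelation pooling, or `NULL` for
#'   none.
#' @param voxel_size Voxel size in mm.
#' @param level Voxelwise test level (default 0.05).
#' @return List with `flags` (3-D logical: nonwhite at any tested h),
#'   `counts` (data frame `h`, `count`) and `mean_count`.
#' @export
whiteness_map <- function(data4d, mask, p = 4L, h_range = NULL,
                          smooth_fwhm_mm = NULL,
                          voxel_size = c(3.75, 3.75, 3.75), level = 0.05) {
  p <- as.integer(p)
  if (is.null(h_range)) h_range <- seq.int(p + 1L, 10L)
  if (any(h_range <= p)) stopf("every h must exceed p = %d", p)
  hmax <- max(h_range)
  sdim <- spatial_dim(data4d)
  nt <- dim(data4d)[4]
  M <- as_voxel_matrix(data4d)
  mvec <- as.vector(mask)

  rmat <- matrix(0, nrow(M), hmax)
  rmat[mvec, ] <- autocorr_rows(M[mvec, , drop = FALSE], seq_len(hmax))
  if (!is.null(smooth_fwhm_mm) && smooth_fwhm_mm > 0) {
    kernel <- gaussian_kernel(smooth_fwhm_mm, voxel_size, dims = 3L)
    for (k in seq_len(hmax)) {
      sm <- normalized_convolve(array(rmat[, k], dim = sdim), mask, kernel)
      rmat[, k] <- as.vector(sm) * mvec
    }
  }

  # cumulative Q over lags, per voxel
  terms <- sweep(rmat^2, 2L, nt - seq_len(hmax), `/`) * nt * (nt + 2)
  Qcum <- t(apply(terms, 1L, cumsum))
  if (hmax == 1L) Qcum <- matrix(terms, ncol = 1L)

  counts <- integer(length(h_range))
  flags <- rep(FALSE, nrow(M))
  for (i in seq_along(h_range)) {
    h <- h_range[i]
    crit <- ljung_box_critical(h, p, level)
    bad <- mvec & (Qcum[, h] > crit)
    counts[i] <- sum(bad)
    flags <- flags | bad
  }
  list(flags = array(flags, dim = sdim),
       counts = data.frame(h = h_range, count = counts),
       mean_count = mean(counts))
}
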