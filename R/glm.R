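# Voxelwise general linear model.

#' GLM t-statistic for one voxel series
#'
#' Ordinary least squares `beta_hat = (X'X)^(-1) X'Y` with
#' `t = c'beta_hat / sqrt(var(resid) c'(X'X)^(-1) c)`; the residual variance
#' uses the unbiased denominator `nt - k`.
#'
#' @param series Numeric vector (length = rows of `X`).
#' @param X Design regressors (nt x k matrix) or a `design_matrix`.
#' @param contrast Contrast vector `c` (default from the design, else
#'   `c(1, 0, ...)`).
#' @return A `glm_fit`: list with `beta_hat`, `resid_var`, `tvalue` and
#'   `flagged` (`TRUE` when the residual variance is zero and the t-value is
#'   the infinite sentinel).
#' @export
glm_tstat <- function(series, X, contrast = NULL) {
  if (inherits(X, "design_matrix")) {
    contrast <- contrast %||% X$contrast
    X <- X$X
  }
  if (is.null(contrast)) contrast <- c(1, numeric(ncol(X) - 1L))
  if (length(series) != nrow(X)) {
    stopf("series length %d does not match design rows %d", length(series), nrow(X))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("design matrix is rank deficient")
  beta_hat <- drop(qr.coef(qrX, series))
  resid <- series - drop(X %*% beta_hat)
  df <- length(series) - ncol(X)
  resid_var <- sum(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  qc <- drop(t(contrast) %*% XtXinv %*% contrast)
  num <- sum(contrast * beta_hat)
  if (resid_var <= 1e-20 * mean(series^2)) {
    t <- sign(num) * Inf
    flagged <- TRUE
  } else {
    t <- num / sqrt(resid_var * qc)
    flagged <- FALSE
  }
  structure(list(beta_hat = beta_hat, resid_var = resid_var, tvalue = t,
                 flagged = flagged),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> t = %.4g, resid var = %.4g\n", x$tvalue, x$resid_var))
  invisible(x)
}

# Vectorized t-map over the rows of a voxels-by-time matrix.
# Returns a list with tmap (vector) and, optionally, precomputed pieces.
glm_tmap_rows <- function(M, X, contrast) {
  nt <- ncol(M)
  k <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  P <- M %*% X                      # V x k, rows are X'y
  Bhat <- P %*% XtXinv              # V x k
  ss <- rowSums(M^2)
  rss <- ss - rowSums(P * Bhat)
  rss[rss < 0] <- 0
  qc <- drop(t(contrast) %*% XtXinv %*% contrast)
  num <- drop(Bhat %*% contrast)
  denom <- sqrt(rss / (nt - k) * qc)
  t <- num / denom
  exact <- rss <= 1e-20 * ss
  t[exact] <- sign(num[exact]) * Inf
  t
}

#' Voxelwise GLM t-map
#'
#' @param data An [fmri_dataset()] or 4-D array.
#' @param design A `design_matrix` (or plain nt x k matrix).
#' @param mask 3-D logical array (taken from the dataset if omitted).
#' @param contrast Contrast vector.
#' @return 3-D array of t-values (0 outside the mask).
#' @export
glm_tmap <- function(data, design, mask = NULL, contrast = NULL) {
  if (inherits(data, "fmri_dataset")) {
    mask <- mask %||% data$mask
    data <- data$data
  }
  if (inherits(design, "design_matrix")) {
    contrast <- contrast %||% design$contrast
    design <- design$X
  }
  if (is.null(contrast)) contrast <- c(1, numeric(ncol(design) - 1L))
  sdim <- spatial_dim(data)
  if (is.null(mask)) mask <- array(TRUE, dim = sdim)
  M <- as_voxel_matrix(data)
  mvec <- as.vector(mask)
  out <- numeric(nrow(M))
  out[mvec] <- glm_tmap_rows(M[mvec, , drop = FALSE], design, contrast)
  array(out, dim = sdim)
}

#' AR(1) prewhitening for the GLM
#'
#' Applies the first-difference filter `y_t <- y_t - phi y_(t-1)` with one
#' global AR(1) coefficient to every voxel series and, consistently, to
#' every design column, so that the GLM errors are (approximately)
#' temporally uncorrelated and the t-value is a true t-value. When `phi` is
#' not supplied it is estimated as the in-mask median lag-1 autocorrelation
#' of the GLM residuals. Not required for the permutation-based analysis
#' itself; needed when permutation thresholds are compared with Bonferroni
#' or random-field-theory thresholds.
#'
#' @param data An [fmri_dataset()] or 4-D array.
#' @param design A `design_matrix`.
#' @param mask 3-D logical array.
#' @param phi AR(1) coefficient in (-1, 1), or `NULL` to estimate.
#' @return List with `data` (whitened, same type as input), `design`
#'   (whitened regressors, same class) and `phi`.
#' @export
prewhiten_glm <- function(data, design, mask = NULL, phi = NULL) {
  ds <- NULL
  if (inherits(data, "fmri_dataset")) {
    ds <- data
    mask <- mask %||% data$mask
    data <- data$data
  }
  sdim <- spatial_dim(data)
  if (is.null(mask)) mask <- array(TRUE, dim = sdim)
  X <- if (inherits(design, "design_matrix")) design$X else design
  M <- as_voxel_matrix(data)
  mvec <- as.vector(mask)
  if (is.null(phi)) {
    resid <- project_out_rows(M[mvec, , drop = FALSE], qr.Q(qr(X)))
    phi <- stats::median(autocorr_rows(resid, 1L))
  }
  if (abs(phi) >= 1) stopf("|phi| must be < 1 for a stationary AR(1) model")
  cvec <- matrix(phi, nrow(M), 1L)
  Mw <- whiten_rows(M, cvec)
  Xw <- whiten_rows(t(X), matrix(phi, ncol(X), 1L))
  Xw <- t(Xw)
  out_data <- as_volume_series(Mw, sdim)
  if (!is.null(ds)) {
    ds$data <- out_data
    out_data <- ds
  }
  out_design <- design
  if (inherits(design, "design_matrix")) out_design$X <- Xw else out_design <- Xw
  list(data = out_data, design = out_design, phi = phi)
}
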