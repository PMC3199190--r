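# Complete permutation analysis: surrogate null data by detrend -> whiten ->
# permute -> inverse whiten, statistic + smoothing inside every permutation,
# corrected thresholds and p-values from the maximum-statistic null.

#' Max-statistic random permutation test for one fMRI dataset
#'
#' Executes the complete single-threshold permutation analysis:
#' \enumerate{
#'   \item Compute the original statistic map on the preprocessed data
#'     (for the GLM: smoothed + detrended; for CCA the filter bank does the
#'     smoothing, so only detrending is applied).
#'   \item Cubic-detrend the raw series and remove the fitted BOLD
#'     component to form residual data.
#'   \item Estimate voxelwise AR(p) models, pool the parameters spatially,
#'     and whiten; repeated `whiten_iters` times with the operators
#'     accumulated.
#'   \item Per permutation: apply one shared random permutation to all
#'     whitened series, regenerate null fMRI series by inverse whitening,
#'     smooth, detrend, (optionally AR(1)-prewhiten for the GLM), compute
#'     the statistic over the mask, and record its maximum.
#'   \item Sort the maxima; the corrected threshold is the sorted value at
#'     position `ceil((1-alpha) Np)` and each voxel's corrected p is the
#'     fraction of maxima at least as large as its statistic.
#' }
#'
#' @param dataset An [fmri_dataset()].
#' @param paradigm A `paradigm`.
#' @param statistic `"glm"` (t-map), `"cca2d"` or `"cca3d"` (restricted
#'   canonical correlation with the matching filter bank).
#' @param fwhm_mm Smoothing FWHM in mm: the Gaussian kernel for the GLM, or
#'   the design size of the CCA filter bank. 0 disables GLM smoothing.
#' @param ar_order AR order for the whitening (default 4).
#' @param n_perm Number of permutations.
#' @param alpha Target familywise error level.
#' @param seed Integer seed for the permutation plan.
#' @param glm_whiten_each_perm AR(1)-prewhiten before the GLM, in the
#'   original analysis and inside each permutation. Off by default (not
#'   needed for permutation inference); turn on to compare thresholds with
#'   Bonferroni/RFT, where a true t-value is required.
#' @param exclude_nonwhite Drop voxels still failing the Ljung-Box test
#'   after whitening from the permutation test (default `FALSE`).
#' @param two_sided Record `max |t|` instead of the signed maximum
#'   (default `FALSE`, matching a one-sided activation test).
#' @param whiten_iters Whitening passes (default 3).
#' @param ar_smooth_fwhm_mm FWHM for AR parameter pooling (default 8 mm;
#'   0 disables).
#' @param plan Optional [make_plan()] object overriding `n_perm`/`seed`.
#' @return A `perm_test` object: `stat_map`, `pmap` (corrected p), `threshold`,
#'   `alpha`, `null` (the `max_null_distribution`), `analysis_mask`,
#'   `design`, `ar_field` and the configuration.
#' @export
run_permutation_test <- function(dataset, paradigm,
                                 statistic = c("glm", "cca2d", "cca3d"),
                                 fwhm_mm = 8, ar_order = 4L, n_perm = 1000L,
                                 alpha = 0.05, seed = 1L,
                                 glm_whiten_each_perm = FALSE,
                                 exclude_nonwhite = FALSE,
                                 two_sided = FALSE,
                                 whiten_iters = 3L,
                                 ar_smooth_fwhm_mm = 8,
                                 plan = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(dataset, "fmri_dataset"))
  d <- dim(dataset$data)
  sdim <- d[1:3]
  nt <- d[4]
  mask <- dataset$mask
  mvec <- as.vector(mask)
  vs <- dataset$voxel_size

  if (is.null(plan)) plan <- make_plan(nt, n_perm, seed)
  if (plan$nt != nt) stopf("plan was built for nt = %d, data has %d", plan$nt, nt)
  np <- plan$np
  if (np < 1 / alpha) {
    warning(sprintf(
      "only %d permutations for alpha = %g: the threshold is the largest observed maximum",
      np, alpha), call. = FALSE)
  }

  design <- build_design(paradigm, nt, dataset$tr)
  X <- design$X
  contrast <- design$contrast
  P <- trend_basis(nt)

  # smoothing / filter-bank machinery, precomputed once
  kernel <- NULL
  smoother <- NULL
  bank <- NULL
  applier <- NULL
  if (statistic == "glm") {
    if (fwhm_mm > 0) {
      kernel <- gaussian_kernel(fwhm_mm, vs, dims = 3L)
      smoother <- make_smoother(kernel, mask)
    }
  } else {
    bank <- if (statistic == "cca2d") cca_filter_bank_2d(fwhm_mm, vs)
            else cca_filters_3d(fwhm_mm, vs)
    applier <- make_bank_applier(bank, mask)
  }

  M0 <- as_voxel_matrix(dataset$data)

  # -- original statistic map --------------------------------------------
  phi <- NULL
  if (statistic == "glm") {
    Ms <- if (is.null(smoother)) M0 else smoother(M0)
    Ms <- project_out_rows(Ms, P)
    Xs <- X
    if (glm_whiten_each_perm) {
      resid0 <- project_out_rows(Ms[mvec, , drop = FALSE], X)
      phi <- stats::median(autocorr_rows(resid0, 1L))
      Ms <- whiten_rows(Ms, matrix(phi, nrow(Ms), 1L))
      Xs <- t(whiten_rows(t(X), matrix(phi, ncol(X), 1L)))
    }
    stat_full <- numeric(length(mvec))
    stat_full[mvec] <- glm_tmap_rows(Ms[mvec, , drop = FALSE], Xs, contrast)
    perm_design <- Xs
  } else {
    Md <- project_out_rows(M0, P)
    stat_full <- as.vector(cca_map_rows(Md, sdim, mask, X, bank, applier))
    perm_design <- X
  }

  # -- residual data and accumulated whitening ---------------------------
  Mres <- project_out_rows(project_out_rows(M0, P), X)
  iw <- iterative_whiten(as_volume_series(Mres * mvec, sdim), mask,
                         p = ar_order, iters = whiten_iters,
                         fwhm_mm = if (ar_smooth_fwhm_mm > 0) ar_smooth_fwhm_mm else NULL,
                         voxel_size = vs)
  W <- as_voxel_matrix(iw$whitened)
  cmat <- ar_coef_matrix(iw$ar_field)

  analysis_mask <- mask
  if (exclude_nonwhite) {
    wm <- whiteness_map(as_volume_series(W, sdim), mask, p = ar_order,
                        smooth_fwhm_mm = if (ar_smooth_fwhm_mm > 0) ar_smooth_fwhm_mm else NULL,
                        voxel_size = vs)
    analysis_mask <- mask & !wm$flags
    if (!any(analysis_mask)) stopf("all voxels excluded as nonwhite")
  }
  avec <- as.vector(analysis_mask)

  # -- permutation loop --------------------------------------------------
  maxima <- numeric(np)
  for (i in seq_len(np)) {
    Wp <- W[, plan$indices[i, ], drop = FALSE]
    Yp <- inverse_whiten_rows(Wp, cmat)
    if (statistic == "glm") {
      if (!is.null(smoother)) Yp <- smoother(Yp)
      Yp <- project_out_rows(Yp, P)
      if (!is.null(phi)) Yp <- whiten_rows(Yp, matrix(phi, nrow(Yp), 1L))
      tv <- glm_tmap_rows(Yp[avec, , drop = FALSE], perm_design, contrast)
    } else {
      Yp <- project_out_rows(Yp, P)
      tv <- as.vector(cca_map_rows(Yp, sdim, analysis_mask, perm_design,
                                   bank, applier))[avec]
    }
    maxima[i] <- if (two_sided) max(abs(tv)) else max(tv)
  }

  null <- new_max_null(maxima, switch(statistic, glm = "GLM-t",
                                      cca2d = "CCA-2D", cca3d = "CCA-3D"), np)
  threshold <- null$maxima[threshold_index(alpha, np)]
  pfull <- rep(1, length(mvec))
  pfull[avec] <- corrected_pvalue(if (two_sided) abs(stat_full[avec]) else stat_full[avec],
                                  null$maxima)

  structure(list(
    stat_map = array(stat_full, dim = sdim),
    pmap = array(pfull, dim = sdim),
    threshold = threshold,
    alpha = alpha,
    null = null,
    analysis_mask = analysis_mask,
    design = design,
    ar_field = iw$ar_field,
    statistic = statistic,
    config = list(fwhm_mm = fwhm_mm, ar_order = ar_order, n_perm = np,
                  seed = plan$seed, glm_whiten_each_perm = glm_whiten_each_perm,
                  exclude_nonwhite = exclude_nonwhite, two_sided = two_sided,
                  whiten_iters = whiten_iters,
                  ar_smooth_fwhm_mm = ar_smooth_fwhm_mm,
                  voxel_size = vs, tr = dataset$tr, nt = nt),
    phi = phi
  ), class = "perm_test")
}

# Mask-aware Gaussian smoothing closure over a voxels-by-time matrix, with
# the normalized-convolution denominator cached.
make_smoother <- function(kernel, mask) {
  sdim <- dim(mask)
  mvec <- as.vector(array(as.numeric(mask), dim = sdim))
  den <- apply_kernel(array(mvec, dim = sdim), kernel)
  eps <- 1e-12 * max(den)
  den[den <= eps] <- Inf
  denv <- as.vector(den)
  function(M) {
    arr <- as_volume_series(M * mvec, sdim)
    out <- as_voxel_matrix(apply_kernel(arr, kernel)) / denv
    out * mvec
  }
}

#' @export
print.perm_test <- function(x, ...) {
  nsig <- sum(x$pmap[x$analysis_mask] < x$alpha)
  cat(sprintf("<perm_test> %s, %d permutations\n", x$null$statistic_label,
              x$null$np))
  cat(sprintf("  corrected threshold (alpha = %g): %.4f\n", x$alpha, x$threshold))
  cat(sprintf("  %d of %d voxels significant (corrected p < %g)\n",
              nsig, sum(x$analysis_mask), x$alpha))
  invisible(x)
}

#' @export
summary.perm_test <- function(object, ...) {
  x <- object
  out <- list(
    statistic = x$null$statistic_label,
    n_perm = x$null$np,
    alpha = x$alpha,
    threshold = x$threshold,
    n_voxels = sum(x$analysis_mask),
    n_significant = sum(x$pmap[x$analysis_mask] < x$alpha),
    max_stat = max(x$stat_map[x$analysis_mask]),
    min_corrected_p = min(x$pmap[x$analysis_mask])
  )
  if (x$statistic == "glm") {
    df <- x$config$nt - ncol(x$design$X)
    out$df <- df
    out$bonferroni <- bonferroni_threshold(x$alpha, out$n_voxels, df)$threshold
    out$rft <- tryCatch(
      suppressWarnings(rft_threshold(x$alpha, x$analysis_mask,
                                     max(x$config$fwhm_mm, x$config$voxel_size),
                                     x$config$voxel_size, df)),
      error = function(e) NA_real_)
  }
  structure(out, class = "summary.perm_test")
}

#' @export
print.summary.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s), %d permutations, alpha = %g\n",
              x$statistic, x$n_perm, x$alpha))
  cat(sprintf("  corrected threshold : %.4f\n", x$threshold))
  if (!is.null(x$bonferroni)) {
    cat(sprintf("  Bonferroni threshold: %.4f (df %d, %d voxels)\n",
                x$bonferroni, x$df, x$n_voxels))
    if (is.finite(x$rft)) cat(sprintf("  RFT threshold       : %.4f\n", x$rft))
  }
  cat(sprintf("  significant voxels  : %d of %d\n", x$n_significant, x$n_voxels))
  invisible(x)
}

#' Familywise-error calibration on pure white noise
#'
#' Validation experiment for the permutation machinery: with every
#' preprocessing step removed and Gaussian white noise as data, compute the
#' corrected max-t threshold by permutation on one noise dataset, then
#' generate fresh noise datasets and count how many contain any t-value
#' above it. For a correct threshold at level `alpha` the exceedance rate
#' is `alpha` (500 of 10,000 datasets at `alpha = 0.05`), within binomial
#' error.
#'
#' @param shape Grid size (all voxels in-mask).
#' @param nt Volumes per dataset.
#' @param n_perm Permutations for the threshold.
#' @param n_datasets Fresh noise datasets to threshold.
#' @param alpha Corrected level.
#' @param fwhm_mm Optional Gaussian smoothing applied to every dataset
#'   (0 = none).
#' @param paradigm Stimulus paradigm for the regressors (default 20 s
#'   on/off blocks filling the scan).
#' @param tr Repetition time in seconds.
#' @param seed Integer seed (threshold noise, plan and every fresh dataset
#'   derive independent seeds from it).
#' @param voxel_size Voxel size in mm (used only when smoothing).
#' @return List with `count`, `rate`, `expected`, `threshold`, `n_datasets`,
#'   `n_voxels`.
#' @export
fwe_calibration <- function(shape = c(20, 20, 10), nt = 80, n_perm = 10000,
                            n_datasets = 10000, alpha = 0.05, fwhm_mm = 0,
                            paradigm = NULL, tr = 2, seed = 1L,
                            voxel_size = c(3.75, 3.75, 3.75)) {
  shape <- as.integer(shape)
  nv <- prod(shape)
  if (is.null(paradigm)) {
    paradigm <- paradigm_block_design(20, 20, total_s = nt * tr)
  }
  design <- build_design(paradigm, nt, tr)
  X <- design$X
  seeds <- derive_seeds(seed, 3L)

  smoother <- NULL
  if (fwhm_mm > 0) {
    smoother <- make_smoother(gaussian_kernel(fwhm_mm, voxel_size, 3L),
                              array(TRUE, dim = shape))
  }
  draw <- function(s) {
    M <- with_seed(s, matrix(stats::rnorm(nv * nt), nrow = nv))
    if (!is.null(smoother)) M <- smoother(M)
    M
  }

  M <- draw(seeds[1])
  plan <- make_plan(nt, n_perm, seeds[2])
  maxima <- perm_max_t(M, X, plan)
  threshold <- sort(maxima)[threshold_index(alpha, n_perm)]

  ds_seeds <- derive_seeds(seeds[3], n_datasets)
  count <- 0L
  for (i in seq_len(n_datasets)) {
    if (max_t_fast(draw(ds_seeds[i]), X) > threshold) count <- count + 1L
  }
  list(count = count, rate = count / n_datasets,
       expected = alpha * n_datasets, threshold = threshold,
       n_datasets = n_datasets, n_perm = n_perm, n_voxels = nv)
}

# Max t over voxels for a raw (unpreprocessed) data matrix; X need not be
# orthonormal.
max_t_fast <- function(M, X) {
  max(glm_tmap_rows(M, X, c(1, numeric(ncol(X) - 1L))))
}

# Permutation maxima of the GLM t for raw exchangeable data: permuting the
# series is equivalent to inversely permuting the design rows, so only the
# small design matrix is shuffled per permutation.
perm_max_t <- function(M, X, plan) {
  vapply(seq_len(plan$np), function(i) {
    max_t_fast(M, X[order(plan$indices[i, ]), , drop = FALSE])
  }, numeric(1))
}

#' Sampling variability of the corrected threshold
#'
#' Repeats the permutation threshold computation on one fixed dataset with
#' independent permutation plans and returns the replicate thresholds. The
#' threshold's standard deviation shrinks like `1/sqrt(Np)`, so 10x more
#' permutations reduce it by sqrt(10).
#'
#' @param data Fixed voxels-by-time data matrix, or `NULL` to generate
#'   white noise of dimensions `prod(shape) x nt`.
#' @param shape,nt Grid used when generating data.
#' @param n_perm Permutations per replicate.
#' @param replicates Number of replicate thresholds.
#' @param alpha Corrected level.
#' @param paradigm,tr Design specification (defaults as in
#'   [fwe_calibration()]).
#' @param seed Integer seed.
#' @return List with `thresholds` (length `replicates`) and `sd`.
#' @export
threshold_variability <- function(data = NULL, shape = c(10, 10, 4), nt = 80,
                                  n_perm = 1000, replicates = 100,
                                  alpha = 0.05, paradigm = NULL, tr = 2,
                                  seed = 1L) {
  if (is.null(paradigm)) {
    paradigm <- paradigm_block_design(20, 20, total_s = nt * tr)
  }
  X <- build_design(paradigm, nt, tr)$X
  seeds <- derive_seeds(seed, replicates + 1L)
  if (is.null(data)) {
    data <- with_seed(seeds[replicates + 1L],
                      matrix(stats::rnorm(prod(shape) * nt), ncol = nt))
  }
  thresholds <- vapply(seq_len(replicates), function(r) {
    plan <- make_plan(nt, n_perm, seeds[r])
    sort(perm_max_t(data, X, plan))[threshold_index(alpha, n_perm)]
  }, numeric(1))
  list(thresholds = thresholds, sd = stats::sd(thresholds))
}
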