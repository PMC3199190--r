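# Canonical correlation analysis with temporal and spatial basis sets.
#
# All CCA routines work on detrended (zero-mean) inputs and therefore use
# raw second moments (crossprod / N) rather than mean-corrected covariances.

cca_covariances <- function(xt, ys, ridge_rel = 1e-10) {
  N <- nrow(xt)
  Cxx <- crossprod(xt) / N
  Cyy <- crossprod(ys) / N
  Cxy <- crossprod(xt, ys) / N
  diag(Cxx) <- diag(Cxx) + ridge_rel * sum(diag(Cxx)) / ncol(Cxx)
  diag(Cyy) <- diag(Cyy) + ridge_rel * sum(diag(Cyy)) / ncol(Cyy)
  list(Cxx = Cxx, Cyy = Cyy, Cxy = Cxy, N = N)
}

# All canonical pairs for (sub)covariances via the Cholesky/SVD reduction:
# with Cxx = Ux'Ux, Cyy = Uy'Uy, the singular values of Ux^-T Cxy Uy^-1 are
# the canonical correlations and beta = Ux^-1 u, gamma = Uy^-1 v.
cca_pairs <- function(Cxx, Cyy, Cxy) {
  Ux <- tryCatch(chol(Cxx), error = function(e) NULL)
  Uy <- tryCatch(chol(Cyy), error = function(e) NULL)
  if (is.null(Ux) || is.null(Uy)) return(NULL)
  A <- solve(t(Ux), Cxy)
  K <- t(solve(t(Uy), t(A)))
  sv <- svd(K)
  list(rho = pmin(sv$d, 1),
       beta = solve(Ux, sv$u),
       gamma = solve(Uy, sv$v))
}

#' Largest canonical correlation
#'
#' Maximizes `rho = b' Cxy g / sqrt(b' Cxx b g' Cyy g)` over weight vectors
#' `b` (temporal) and `g` (spatial). Weights are normalized in their
#' covariance metrics (`b'Cxx b = g'Cyy g = 1`) and oriented so the
#' correlation is positive. Covariance matrices get a relative ridge of
#' `1e-10 * trace/dim` before factorization.
#'
#' @param xt nt x n temporal basis matrix (zero-mean columns assumed).
#' @param ys nt x m spatially filtered data matrix.
#' @return A `cca_result`: list with `rho` in `[0, 1]`, `beta`, `gamma`,
#'   `restricted = FALSE`.
#' @export
cca_max <- function(xt, ys) {
  xt <- as.matrix(xt)
  ys <- as.matrix(ys)
  if (nrow(xt) != nrow(ys)) stopf("`xt` and `ys` must have the same number of rows")
  if (nrow(xt) <= ncol(xt) + ncol(ys)) {
    stopf("need more samples than combined basis dimensions")
  }
  cv <- cca_covariances(xt, ys)
  pr <- cca_pairs(cv$Cxx, cv$Cyy, cv$Cxy)
  if (is.null(pr)) stopf("degenerate covariance structure")
  new_cca_result(pr$rho[1], pr$beta[, 1], pr$gamma[, 1], FALSE)
}

new_cca_result <- function(rho, beta, gamma, restricted) {
  structure(list(rho = min(max(rho, 0), 1), beta = beta, gamma = gamma,
                 restricted = restricted),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result>%s rho = %.4f\n",
              if (x$restricted) " restricted," else "", x$rho))
  invisible(x)
}

#' Restricted canonical correlation (nonnegative spatial weights)
#'
#' Maximizes the canonical correlation subject to plausibility constraints:
#' the spatial weights must be elementwise nonnegative (so the implied
#' combined filter is a lowpass) and, optionally, the HRF temporal weight
#' must be nonnegative (non-inverted response). Solved exactly by
#' enumerating active-constraint faces: every face's canonical pairs are
#' computed on the reduced basis and the feasible pair with the largest
#' correlation wins (at most `2^m * 2` subproblems; cheap for m <= 4).
#'
#' @inheritParams cca_max
#' @param gamma_nonneg Constrain spatial weights `g >= 0` (default `TRUE`).
#' @param beta1_nonneg Constrain the first temporal weight `b_1 >= 0`
#'   (default `TRUE`).
#' @return A `cca_result` with `restricted = TRUE`; its `rho` never exceeds
#'   the unrestricted [cca_max()] value.
#' @export
restricted_cca_max <- function(xt, ys, gamma_nonneg = TRUE, beta1_nonneg = TRUE) {
  xt <- as.matrix(xt)
  ys <- as.matrix(ys)
  if (nrow(xt) != nrow(ys)) stopf("`xt` and `ys` must have the same number of rows")
  n <- ncol(xt)
  m <- ncol(ys)
  cv <- cca_covariances(xt, ys)

  beta_faces <- list(seq_len(n))
  if (beta1_nonneg && n > 1L) beta_faces <- c(beta_faces, list(2:n))
  gamma_faces <- if (gamma_nonneg) {
    unlist(lapply(seq_len(m), function(s) utils::combn(m, s, simplify = FALSE)),
           recursive = FALSE)
  } else {
    list(seq_len(m))
  }

  best <- NULL
  for (bf in beta_faces) {
    for (gf in gamma_faces) {
      pr <- cca_pairs(cv$Cxx[bf, bf, drop = FALSE],
                      cv$Cyy[gf, gf, drop = FALSE],
                      cv$Cxy[bf, gf, drop = FALSE])
      if (is.null(pr)) next
      for (i in seq_along(pr$rho)) {
        beta <- numeric(n); beta[bf] <- pr$beta[, i]
        gamma <- numeric(m); gamma[gf] <- pr$gamma[, i]
        for (sgn in c(1, -1)) {
          b <- sgn * beta; g <- sgn * gamma
          tol_g <- 1e-8 * max(abs(g), 1e-300)
          tol_b <- 1e-8 * max(abs(b), 1e-300)
          ok_g <- !gamma_nonneg || all(g >= -tol_g)
          ok_b <- !beta1_nonneg || b[1] >= -tol_b
          if (ok_g && ok_b && (is.null(best) || pr$rho[i] > best$rho)) {
            best <- list(rho = pr$rho[i], beta = b, gamma = g)
          }
        }
      }
    }
  }
  if (is.null(best)) stopf("no feasible nonzero spatial weights")
  new_cca_result(best$rho, best$beta, best$gamma, TRUE)
}

#' Joint null density of the canonical correlations
#'
#' Evaluates the unnormalized joint density
#' `f = prod_i (r_i^2)^((n-m-1)/2) (1-r_i^2)^((N-n-m-1)/2)
#'      prod_(j>i) (r_i^2 - r_j^2)`
#' for independent Gaussian variables of dimensions n and m observed over N
#' samples. The product measures the squared coefficients `r_i^2`; use
#' [cca_null_density_largest()] for a numerically normalized density of the
#' largest coefficient on the r scale.
#'
#' @param r Ordered canonical correlations `1 > r_1 > ... > r_m > 0`.
#' @param N Number of samples (> n + m).
#' @param n,m Dimensions of the two variables (`m = length(r)`).
#' @return Nonnegative density value.
#' @export
cca_null_density <- function(r, N, n, m = length(r)) {
  if (length(r) != m) stopf("`r` must have length m")
  if (any(r <= 0) || any(r >= 1)) stopf("r must lie strictly in (0, 1)")
  if (m > 1L && is.unsorted(rev(r), strictly = TRUE)) {
    stopf("r must be strictly decreasing")
  }
  if (N <= n + m) stopf("need N > n + m")
  r2 <- r^2
  f <- prod(r2^((n - m - 1) / 2) * (1 - r2)^((N - n - m - 1) / 2))
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      f <- f * prod(r2[i] - r2[(i + 1L):m])
    }
  }
  f
}

#' @rdname cca_null_density
#' @param r_grid Grid on (0, 1) at which to evaluate the marginal density of
#'   the largest coefficient (`m <= 2` supported).
#' @return `cca_null_density_largest()`: numerically normalized density
#'   values of `r_1` on `r_grid`.
#' @export
cca_null_density_largest <- function(r_grid, N, n, m = 1L) {
  if (!m %in% c(1L, 2L)) stopf("numerical normalization implemented for m <= 2")
  if (m == 1L) {
    g <- vapply(r_grid, function(r) cca_null_density(r, N, n, 1L) * 2 * r,
                numeric(1))
  } else {
    g <- vapply(r_grid, function(r1) {
      if (r1 <= 1e-8) return(0)
      r2s <- seq(1e-9, r1 - 1e-9, length.out = 256L)
      vals <- vapply(r2s, function(r2) {
        cca_null_density(c(r1, r2), N, n, 2L) * 4 * r1 * r2
      }, numeric(1))
      mean(vals) * (r1 - 2e-9)
    }, numeric(1))
  }
  # trapezoid normalization on the supplied grid
  z <- sum((g[-1] + g[-length(g)]) / 2 * diff(r_grid))
  g / z
}

#' Voxelwise (restricted) CCA activation map
#'
#' For every in-mask voxel, builds the spatial-side matrix by filtering each
#' volume with every kernel of the bank (mask-aware normalized convolution;
#' slicewise for 2-D banks) and sampling at the voxel, then solves the
#' restricted CCA against the temporal design. The bank IS the smoothing:
#' the input data must be unsmoothed.
#'
#' @param data An [fmri_dataset()] or 4-D array of detrended data.
#' @param design A `design_matrix` (or nt x n matrix).
#' @param bank A `filter_bank` from [cca_filter_bank_2d()] or
#'   [cca_filters_3d()].
#' @param mask 3-D logical array.
#' @param restricted Use the restricted solver (default `TRUE`).
#' @param keep_weights If `TRUE`, attach the per-voxel spatial weights as a
#'   4-D attribute `"gamma"` for inspecting the adaptive smoothing.
#' @return 3-D array of canonical correlations (0 outside the mask).
#' @export
cca_map <- function(data, design, bank, mask = NULL, restricted = TRUE,
                    keep_weights = FALSE) {
  if (inherits(data, "fmri_dataset")) {
    mask <- mask %||% data$mask
    data <- data$data
  }
  sdim <- spatial_dim(data)
  if (is.null(mask)) mask <- array(TRUE, dim = sdim)
  X <- if (inherits(design, "design_matrix")) design$X else design
  applier <- make_bank_applier(bank, mask)
  cca_map_rows(as_voxel_matrix(data), sdim, mask, X, bank, applier,
               restricted = restricted, keep_weights = keep_weights)
}

# Precompute the smoothed-certainty denominators and kernel FFTs for a
# bank; returns a function mapping a voxels-by-time matrix to a list of
# filtered in-mask matrices (normalized convolution with the mask as
# certainty). The data volume is Fourier-transformed once and shared by all
# kernels of the bank.
make_bank_applier <- function(bank, mask) {
  sdim <- dim(mask)
  mvec <- as.vector(array(as.numeric(mask), dim = sdim))
  inm <- as.vector(mask)
  # Certainty denominators: for a zero-sum (derivative-type) kernel the own
  # smoothed certainty is ~0 and sign-indefinite, so it shares the
  # denominator of the bank's first (lowpass) kernel - consistent with
  # normalizing the combined filter g + w dg by the lowpass certainty and
  # preserving the sign of the nonnegativity constraint.
  den_of <- function(k) {
    den <- apply_kernel(array(mvec, dim = sdim), k)
    eps <- 1e-12 * max(den)
    den[den <= eps] <- Inf
    as.vector(den)[inm]
  }
  den1 <- den_of(bank$kernels[[1]])
  dens <- lapply(bank$kernels, function(k) {
    if (identical(k$kind, "derivative")) den1 else den_of(k)
  })
  nd <- if (bank$dims == 2L) 2L else 3L
  rad <- (dim(bank$kernels[[1]]$kernel) - 1L) %/% 2L
  P <- fft_pad_sizes(sdim, rad)
  kfs <- lapply(bank$kernels, function(k) kernel_fft(k$kernel, P))
  function(M) {
    arr <- as_volume_series(M * mvec, sdim)
    Fd <- fft_pad_forward(arr, P, nd)
    lapply(seq_along(kfs), function(i) {
      num <- as_voxel_matrix(fft_filter_crop(Fd, kfs[[i]], nd, sdim, dim(arr)))
      num[inm, , drop = FALSE] / dens[[i]]
    })
  }
}

# Core map computation on a full voxels-by-time matrix.
cca_map_rows <- function(Mfull, sdim, mask, X, bank, applier,
                         restricted = TRUE, keep_weights = FALSE) {
  inm <- as.vector(mask)
  nt <- ncol(Mfull)
  n <- ncol(X)
  mdim <- length(bank$kernels)
  Ys <- applier(Mfull)
  V <- sum(inm)

  Cxx <- crossprod(X) / nt
  Cxy <- matrix(0, n * mdim, V)
  for (f in seq_len(mdim)) {
    Cxy[seq.int((f - 1L) * n + 1L, f * n), ] <- t(Ys[[f]] %*% X) / nt
  }
  Cyy <- matrix(0, mdim * mdim, V)
  for (f in seq_len(mdim)) {
    for (g in f:mdim) {
      v <- rowSums(Ys[[f]] * Ys[[g]]) / nt
      Cyy[(g - 1L) * mdim + f, ] <- v
      Cyy[(f - 1L) * mdim + g, ] <- v
    }
  }

  res <- rcca_solve_cpp(Cxx, Cxy, Cyy,
                        gamma_nonneg = restricted,
                        beta1_nonneg = restricted,
                        ridge_rel = 1e-10)
  rho <- numeric(length(inm))
  rho[inm] <- res[1, ]
  out <- array(rho, dim = sdim)
  if (keep_weights) {
    gm <- matrix(0, length(inm), mdim)
    gm[inm, ] <- t(res[(1 + n + 1):(1 + n + mdim), , drop = FALSE])
    attr(out, "gamma") <- array(gm, dim = c(sdim, mdim))
  }
  out
}
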