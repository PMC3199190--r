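test_that("GLM t-statistic matches the normal-equations oracle", {
  set.seed(1)
  X <- cbind(rnorm(80), rnorm(80))
  y <- rnorm(80)
  cc <- c(1, 0)
  f <- glm_tstat(y, X, cc)
  bh <- solve(crossprod(X), crossprod(X, y))
  s2 <- sum((y - X %*% bh)^2) / 78
  t_or <- drop(crossprod(cc, bh)) / sqrt(s2 * drop(t(cc) %*% solve(crossprod(X)) %*% cc))
  expect_equal(f$tvalue, t_or, tolerance = 1e-10)
  expect_equal(f$beta_hat, drop(bh), tolerance = 1e-10)

  # orthogonal series -> t = 0
  X2 <- std_design()$X
  yp <- drop(y - X2 %*% crossprod(X2, y))
  expect_equal(glm_tstat(yp, X2, cc)$tvalue, 0, tolerance = 1e-10)

  # positive scale invariance
  expect_equal(glm_tstat(3.7 * y, X, cc)$tvalue, f$tvalue, tolerance = 1e-10)

  # exact fit flags an infinite sentinel
  ex <- glm_tstat(2 * X[, 1], X, cc)
  expect_true(ex$flagged)
  expect_true(is.infinite(ex$tvalue))
  expect_error(glm_tstat(y, cbind(X[, 1], X[, 1]), cc), "rank")
})

test_that("the vectorized t-map equals the per-voxel computation", {
  set.seed(2)
  sdim <- c(5, 5, 2)
  arr <- array(rnorm(prod(sdim) * 80), dim = c(sdim, 80))
  dsn <- std_design()
  tm <- glm_tmap(arr, dsn)
  M <- matrix(arr, ncol = 80)
  for (v in sample(prod(sdim), 10)) {
    expect_equal(tm[v], glm_tstat(M[v, ], dsn)$tvalue, tolerance = 1e-10)
  }
})

test_that("AR(1) prewhitening decorrelates residuals and preserves exact fits", {
  expect_equal(prewhiten_glm(array(rnorm(4 * 4 * 2 * 30), c(4, 4, 2, 30)),
                             std_design(30)$X, phi = 0)$phi, 0)

  spec <- synthetic_spec(shape = c(10, 10, 1), nt = 2000, ar_coeffs = 0.4, seed = 3)
  arr <- generate_synthetic(spec)$dataset$data
  dsn <- std_design(2000)
  pw <- prewhiten_glm(arr, dsn)
  expect_equal(pw$phi, 0.4, tolerance = 0.05)
  Mw <- matrix(pw$data, ncol = 2000)
  r1 <- permfmri:::autocorr_rows(Mw, 1L)
  expect_lt(abs(mean(r1)), 0.03)

  # noiseless signal: whitening both sides preserves beta exactly
  X <- std_design(60)$X
  beta <- c(2, -1)
  y <- drop(X %*% beta)
  arr1 <- array(y, dim = c(1, 1, 1, 60))
  pw2 <- prewhiten_glm(arr1, X, phi = 0.5)
  yh <- drop(pw2$data)
  bh <- solve(crossprod(pw2$design), crossprod(pw2$design, yh))
  expect_equal(unname(drop(bh)), beta, tolerance = 1e-10)
  expect_error(prewhiten_glm(arr1, X, phi = 1.2), "stationary")
})

test_that("CCA reduces to Pearson correlation and detects exact relations", {
  set.seed(4)
  x <- rnorm(50)
  y <- 0.3 * x + rnorm(50)
  expect_equal(cca_max(x, y)$rho,
               abs(sum(x * y) / sqrt(sum(x^2) * sum(y^2))), tolerance = 1e-6)

  xt <- matrix(rnorm(50 * 2), 50)
  A <- matrix(c(1, 2, -1, 0.5), 2)
  expect_equal(cca_max(xt, xt %*% A)$rho, 1, tolerance = 1e-6)
})

test_that("CCA matches the dense grid-search oracle and is reparameterization invariant", {
  set.seed(5)
  for (rep in 1:3) {
    xt <- matrix(rnorm(60 * 2), 60)
    ys <- matrix(rnorm(60 * 2), 60)
    r <- cca_max(xt, ys)
    expect_equal(r$rho, oracle_cca_grid(xt, ys), tolerance = 1e-3)
    A <- matrix(rnorm(4), 2); while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2)
    B <- matrix(rnorm(4), 2); while (abs(det(B)) < 0.1) B <- matrix(rnorm(4), 2)
    expect_equal(cca_max(xt %*% A, ys %*% B)$rho, r$rho, tolerance = 1e-8)
  }
})

test_that("restricted CCA never exceeds the unrestricted optimum and matches the orthant grid", {
  set.seed(6)
  X <- std_design(50)$X
  for (rep in 1:4) {
    ys <- matrix(rnorm(50 * 3), 50)
    unr <- cca_max(X, ys)
    res <- restricted_cca_max(X, ys)
    expect_lte(res$rho, unr$rho + 1e-10)
    expect_true(all(res$gamma >= -1e-8 * max(abs(res$gamma))))
    expect_gte(res$beta[1], -1e-8 * max(abs(res$beta)))
    expect_equal(res$rho, oracle_rcca_grid(X, ys), tolerance = 1e-3)
  }
  # inactive constraints: data built so the unconstrained optimum is feasible
  g0 <- c(0.8, 0.5, 0.2)
  ys <- drop(X %*% c(1, 0)) %o% g0 + 0.05 * matrix(rnorm(50 * 3), 50)
  unr <- cca_max(X, ys)
  feasible <- (all(unr$gamma >= 0) && unr$beta[1] >= 0) ||
              (all(unr$gamma <= 0) && unr$beta[1] <= 0)
  expect_true(feasible)
  expect_equal(restricted_cca_max(X, ys)$rho, unr$rho, tolerance = 1e-10)
})

test_that("the compiled map solver equals the per-voxel reference", {
  set.seed(7)
  sdim <- c(6, 6, 2)
  nt <- 40
  arr <- array(rnorm(prod(sdim) * nt), dim = c(sdim, nt))
  mask <- array(TRUE, sdim)
  dsn <- std_design(nt)
  for (bank in list(cca_filter_bank_2d(8, c(3.75, 3.75, 3.75)),
                    cca_filters_3d(8, c(3.75, 3.75, 3.75)))) {
    map <- cca_map(arr, dsn, bank, mask)
    # zero-sum (derivative) kernels share the lowpass kernel's certainty
    # denominator, mirroring the applier's normalization
    den1 <- permfmri:::apply_kernel(array(1, sdim), bank$kernels[[1]])
    dens <- lapply(bank$kernels, function(k) {
      if (identical(k$kind, "derivative")) den1
      else permfmri:::apply_kernel(array(1, sdim), k)
    })
    Ys <- lapply(seq_along(bank$kernels), function(i) {
      permfmri:::apply_kernel(arr, bank$kernels[[i]]) / as.vector(dens[[i]])
    })
    for (v in sample(prod(sdim), 8)) {
      ys <- sapply(Ys, function(Y) matrix(Y, prod(sdim))[v, ])
      expect_equal(map[v], restricted_cca_max(dsn$X, ys)$rho, tolerance = 1e-9)
    }
  }
})

test_that("single-filter CCA squared equals the GLM coefficient of determination", {
  set.seed(8)
  sdim <- c(6, 6, 1)
  nt <- 60
  arr <- array(rnorm(prod(sdim) * nt), dim = c(sdim, nt))
  dsn <- std_design(nt)
  k <- gaussian_kernel(6, c(3.75, 3.75, 3.75), dims = 2)
  sm <- smooth_dataset(arr, array(TRUE, sdim), k)
  M <- matrix(sm, ncol = nt)
  for (v in seq_len(prod(sdim))) {
    y <- M[v, ]
    rho <- restricted_cca_max(dsn$X, matrix(y, ncol = 1),
                              beta1_nonneg = FALSE)$rho
    R2 <- sum(crossprod(dsn$X, y)^2) / sum(y^2)
    expect_equal(rho^2, R2, tolerance = 1e-8)
  }
})

test_that("the canonical-correlation null density is valid on its domain", {
  expect_gte(cca_null_density(0.5, N = 80, n = 2, m = 1), 0)
  expect_gte(cca_null_density(c(0.6, 0.3), N = 80, n = 2, m = 2), 0)
  # boundary decay when N - n - m - 1 > 0
  expect_lt(cca_null_density(1 - 1e-9, N = 80, n = 2, m = 1),
            cca_null_density(0.2, N = 80, n = 2, m = 1) * 1e-6)
  expect_error(cca_null_density(c(0.3, 0.6), N = 80, n = 2, m = 2), "decreasing")
  expect_error(cca_null_density(1.2, N = 80, n = 2, m = 1), "in \\(0, 1\\)")
  expect_error(cca_null_density(0.5, N = 3, n = 2, m = 1), "N > n")
  g <- cca_null_density_largest(seq(1e-3, 0.999, length.out = 512), N = 80, n = 2)
  expect_true(all(g >= 0))
})
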