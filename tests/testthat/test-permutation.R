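test_that("the exact permutation count is correct", {
  expect_equal(unclass(count_permutations(1)), "1")
  expect_equal(unclass(count_permutations(5)), "120")
  expect_equal(unclass(count_permutations(12)), "479001600")
  # 80!: 119 digits
  s <- count_permutations(80)
  expect_equal(nchar(unclass(s)), 119)
})

test_that("permutation plans are seeded bijections shared by all voxels", {
  p1 <- make_plan(20, 50, seed = 42)
  p2 <- make_plan(20, 50, seed = 42)
  expect_identical(p1$indices, p2$indices)
  expect_false(identical(p1$indices, make_plan(20, 50, seed = 43)$indices))
  for (i in seq_len(50)) {
    expect_identical(sort(p1$indices[i, ]), 1:20)
  }
})

test_that("the threshold index reproduces the sorted-position convention", {
  expect_equal(permfmri:::threshold_index(0.05, 10000), 9500L)
  expect_equal(permfmri:::threshold_index(0.05, 1000), 950L)
  expect_equal(permfmri:::threshold_index(0.1, 10), 9L)
  expect_equal(permfmri:::threshold_index(0.03, 1000), 970L)
})

test_that("corrected p-values count ties and take values on the 1/Np grid", {
  mx <- c(1, 2, 3, 4)
  expect_equal(corrected_pvalue(2.5, mx), 0.5)
  expect_equal(corrected_pvalue(10, mx), 0)
  expect_equal(corrected_pvalue(0.5, mx), 1)
  expect_equal(corrected_pvalue(2, mx), 0.75)   # >= counts the tie
  set.seed(1)
  mx2 <- rnorm(200)
  p <- corrected_pvalue(rnorm(500), mx2)
  expect_true(all(p %in% ((0:200) / 200)))
  expect_equal(min(p[p > 0]), 1 / 200)
  # oracle: direct counting
  tv <- rnorm(50)
  expect_equal(corrected_pvalue(tv, mx2),
               vapply(tv, function(t) mean(mx2 >= t), numeric(1)))
})

test_that("Bonferroni correction divides the level by the test count", {
  b <- bonferroni_threshold(0.05, 20000, 78)
  expect_equal(b$per_comparison, 2.5e-6)
  expect_equal(bonferroni_threshold(0.05, 1, 78)$threshold,
               qt(0.95, 78), tolerance = 1e-12)
  expect_equal(round(bonferroni_threshold(0.05, 1, 78)$threshold, 2), 1.66)
})

test_that("RFT thresholds match an independent Euler-characteristic computation", {
  mask <- array(TRUE, c(10, 10, 6))
  vs <- c(3, 3, 3); df <- 78
  thr <- rft_threshold(0.05, mask, 6, vs, df)
  # independent: closed-form solid-box resel counts + textbook EC densities
  rx <- 3 / 6
  R <- c(1, (9 + 9 + 5) * rx, (9 * 9 + 9 * 5 + 9 * 5) * rx^2, 9 * 9 * 5 * rx^3)
  l2 <- 4 * log(2)
  rho <- function(t, d) {
    f <- (1 + t^2 / df)^(-(df - 1) / 2)
    switch(d + 1,
           pt(t, df, lower.tail = FALSE),
           sqrt(l2) / (2 * pi) * f,
           l2 / (2 * pi)^1.5 * gamma((df + 1) / 2) / (sqrt(df / 2) * gamma(df / 2)) * t * f,
           l2^1.5 / (2 * pi)^2 * f * ((df - 1) / df * t^2 - 1))
  }
  oracle <- uniroot(function(t) sum(sapply(0:3, function(d) R[d + 1] * rho(t, d))) - 0.05,
                    c(2, 20), tol = 1e-12)$root
  expect_equal(thr, oracle, tolerance = 1e-6)

  # more smoothing -> fewer resels -> lower threshold; never below uncorrected
  expect_lte(rft_threshold(0.05, mask, 9, vs, df), thr)
  expect_gte(thr, qt(0.95, df))
  expect_warning(rft_threshold(0.05, mask, 1, vs, df), "below one voxel")
})

test_that("relative p-value sd follows the square-root law", {
  expect_equal(round(100 * relative_sd_pvalue(0.01, 1000), 2), 31.46)
  expect_equal(round(100 * relative_sd_pvalue(0.01, 10000), 2), 9.95)
  expect_equal(relative_sd_pvalue(0.05, 1000) / relative_sd_pvalue(0.05, 100000),
               10, tolerance = 1e-12)
  expect_error(relative_sd_pvalue(0, 100), "strictly")
})

test_that("design-permutation shortcut equals literally permuting the data", {
  set.seed(2)
  nt <- 30
  M <- matrix(rnorm(50 * nt), 50, nt)
  X <- std_design(nt)$X
  plan <- make_plan(nt, 20, seed = 3)
  fast <- permfmri:::perm_max_t(M, X, plan)
  direct <- vapply(seq_len(20), function(i) {
    permfmri:::max_t_fast(M[, plan$indices[i, ]], X)
  }, numeric(1))
  expect_equal(fast, direct, tolerance = 1e-10)
})

test_that("threshold variability shrinks like one over sqrt(Np)", {
  tv_small <- threshold_variability(shape = c(5, 5, 2), nt = 40, n_perm = 100,
                                    replicates = 60, seed = 4)
  tv_big <- threshold_variability(shape = c(5, 5, 2), nt = 40, n_perm = 1000,
                                  replicates = 60, seed = 4)
  expect_true(all(is.finite(tv_small$thresholds)) && all(tv_small$thresholds > 0))
  ratio <- tv_small$sd / tv_big$sd
  expect_gt(ratio, sqrt(10) / 1.8)
  expect_lt(ratio, sqrt(10) * 1.8)
  # replicate thresholds roughly symmetric: modest skewness
  z <- scale(tv_big$thresholds)
  expect_lt(abs(mean(z^3)), 1.0)
})

test_that("white-noise FWE calibration is near nominal at reduced scale", {
  res <- fwe_calibration(shape = c(8, 8, 4), nt = 40, n_perm = 500,
                         n_datasets = 400, alpha = 0.5, seed = 5)
  # alpha = 0.5 sanity run: generous binomial band (sd ~ 0.025)
  expect_gt(res$rate, 0.4)
  expect_lt(res$rate, 0.6)
})
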