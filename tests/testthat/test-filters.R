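test_that("Gaussian kernels are normalized with the requested width", {
  k <- gaussian_kernel(8, c(3.75, 3.75, 3.75), dims = 3)
  expect_equal(sum(k$kernel), 1, tolerance = 1e-12)
  expect_true(all(k$kernel >= 0))
  # sigma = fwhm / sqrt(8 ln 2): 8 mm at 3.75 mm voxels ~ 0.906 voxels
  sig <- 8 / sqrt(8 * log(2)) / 3.75
  expect_equal(sig, 0.906, tolerance = 1e-3)

  # measured FWHM of a densely sampled kernel matches the request
  kf <- gaussian_kernel(8, c(0.25, 0.25, 0.25), dims = 2)
  prof <- kf$sep[[1]]
  x <- (seq_along(prof) - (length(prof) + 1) / 2) * 0.25
  half <- max(prof) / 2
  above <- range(x[prof >= half])
  expect_equal(diff(above), 8, tolerance = 0.25 / 2 + 0.26)

  expect_error(gaussian_kernel(0.01, c(3.75, 3.75, 3.75)), "0.1 voxel")
  expect_error(gaussian_kernel(-2), "positive")
})

test_that("separable application equals full-kernel convolution", {
  set.seed(1)
  arr <- array(rnorm(9 * 9 * 5), dim = c(9, 9, 5))
  k <- gaussian_kernel(7, c(3, 3, 3), dims = 3)
  sep <- permfmri:::apply_kernel(arr, k)
  kfull <- k
  kfull$sep <- NULL
  full <- permfmri:::apply_kernel(arr, kfull)
  expect_equal(sep, full, tolerance = 1e-10)
})

test_that("FFT filtering agrees with direct shift-add convolution", {
  set.seed(2)
  sdim <- c(7, 8, 3)
  arr <- array(rnorm(prod(sdim) * 4), dim = c(sdim, 4))
  bank <- cca_filter_bank_2d(8, c(3.75, 3.75, 3.75))
  mask <- array(TRUE, sdim)
  applier <- permfmri:::make_bank_applier(bank, mask)
  got <- applier(permfmri:::as_voxel_matrix(arr))
  for (i in seq_along(bank$kernels)) {
    den <- permfmri:::apply_kernel(array(1, sdim), bank$kernels[[i]])
    ref <- permfmri:::apply_kernel(arr, bank$kernels[[i]]) / as.vector(den)
    expect_equal(got[[i]], permfmri:::as_voxel_matrix(ref), tolerance = 1e-12)
  }
})

test_that("mask-aware smoothing ignores data outside the mask", {
  set.seed(3)
  sdim <- c(8, 8, 3)
  mask <- array(FALSE, sdim)
  mask[3:6, 3:6, 2] <- TRUE
  arr1 <- array(rnorm(prod(sdim) * 3), dim = c(sdim, 3))
  arr2 <- arr1
  arr2[!array(mask, dim = c(sdim, 3))[, , , 1]] <- 99  # garbage outside mask
  for (t in 1:3) {
    a <- arr1[, , , t]; a[!mask] <- 99; arr2[, , , t] <- a
  }
  k <- gaussian_kernel(8, c(3.75, 3.75, 3.75), dims = 3)
  s1 <- smooth_dataset(arr1, mask, k)
  s2 <- smooth_dataset(arr2, mask, k)
  expect_equal(s1[array(mask, dim = c(sdim, 3))], s2[array(mask, dim = c(sdim, 3))],
               tolerance = 1e-12)
  expect_true(all(s1[!array(mask, dim = c(sdim, 3))] == 0))

  # delta kernel: identity inside the mask
  d <- smooth_dataset(arr1, mask, delta_kernel(3))
  for (t in 1:3) {
    expect_equal(d[, , , t][mask], arr1[, , , t][mask], tolerance = 1e-12)
  }

  # constant volumes unchanged inside the mask
  const <- array(3.3, dim = c(sdim, 2))
  sc <- smooth_dataset(const, mask, k)
  expect_equal(sc[array(mask, dim = c(sdim, 2))],
               rep(3.3, 2 * sum(mask)), tolerance = 1e-12)
})

test_that("small smoothing oracle: explicit weighted average on toy data", {
  set.seed(4)
  sdim <- c(6, 6, 1)
  arr <- array(rnorm(prod(sdim) * 3), dim = c(sdim, 3))
  mask <- array(TRUE, sdim)
  mask[1, 1, 1] <- FALSE
  k <- gaussian_kernel(6, c(3, 3, 3), dims = 3)
  got <- smooth_dataset(arr, mask, k)
  for (t in 1:3) {
    or <- oracle_normalized_convolve(array(arr[, , , t], sdim),
                                     array(as.numeric(mask), sdim), k$kernel)
    or[!mask] <- 0
    expect_equal(array(got[, , , t], sdim), or, tolerance = 1e-10)
  }
})

test_that("the 2D CCA bank has the documented structure", {
  bank <- cca_filter_bank_2d(8, c(1, 1, 1))
  expect_length(bank$kernels, 4)
  expect_equal(bank$labels, c("small", "aniso0", "aniso60", "aniso120"))
  for (k in bank$kernels) {
    expect_true(all(k$kernel >= 0))
    expect_equal(sum(k$kernel), 1, tolerance = 1e-12)
  }
  # weights (1,0,0,0): the small isotropic lowpass
  expect_equal(combine_bank(bank, c(1, 0, 0, 0)), bank$kernels[[1]]$kernel)
  # rotating the anisotropic weight pattern rotates the filter: equal energy
  e <- vapply(bank$kernels[2:4], function(k) sum(k$kernel^2), numeric(1))
  expect_lt(max(abs(e - mean(e))), 1e-6 * mean(e))
})

test_that("equal weights on the 2D bank give the design-size isotropic filter", {
  fwhm <- 8
  bank <- cca_filter_bank_2d(fwhm, c(1, 1, 1))
  K <- combine_bank(bank, rep(0.25, 4))
  n <- nrow(K)
  ix <- seq_len(n) - (n + 1) / 2
  d2 <- outer(ix^2, ix^2, `+`)
  fit <- function(sig) {
    G <- exp(-d2 / (2 * sig^2)); G <- G / sum(G)
    sum((G - K)^2)
  }
  sig_best <- optimize(fit, c(0.5, 10))$minimum
  sig_target <- fwhm / sqrt(8 * log(2))
  expect_equal(sig_best, sig_target, tolerance = 0.05)
  # the orientation set {0, 60, 120} is closed under reflection about both
  # axes, so the equal-weight sum is symmetric under either flip
  expect_equal(K, K[n:1, ], tolerance = 1e-10)
  expect_equal(K, K[, n:1], tolerance = 1e-10)
})

test_that("the 3D scale-adaptive pair behaves like a Gaussian and its width derivative", {
  bank <- cca_filters_3d(8, c(2, 2, 2))
  expect_length(bank$kernels, 2)
  g <- bank$kernels[[1]]$kernel
  dg <- bank$kernels[[2]]$kernel
  expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_lt(abs(sum(dg)), 1e-3)

  # first-order Taylor: g + eps dg/dsigma has best-fit width ~ sigma0 + eps
  sig0 <- 8 / (2 * sqrt(8 * log(2)))
  n <- dim(g)[1]
  ix <- (seq_len(n) - (n + 1) / 2) * 2   # mm
  r2 <- outer(outer(ix^2, ix^2, `+`), ix^2, `+`)
  fitw <- function(K) {
    optimize(function(s) {
      G <- exp(-r2 / (2 * s^2)); G <- G / sum(G)
      sum((G - K / sum(K))^2)
    }, c(0.4, 8))$minimum
  }
  expect_equal(fitw(g), sig0, tolerance = 0.01)
  eps <- 0.1
  expect_equal(fitw(g + eps * dg), sig0 + eps, tolerance = 0.03)
})
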