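# The max-statistic random permutation engine.

#' Exact permutation count
#'
#' Number of distinct orderings of `nt` time points, computed exactly in
#' arbitrary precision (for 80 samples the count is ~7.16e118, which is why
#' complete permutation tests are infeasible and a random subset is drawn).
#'
#' @param nt Number of time samples (>= 1).
#' @return The exact value of `nt!` as a decimal digit string of class
#'   `bigint`.
#' @export
count_permutations <- function(nt) {
  nt <- as.integer(nt)
  if (nt < 1L) stopf("`nt` must be >= 1")
  base <- 10000L
  d <- 1L  # little-endian base-1e4 limbs
  for (k in seq_len(nt)) {
    d <- d * k
    carry <- 0
    for (i in seq_along(d)) {
      v <- d[i] + carry
      d[i] <- v %% base
      carry <- v %/% base
    }
    while (carry > 0) {
      d <- c(d, carry %% base)
      carry <- carry %/% base
    }
  }
  digits <- paste0(
    d[length(d)],
    paste(sprintf("%04d", rev(d[-length(d)])), collapse = "")
  )
  structure(digits, class = "bigint")
}

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.bigint <- function(x, digits = 3, ...) {
  s <- unclass(x)
  expo <- nchar(s) - 1L
  mant <- as.numeric(paste0(substr(s, 1, 1), ".", substr(s, 2, min(nchar(s), 16))))
  mant <- signif(mant, digits)
  if (expo < 7) s else sprintf("%.*ge+%d", digits, mant, expo)
}

#' Random permutation plan
#'
#' An `Np x Nt` matrix whose rows are independent uniform permutations of
#' `1..Nt`; the same row is applied to all voxel series of a permutation so
#' spatial correlation is preserved while temporal structure is destroyed.
#' The identity permutation is not excluded (its probability is
#' negligible).
#'
#' @param nt Number of time points (>= 2).
#' @param np Number of permutations (>= 1).
#' @param seed Integer seed; identical seeds give identical plans.
#' @return A `permutation_plan`: list with `indices` (Np x Nt integer
#'   matrix), `np`, `nt`, `seed`.
#' @export
make_plan <- function(nt, np, seed) {
  nt <- as.integer(nt)
  np <- as.integer(np)
  if (nt < 2L) stopf("`nt` must be >= 2")
  if (np < 1L) stopf("`np` must be >= 1")
  idx <- with_seed(seed, {
    t(vapply(seq_len(np), function(i) sample.int(nt), integer(nt)))
  })
  structure(list(indices = idx, np = np, nt = nt, seed = as.integer(seed)),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat(sprintf("<permutation_plan> %d permutations of %d time points (seed %d)\n",
              x$np, x$nt, x$seed))
  invisible(x)
}

# 1-based index into the ascending sorted maxima for a corrected level
# alpha; reproduces position 9500 for Np = 10000, alpha = 0.05. The small
# epsilon guards against floating-point roundup when (1-alpha)*np is an
# exact integer.
threshold_index <- function(alpha, np) {
  i <- as.integer(ceiling((1 - alpha) * np - 1e-9))
  as.integer(min(max(i, 1L), np))
}

new_max_null <- function(maxima, label, np) {
  structure(list(maxima = sort(maxima), statistic_label = label, np = np),
            class = "max_null_distribution")
}

#' @export
print.max_null_distribution <- function(x, ...) {
  cat(sprintf("<max_null_distribution> %s, %d permutations; median %.4g, max %.4g\n",
              x$statistic_label, x$np, stats::median(x$maxima), max(x$maxima)))
  invisible(x)
}

#' Corrected p-value from the maximum-statistic null distribution
#'
#' `p = #( max_i >= t ) / Np`: the fraction of permutation maxima at least
#' as large as the observed statistic (ties count). Values are multiples of
#' `1/Np`; the smallest observable nonzero p is `1/Np`.
#'
#' @param t_voxel Observed statistic(s) (vectorized).
#' @param maxima Numeric vector of permutation maxima, or a
#'   `max_null_distribution`.
#' @return Corrected p-value(s) in `[0, 1]`.
#' @export
corrected_pvalue <- function(t_voxel, maxima) {
  if (inherits(maxima, "max_null_distribution")) maxima <- maxima$maxima
  np <- length(maxima)
  srt <- sort(maxima)
  n_below <- findInterval(t_voxel, srt, left.open = TRUE)
  (np - n_below) / np
}

#' Bonferroni-corrected t threshold
#'
#' Divides the familywise level by the number of tests: each voxel is
#' tested at `alpha / n_voxels`, and the threshold is the corresponding
#' upper Student-t quantile. Exact for independent tests; conservative when
#' smoothing correlates neighbouring voxels.
#'
#' @param alpha Familywise error level.
#' @param n_voxels Number of tests (brain voxels).
#' @param df Degrees of freedom (typically `nt - k`).
#' @return List with `threshold` and `per_comparison` (= `alpha/n_voxels`).
#' @export
bonferroni_threshold <- function(alpha, n_voxels, df) {
  if (n_voxels < 1L) stopf("`n_voxels` must be >= 1")
  rate <- alpha / n_voxels
  list(threshold = stats::qt(1 - rate, df = df), per_comparison = rate)
}

# Lattice resolution-element (resel) counts of a mask: counts of in-mask
# points, edges, faces and cubes combined by inclusion-exclusion so a solid
# box gives R0 = 1, R1 = sum of box edges, etc., in FWHM units.
resel_counts <- function(mask, voxel_size, fwhm_mm) {
  m <- array(as.logical(mask), dim = dim(mask))
  d <- dim(m)
  fw <- rep(as.numeric(fwhm_mm), length.out = 3L)
  vs <- rep(as.numeric(voxel_size), length.out = 3L)
  r <- vs / fw
  sub <- function(keep1, keep2, keep3) m[keep1, keep2, keep3, drop = FALSE]
  a1 <- seq_len(d[1] - 1L); b1 <- a1 + 1L
  a2 <- seq_len(d[2] - 1L); b2 <- a2 + 1L
  a3 <- seq_len(d[3] - 1L); b3 <- a3 + 1L
  P <- sum(m)
  Ex <- if (d[1] > 1) sum(sub(a1, TRUE, TRUE) & sub(b1, TRUE, TRUE)) else 0
  Ey <- if (d[2] > 1) sum(sub(TRUE, a2, TRUE) & sub(TRUE, b2, TRUE)) else 0
  Ez <- if (d[3] > 1) sum(sub(TRUE, TRUE, a3) & sub(TRUE, TRUE, b3)) else 0
  Fxy <- if (d[1] > 1 && d[2] > 1) {
    sum(sub(a1, a2, TRUE) & sub(b1, a2, TRUE) & sub(a1, b2, TRUE) & sub(b1, b2, TRUE))
  } else 0
  Fxz <- if (d[1] > 1 && d[3] > 1) {
    sum(sub(a1, TRUE, a3) & sub(b1, TRUE, a3) & sub(a1, TRUE, b3) & sub(b1, TRUE, b3))
  } else 0
  Fyz <- if (d[2] > 1 && d[3] > 1) {
    sum(sub(TRUE, a2, a3) & sub(TRUE, b2, a3) & sub(TRUE, a2, b3) & sub(TRUE, b2, b3))
  } else 0
  C <- if (all(d > 1)) {
    sum(sub(a1, a2, a3) & sub(b1, a2, a3) & sub(a1, b2, a3) & sub(b1, b2, a3) &
        sub(a1, a2, b3) & sub(b1, a2, b3) & sub(a1, b2, b3) & sub(b1, b2, b3))
  } else 0
  c(R0 = P - Ex - Ey - Ez + Fxy + Fxz + Fyz - C,
    R1 = (Ex - Fxy - Fxz + C) * r[1] + (Ey - Fxy - Fyz + C) * r[2] +
         (Ez - Fxz - Fyz + C) * r[3],
    R2 = (Fxy - C) * r[1] * r[2] + (Fxz - C) * r[1] * r[3] +
         (Fyz - C) * r[2] * r[3],
    R3 = C * r[1] * r[2] * r[3])
}

# Euler-characteristic densities of a t-field with df degrees of freedom.
ec_density_t <- function(t, df, d) {
  f <- (1 + t^2 / df)^(-(df - 1) / 2)
  l2 <- 4 * log(2)
  switch(as.character(d),
    "0" = stats::pt(t, df = df, lower.tail = FALSE),
    "1" = sqrt(l2) / (2 * pi) * f,
    "2" = l2 / (2 * pi)^(3 / 2) *
      exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df / 2) * t * f,
    "3" = l2^(3 / 2) / (2 * pi)^2 * f * ((df - 1) / df * t^2 - 1),
    stopf("d must be 0..3"))
}

#' Random-field-theory corrected t threshold
#'
#' Solves `alpha = sum_d R_d rho_d(t)` for `t`, where `R_d` are the mask's
#' resolution-element counts at the given smoothness and `rho_d` the
#' Euler-characteristic densities of a t-field. Provided for comparison
#' with the permutation threshold only; its validity requires the statistic
#' field to be sufficiently smooth.
#'
#' @param alpha Familywise error level.
#' @param mask 3-D logical array.
#' @param fwhm_mm Estimated smoothness (scalar or per-axis FWHM, mm).
#' @param voxel_size Voxel size in mm.
#' @param df Degrees of freedom of the t statistic.
#' @return The corrected threshold (a warning is issued when the smoothness
#'   is below one voxel and the continuous-field approximation is suspect).
#' @export
rft_threshold <- function(alpha, mask, fwhm_mm, voxel_size, df) {
  fw <- rep(as.numeric(fwhm_mm), length.out = 3L)
  if (any(fw <= 0)) stopf("`fwhm_mm` must be positive")
  vs <- rep(as.numeric(voxel_size), length.out = 3L)
  if (any(fw < vs)) {
    warning("smoothness below one voxel: random-field assumptions are violated",
            call. = FALSE)
  }
  R <- resel_counts(mask, vs, fw)
  expected_ec <- function(t) {
    sum(vapply(0:3, function(d) R[d + 1L] * ec_density_t(t, df, d), numeric(1)))
  }
  lo <- stats::qt(1 - alpha, df = df)
  hi <- 100
  if (expected_ec(lo) < alpha) return(lo)
  stats::uniroot(function(t) expected_ec(t) - alpha, c(lo, hi),
                 tol = 1e-10)$root
}

#' Relative standard deviation of a permutation p-value
#'
#' The one-sided p estimated from `Np` permutations has standard deviation
#' ~ `sqrt(p(1-p)/Np)`; this returns it relative to `p` (so 0.3146 means a
#' 31.46% relative sd, and scaling `Np` by 100 scales the relative sd by
#' 1/10).
#'
#' @param p Desired p-value in (0, 1).
#' @param np Number of permutations.
#' @return Relative standard deviation (fraction of `p`).
#' @export
relative_sd_pvalue <- function(p, np) {
  if (any(p <= 0 | p >= 1)) stopf("`p` must lie strictly in (0, 1)")
  if (any(np < 1)) stopf("`np` must be >= 1")
  sqrt(p * (1 - p) / np) / p
}
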