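# Base-graphics displays for the result objects.

#' Histogram of the maximum-statistic null distribution
#'
#' @param x A `max_null_distribution`.
#' @param alpha Level at which to mark the corrected threshold.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further arguments to [graphics::hist()].
#' @export
plot.max_null_distribution <- function(x, alpha = 0.05, breaks = 50, ...) {
  graphics::hist(x$maxima, breaks = breaks, freq = FALSE,
                 main = sprintf("Null distribution of max %s (%d permutations)",
                                x$statistic_label, x$np),
                 xlab = sprintf("maximum %s", x$statistic_label), ...)
  thr <- x$maxima[threshold_index(alpha, x$np)]
  graphics::abline(v = thr, lwd = 2)
  graphics::mtext(sprintf("corrected P = %g threshold: %.3f", alpha, thr),
                  side = 3, line = 0, cex = 0.8)
  invisible(x)
}

#' Axial slice of a statistic or p map
#'
#' @param map 3-D array (e.g. `stat_map` or `1 - pmap` of a `perm_test`).
#' @param z Slice index (default: middle slice).
#' @param mask Optional 3-D mask; out-of-mask voxels are blanked.
#' @param ... Passed to [graphics::image()].
#' @export
plot_stat_slice <- function(map, z = NULL, mask = NULL, ...) {
  z <- z %||% ceiling(dim(map)[3] / 2)
  sl <- map[, , z]
  if (!is.null(mask)) sl[!mask[, , z]] <- NA
  graphics::image(sl, useRaster = TRUE, asp = dim(map)[2] / dim(map)[1],
                  main = sprintf("slice z = %d", z), ...)
  invisible(map)
}

#' @rdname plot.max_null_distribution
#' @export
plot.perm_test <- function(x, alpha = x$alpha, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$null, alpha = alpha, ...)
  plot_stat_slice(x$stat_map, mask = x$analysis_mask)
  invisible(x)
}

#' Write permutation-test results to disk
#'
#' Writes the statistic map, the corrected p map and the `1 - p` map as
#' NIfTI, the sorted maxima as CSV, and a JSON summary (threshold, alpha,
#' permutation count, seed and - for the GLM - Bonferroni and RFT
#' comparison thresholds).
#'
#' @param x A `perm_test`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_perm_test <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- x$config$voxel_size
  write_fmri(x$stat_map, file.path(dir, "stat.nii.gz"), voxel_size = vs)
  write_fmri(x$pmap, file.path(dir, "p_corrected.nii.gz"), voxel_size = vs)
  write_fmri(1 - x$pmap, file.path(dir, "one_minus_p.nii.gz"), voxel_size = vs)
  utils::write.csv(data.frame(maximum = x$null$maxima),
                   file.path(dir, "max_null.csv"), row.names = FALSE)
  s <- summary(x)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(s), file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(data.frame(field = names(s),
                                value = vapply(s, function(v) paste(format(v), collapse = ";"), "")),
                     file.path(dir, "summary.csv"), row.names = FALSE)
  }
  invisible(dir)
}
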