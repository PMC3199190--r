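#' Block stimulus paradigm
#'
#' A paradigm is either a list of `(onset, duration)` blocks in seconds or a
#' per-volume 0/1 indicator vector. Blocks must have nonnegative, strictly
#' increasing onsets and must not overlap.
#'
#' @param onsets Numeric vector of block onsets in seconds.
#' @param durations Numeric vector of block durations in seconds (recycled if
#'   scalar).
#' @return An object of class `paradigm`.
#' @export
paradigm_blocks <- function(onsets, durations) {
  onsets <- as.numeric(onsets)
  durations <- as.numeric(rep(durations, length.out = length(onsets)))
  if (length(onsets) == 0L) stopf("paradigm needs at least one block")
  if (any(onsets < 0)) stopf("block onsets must be nonnegative")
  if (is.unsorted(onsets, strictly = TRUE)) {
    stopf("block onsets must be strictly increasing")
  }
  if (any(durations <= 0)) stopf("block durations must be positive")
  ends <- onsets + durations
  if (any(ends[-length(ends)] > onsets[-1])) stopf("blocks overlap")
  structure(list(onsets = onsets, durations = durations, indicator = NULL),
            class = "paradigm")
}

#' @rdname paradigm_blocks
#' @param indicator Per-volume 0/1 vector.
#' @export
paradigm_indicator <- function(indicator) {
  indicator <- as.numeric(indicator)
  if (!all(indicator %in% c(0, 1))) stopf("indicator must contain only 0 and 1")
  structure(list(onsets = NULL, durations = NULL, indicator = indicator),
            class = "paradigm")
}

#' Standard periodic on/off block paradigm
#'
#' @param on_s,off_s Activity and rest durations in seconds (defaults 20/20,
#'   the block lengths of a typical motor/language acquisition).
#' @param total_s Experiment length in seconds.
#' @param first What the run starts with, `"off"` (rest first, default) or
#'   `"on"`.
#' @return A `paradigm`.
#' @export
paradigm_block_design <- function(on_s = 20, off_s = 20, total_s = 160,
                                  first = c("off", "on")) {
  first <- match.arg(first)
  start <- if (first == "off") off_s else 0
  onsets <- seq(start, total_s - on_s, by = on_s + off_s)
  paradigm_blocks(onsets, on_s)
}

#' Read a paradigm from file
#'
#' Accepts either a TSV with header columns `onset` and `duration` (seconds)
#' or a one-column file of per-volume 0/1 values.
#'
#' @param path Path to the paradigm file.
#' @return A `paradigm`.
#' @export
read_paradigm <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("onset", first, ignore.case = TRUE)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    names(tab) <- tolower(names(tab))
    if (!all(c("onset", "duration") %in% names(tab))) {
      stopf("paradigm TSV must have 'onset' and 'duration' columns")
    }
    paradigm_blocks(tab$onset, tab$duration)
  } else {
    v <- utils::read.table(path, header = FALSE)[[1]]
    paradigm_indicator(v)
  }
}

#' Per-volume indicator of a paradigm
#'
#' Samples the paradigm at volume acquisition times `(t-1)*tr`,
#' `t = 1..nt`; a volume is "on" when its acquisition time falls inside a
#' block.
#'
#' @param x A `paradigm`.
#' @param nt Number of volumes.
#' @param tr Repetition time in seconds.
#' @return Numeric 0/1 vector of length `nt`.
#' @export
paradigm_indicator_vector <- function(x, nt, tr) {
  if (!inherits(x, "paradigm")) stopf("`x` must be a paradigm")
  if (!is.null(x$indicator)) {
    if (length(x$indicator) != nt) {
      stopf("indicator length %d does not match nt = %d", length(x$indicator), nt)
    }
    return(x$indicator)
  }
  ends <- x$onsets + x$durations
  if (any(ends > nt * tr + 1e-9)) {
    stopf("paradigm blocks extend past the end of the scan (%g s)", nt * tr)
  }
  times <- (seq_len(nt) - 1) * tr
  ind <- numeric(nt)
  for (b in seq_along(x$onsets)) {
    ind[times >= x$onsets[b] - 1e-9 & times < ends[b] - 1e-9] <- 1
  }
  ind
}

#' @export
print.paradigm <- function(x, ...) {
  if (is.null(x$indicator)) {
    cat(sprintf("<paradigm> %d blocks; onsets %s s\n", length(x$onsets),
                paste(utils::head(x$onsets, 5), collapse = ", ")))
  } else {
    cat(sprintf("<paradigm> per-volume indicator, %d volumes, %d on\n",
                length(x$indicator), sum(x$indicator)))
  }
  invisible(x)
}
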