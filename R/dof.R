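#' Initial peak-trough range of a ladder profile
#'
#' Measures the contrast of the first full line pair: the first peak
#' that rises by at least `min_prominence` above what precedes it
#' (excluding a clipped partial peak at the line start), minus its
#' adjacent trough. The failure threshold (`range_check`) is half this
#' range.
#'
#' @param extrema An [extrema_sequence][detect_extrema] from a ladder
#'   profile.
#' @param profile_start Intensity at the first profile sample, used to
#'   qualify a leading peak that has no preceding trough.
#' @param min_prominence Minimum rise qualifying a full peak.
#' @return List with `initial_range`, `range_check`
#'   (= `initial_range / 2`) and `first_pair` (extrema-row indices of
#'   the qualifying peak and trough).
#' @export
initial_range <- function(extrema, profile_start = NULL, min_prominence = 5) {
  n <- nrow(extrema)
  if (n < 2) stop("too few extrema for a ladder analysis; redraw the line")
  limit <- min(3L, n - 1L)
  for (j in seq_len(limit)) {
    if (extrema$kind[j] != "peak") next
    ref <- if (j == 1) {
      if (is.null(profile_start)) -Inf else profile_start
    } else {
      extrema$value[j - 1]
    }
    if (extrema$value[j] - ref < min_prominence) next
    if (j + 1 > n || extrema$kind[j + 1] != "trough") next
    ir <- extrema$value[j] - extrema$value[j + 1]
    if (ir <= 0) stop("degenerate profile: first peak does not exceed first trough")
    return(list(initial_range = ir, range_check = ir / 2,
                first_pair = c(peak = j, trough = j + 1)))
  }
  stop("no qualifying full peak in the first extrema; redraw the line so it starts on a full line pair")
}

# Peak-trough pairs from the first full peak on: each peak pairs with
# its immediately following trough; a trailing unpaired peak is ignored.
ladder_pairs <- function(extrema, first_peak) {
  peak_rows <- which(extrema$kind == "peak")
  peak_rows <- peak_rows[peak_rows >= first_peak]
  peak_rows <- peak_rows[peak_rows + 1 <= nrow(extrema)]
  if (length(peak_rows) == 0) {
    return(data.frame(peak_row = integer(0), trough_row = integer(0),
                      diff = numeric(0)))
  }
  data.frame(peak_row = peak_rows, trough_row = peak_rows + 1,
             diff = extrema$value[peak_rows] - extrema$value[peak_rows + 1])
}

#' Find the validated contrast failure point
#'
#' Scans consecutive peak/trough pairs for the first whose range falls
#' below `range_check`; the candidate is confirmed only if the
#' following `validation_window` pairs (or all remaining pairs, when
#' fewer are left) are also below the threshold, which screens out
#' single-pair anomalies. Otherwise scanning continues past the
#' anomaly.
#'
#' @param pairs Pair table from the ladder (internal; produced by
#'   [analyze_dof()]).
#' @param range_check Failure threshold (half the initial range).
#' @param validation_window Number of subsequent pairs that must also
#'   fail (default 20).
#' @return 1-based index into `pairs` of the validated failure, or
#'   `NA` when none is found.
#' @export
find_failure <- function(pairs, range_check, validation_window = 20L) {
  stopifnot(range_check > 0, validation_window >= 0)
  m <- nrow(pairs)
  k <- 1L
  while (k <= m) {
    if (pairs$diff[k] < range_check) {
      upto <- min(m, k + validation_window)
      follow <- pairs$diff[seq_len(upto - k) + k]
      if (all(follow < range_check)) return(k)
    }
    k <- k + 1L
  }
  NA_integer_
}

#' Depth of field from a ladder profile
#'
#' Runs the complete depth-of-field rule on an image of a line ladder:
#' profile along the user's line, extrema, initial range, validated
#' failure search, then DOF = peaks before the failure divided by the
#' ladder frequency (5 lp/mm by default, so peaks/5 gives mm). When no
#' failure is found the reported DOF is a lower bound.
#'
#' @param image Ladder image (matrix or RGB array, 0--255).
#' @param line A [line_segment()] down the ladder.
#' @param lp_per_mm Ladder line-pair frequency (default 5).
#' @param validation_window Pairs that must confirm a failure
#'   (default 20).
#' @param min_prominence Extrema prominence floor.
#' @return A `dof_result`: `initial_range`, `range_check`,
#'   `failure_pair_index` (`NA` if none), `peaks_before_failure`,
#'   `dof_mm`, `status` (`"failed_at"` or `"no_failure_found"`), plus
#'   profile/extrema/pair tables for audit.
#' @export
analyze_dof <- function(image, line, lp_per_mm = 5, validation_window = 20L,
                        min_prominence = 5) {
  profile <- sample_profile(image, line)
  extrema <- detect_extrema(profile, min_prominence)
  ir <- initial_range(extrema, profile_start = profile$values[1],
                      min_prominence = min_prominence)
  pairs <- ladder_pairs(extrema, ir$first_pair[["peak"]])
  fail <- find_failure(pairs, ir$range_check, validation_window)

  peak_rows <- which(extrema$kind == "peak")
  peak_rows <- peak_rows[peak_rows >= ir$first_pair[["peak"]]]
  if (is.na(fail)) {
    n_peaks <- length(peak_rows)
    status <- "no_failure_found"
  } else {
    n_peaks <- sum(peak_rows < pairs$peak_row[fail])
    status <- "failed_at"
  }
  structure(list(initial_range = ir$initial_range,
                 range_check = ir$range_check,
                 failure_pair_index = fail,
                 peaks_before_failure = n_peaks,
                 dof_mm = n_peaks / lp_per_mm,
                 lp_per_mm = lp_per_mm,
                 status = status,
                 validation_window = as.integer(validation_window),
                 profile = profile, extrema = extrema, pairs = pairs),
            class = "dof_result")
}

#' @export
print.dof_result <- function(x, ...) {
  cat("<dof_result>\n")
  cat(sprintf("  initial range %.1f, range check %.1f\n",
              x$initial_range, x$range_check))
  if (x$status == "failed_at") {
    cat(sprintf("  failure at pair %d; %d peaks before -> DOF %.2f mm\n",
                x$failure_pair_index, x$peaks_before_failure, x$dof_mm))
  } else {
    cat(sprintf("  no failure found; DOF >= %.2f mm (lower bound, %d peaks)\n",
                x$dof_mm, x$peaks_before_failure))
  }
  invisible(x)
}
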