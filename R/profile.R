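#' Define a profile line
#'
#' A straight line between two real-valued endpoints in 0-based
#' (row, col) pixel coordinates, with an optional perpendicular
#' averaging width, along which pixel intensity is sampled.
#'
#' @param p0,p1 Length-2 numeric `(row, col)` endpoints.
#' @param width_px Odd positive integer; intensities are averaged over
#'   this many 1-px-spaced perpendicular offsets (default 1, i.e. the
#'   bare line).
#' @return A `line_segment`.
#' @export
line_segment <- function(p0, p1, width_px = 1L) {
  stopifnot(length(p0) == 2, length(p1) == 2, width_px >= 1)
  if (all(p0 == p1)) stop("zero-length line: p0 equals p1")
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1),
                 width_px = as.integer(width_px)),
            class = "line_segment")
}

#' Sample an intensity profile along a line
#'
#' Replicates the classic "plot profile" operation: intensity is
#' sampled at 1-px arc-length steps along the line by bilinear
#' interpolation, averaged across `width_px` perpendicular offsets.
#' RGB images are converted to luminance first.
#'
#' @param image Matrix or RGB array, 0--255.
#' @param line A [line_segment()]; both endpoints must lie inside the
#'   image.
#' @return An `intensity_profile`: list with `distances` (arc length,
#'   px), `values` (0--255) and the source `line`.
#' @export
sample_profile <- function(image, line) {
  stopifnot(inherits(line, "line_segment"))
  img <- to_luminance(image)
  h <- nrow(img); w <- ncol(img)
  for (p in list(line$p0, line$p1)) {
    if (p[1] < 0 || p[1] > h - 1 || p[2] < 0 || p[2] > w - 1) {
      stop(sprintf("line endpoint (%.1f, %.1f) outside image bounds %d x %d",
                   p[1], p[2], h, w))
    }
  }
  d <- line$p1 - line$p0
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length line")
  u <- d / len                              # unit along-line vector
  perp <- c(-u[2], u[1])                    # unit perpendicular
  # both endpoints sampled; step is len/round(len), i.e. 1 px up to the
  # fractional remainder, so reversing the line reverses the samples
  n_seg <- max(1, round(len))
  t <- seq(0, n_seg) * (len / n_seg)
  offs <- seq_len(line$width_px) - (line$width_px + 1) / 2

  acc <- numeric(length(t))
  for (o in offs) {
    rr <- line$p0[1] + t * u[1] + o * perp[1]
    cc <- line$p0[2] + t * u[2] + o * perp[2]
    acc <- acc + bilinear_sample(img, rr, cc)
  }
  structure(list(distances = t, values = acc / length(offs), line = line),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples, range [%.1f, %.1f]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.intensity_profile <- function(x, ...) {
  data.frame(distance = x$distances, value = x$values)
}

#' Extract alternating peaks and troughs from a profile
#'
#' Finds local maxima and minima (plateaus contribute their center
#' sample), then repeatedly removes the adjacent extremum pair with the
#' smallest intensity swing until every remaining swing is at least
#' `min_prominence`, which both de-noises the sequence and guarantees
#' strict peak/trough alternation.
#'
#' @param profile An [intensity_profile][sample_profile].
#' @param min_prominence Minimum peak-to-trough swing, in gray levels,
#'   for an extremum to survive (default 5).
#' @return An `extrema_sequence`: data frame with columns `index`
#'   (1-based index into the profile), `distance`, `value`, `kind`
#'   (`"peak"`/`"trough"`). Empty when the profile has no qualifying
#'   extrema.
#' @export
detect_extrema <- function(profile, min_prominence = 5) {
  stopifnot(inherits(profile, "intensity_profile"), min_prominence >= 0)
  v <- profile$values
  n <- length(v)
  if (n < 3) return(empty_extrema(profile))

  # local extrema with plateau handling: compare each run of equal
  # values against its non-equal neighbours
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  idx <- integer(0); kind <- character(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      prev <- r$values[j - 1]; cur <- r$values[j]; nxt <- r$values[j + 1]
      center <- floor((starts[j] + ends[j]) / 2)
      if (cur > prev && cur > nxt) {
        idx <- c(idx, center); kind <- c(kind, "peak")
      } else if (cur < prev && cur < nxt) {
        idx <- c(idx, center); kind <- c(kind, "trough")
      }
    }
  }
  if (length(idx) == 0) return(empty_extrema(profile))

  # prune smallest swings below the prominence floor; removal is
  # pairwise so alternation is preserved
  val <- v[idx]
  repeat {
    if (length(idx) == 0) break
    swings <- abs(diff(val))
    # swing of the boundary extrema against the profile ends
    lead_s <- abs(val[1] - v[1])
    tail_s <- abs(val[length(val)] - v[n])
    cand <- c(lead_s, swings, tail_s)
    m <- which.min(cand)
    if (cand[m] >= min_prominence) break
    if (m == 1) {
      idx <- idx[-1]; val <- val[-1]; kind <- kind[-1]
    } else if (m == length(cand)) {
      idx <- idx[-length(idx)]; val <- val[-length(val)]
      kind <- kind[-length(kind)]
    } else {
      keep <- setdiff(seq_along(idx), c(m - 1, m))
      idx <- idx[keep]; val <- val[keep]; kind <- kind[keep]
    }
    # removing a boundary extremum can leave a same-kind run; keep the
    # more extreme member
    fix <- enforce_alternation(idx, val, kind)
    idx <- fix$idx; val <- fix$val; kind <- fix$kind
  }

  structure(data.frame(index = idx, distance = profile$distances[idx],
                       value = val, kind = kind,
                       stringsAsFactors = FALSE),
            class = c("extrema_sequence", "data.frame"))
}

enforce_alternation <- function(idx, val, kind) {
  repeat {
    same <- which(kind[-1] == kind[-length(kind)])
    if (length(same) == 0) break
    j <- same[1]
    better_first <- if (kind[j] == "peak") val[j] >= val[j + 1] else
      val[j] <= val[j + 1]
    drop <- if (better_first) j + 1 else j
    idx <- idx[-drop]; val <- val[-drop]; kind <- kind[-drop]
  }
  list(idx = idx, val = val, kind = kind)
}

empty_extrema <- function(profile) {
  structure(data.frame(index = integer(0), distance = numeric(0),
                       value = numeric(0), kind = character(0),
                       stringsAsFactors = FALSE),
            class = c("extrema_sequence", "data.frame"))
}

#' @export
print.extrema_sequence <- function(x, ...) {
  cat(sprintf("<extrema_sequence> %d peaks, %d troughs\n",
              sum(x$kind == "peak"), sum(x$kind == "trough")))
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10))
  invisible(x)
}
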