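#' Six distortion landmark points
#'
#' The left-most, middle and right-most points on the outer top and
#' bottom lines of an imaged grid chart, in 0-based (row, col) pixel
#' coordinates.
#'
#' @param top_left,top_mid,top_right,bottom_left,bottom_mid,bottom_right
#'   Length-2 `(row, col)` coordinates.
#' @return A `six_points` matrix (6 x 2, named rows).
#' @export
six_points <- function(top_left, top_mid, top_right,
                       bottom_left, bottom_mid, bottom_right) {
  pts <- rbind(top_left = top_left, top_mid = top_mid, top_right = top_right,
               bottom_left = bottom_left, bottom_mid = bottom_mid,
               bottom_right = bottom_right)
  stopifnot(ncol(pts) == 2, !anyNA(pts))
  colnames(pts) <- c("row", "col")
  if (!all(pts[1:3, "row"] < pts[4:6, "row"])) {
    stop("top points must lie above bottom points")
  }
  for (rows in list(1:3, 4:6)) {
    cc <- pts[rows, "col"]
    if (!(cc[1] < cc[2] && cc[2] < cc[3])) {
      stop("points must be ordered left < mid < right in column")
    }
  }
  structure(pts, class = c("six_points", "matrix"))
}

#' Vertical extents A1, B, A2 from the six landmarks
#'
#' Euclidean pixel distances between vertically paired landmarks:
#' `A1` between the left pair, `B` between the middle pair, `A2`
#' between the right pair.
#'
#' @param points A [six_points()] set (a plain named 6 x 2 matrix also
#'   works).
#' @return Named numeric vector `c(A1, B, A2)`.
#' @export
side_lengths <- function(points) {
  d <- function(a, b) sqrt(sum((points[a, ] - points[b, ])^2))
  out <- c(A1 = d("top_left", "bottom_left"),
           B = d("top_mid", "bottom_mid"),
           A2 = d("top_right", "bottom_right"))
  if (any(out == 0)) stop("coincident landmark pair gives a zero side length")
  out
}

#' Signed SMIA TV distortion
#'
#' `A = (A1 + A2) / 2`; percent distortion `= 100 (A - B) / B`.
#' Negative for barrel distortion (outer sides pulled toward the
#' center), positive for pincushion.
#'
#' @param A1,A2 Outer vertical extents in pixels.
#' @param B Central vertical extent in pixels.
#' @return A `distortion_result`: `A1`, `A2`, `B`, `A`, `percent`,
#'   `percent_magnitude`.
#' @export
smia_tv <- function(A1, A2, B) {
  stopifnot(A1 > 0, A2 > 0)
  if (B <= 0) stop("central extent B must be positive")
  A <- (A1 + A2) / 2
  pct <- 100 * (A - B) / B
  structure(list(A1 = A1, A2 = A2, B = B, A = A,
                 percent = pct, percent_magnitude = abs(pct)),
            class = "distortion_result")
}

#' Refine landmark points against the image
#'
#' Snaps each supplied point to the sub-pixel center of the dark grid
#' line(s) near it, reducing click/rounding error. Each coordinate is
#' estimated independently as the darkness-weighted centroid along its
#' axis, ignoring an exclusion band around the crossing line so that
#' line intersections (crosses, corners, T-junctions) do not bias the
#' estimate. Off by default in [analyze_distortion()], which by design
#' uses the user's raw points.
#'
#' @param image Grid image (matrix or RGB array, 0--255).
#' @param points A [six_points()] set.
#' @param window Half-width of the square search window in pixels.
#' @param exclude Half-width of the band around the crossing line to
#'   ignore; should be at least half the grid line width plus 1 px.
#' @return Refined `six_points`.
#' @export
snap_points <- function(image, points, window = 5L, exclude = 2L) {
  img <- to_luminance(image)
  out <- unclass(points)
  for (i in seq_len(nrow(points))) {
    p <- out[i, ]
    for (pass in 1:3) p <- snap_axiswise(img, p, window, exclude)
    out[i, ] <- p
  }
  structure(out, class = c("six_points", "matrix"))
}

snap_axiswise <- function(img, p, window, exclude) {
  h <- nrow(img); w <- ncol(img)
  r <- round(p[1]); c <- round(p[2])
  rr <- max(0, r - window):min(h - 1, r + window)
  cc <- max(0, c - window):min(w - 1, c + window)
  dark <- 255 - img[rr + 1, cc + 1, drop = FALSE]
  new_r <- p[1]; new_c <- p[2]
  keep_c <- abs(cc - c) > exclude
  if (any(keep_c)) {
    wt <- rowSums(dark[, keep_c, drop = FALSE])
    if (sum(wt) > 0) new_r <- sum(wt * rr) / sum(wt)
  }
  keep_r <- abs(rr - r) > exclude
  if (any(keep_r)) {
    wt <- colSums(dark[keep_r, , drop = FALSE])
    if (sum(wt) > 0) new_c <- sum(wt * cc) / sum(wt)
  }
  c(new_r, new_c)
}

#' SMIA TV distortion from landmark points on an image
#'
#' @param image Grid chart image.
#' @param points A [six_points()] set (user-selected).
#' @param snap If `TRUE`, refine the points with [snap_points()] first.
#' @param window Snap window half-width.
#' @return A [distortion_result][smia_tv] with the (possibly refined)
#'   points attached.
#' @export
analyze_distortion <- function(image, points, snap = FALSE, window = 5L) {
  if (snap) points <- snap_points(image, points, window)
  s <- side_lengths(points)
  res <- smia_tv(s[["A1"]], s[["A2"]], s[["B"]])
  res$points <- points
  res
}

#' @export
print.distortion_result <- function(x, ...) {
  cat(sprintf("<distortion_result> A1 %.2f, B %.2f, A2 %.2f px -> %+.3f%% SMIA TV\n",
              x$A1, x$B, x$A2, x$percent))
  invisible(x)
}
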