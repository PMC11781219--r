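# Pixel coordinate convention (used package-wide): 0-based (row, col),
# pixel centers at integer coordinates, pixel i covering [i-0.5, i+0.5).

# Fraction of each of n pixels covered by the interval [a, b), measured
# on a 4x supersampled lattice so edges are anti-aliased reproducibly.
coverage1d <- function(n, a, b, ss = 4L) {
  t <- (seq_len(n * ss) - 0.5) / ss - 0.5
  inside <- t >= a & t < b
  colMeans(matrix(inside, nrow = ss))
}

#' Render an idealized test chart with ground truth
#'
#' Rasterizes a [chart spec][usaf_chart] into an 8-bit image (grayscale
#' matrix for usaf/grid/dof charts, RGB array for colour charts) using
#' 4x supersampled anti-aliasing, and returns alongside it a
#' machine-readable record of what the image truly contains: bar
#' positions and contrasts, distortion landmark coordinates, patch
#' CIELAB values, or the analytic contrast-failure position.
#'
#' @param spec A `chart_spec` from [usaf_chart()], [grid_chart()],
#'   [colorchecker_chart()] or [dof_ladder()].
#' @return List with elements `image` (0--255 integer raster) and
#'   `truth` (a `lapqc_truth` list).
#' @export
render_chart <- function(spec) {
  stopifnot(inherits(spec, "chart_spec"))
  out <- switch(spec$kind,
    usaf = render_usaf(spec),
    grid = render_grid(spec),
    colorchecker = render_colorchecker(spec),
    dof_ladder = render_dof_ladder(spec),
    stop("unknown chart kind: ", spec$kind)
  )
  out$image <- quantize8(out$image)
  out$truth$width_px <- ncol(out$image)
  out$truth$height_px <- nrow(out$image)
  class(out$truth) <- "lapqc_truth"
  out
}

render_usaf <- function(spec) {
  ppm <- spec$px_per_mm
  freq <- usaf_frequency(spec$group, spec$elements)
  bar_w <- 0.5 / freq                      # bar width in mm
  n_el <- length(spec$elements)

  y <- spec$margin_mm
  bar_rows <- vector("list", n_el)
  for (i in seq_len(n_el)) {
    w <- bar_w[i]
    bar_rows[[i]] <- lapply(0:2, function(k) c(y + 2 * k * w, y + (2 * k + 1) * w))
    y <- y + 5 * w + 2 * w                 # 3 bars + inter-element gap
  }
  total_h <- y - 2 * bar_w[n_el] + spec$margin_mm
  height <- ceiling(total_h * ppm)
  width <- ceiling((spec$bar_length_mm + 2 * spec$margin_mm) * ppm)

  white <- spec$white_level
  bar_level <- ifelse(is.finite(spec$contrast), white / spec$contrast, 0)
  c0 <- spec$margin_mm * ppm
  c1 <- (spec$margin_mm + spec$bar_length_mm) * ppm
  cov_c <- coverage1d(width, c0, c1)

  img <- matrix(white, height, width)
  for (i in seq_len(n_el)) {
    for (bar in bar_rows[[i]]) {
      cov_r <- coverage1d(height, bar[1] * ppm, bar[2] * ppm)
      img <- pmin(img, white - (white - bar_level[i]) * outer(cov_r, cov_c))
    }
  }

  elements <- data.frame(
    group = spec$group,
    element = spec$elements,
    frequency_lp_mm = freq,
    line_width_um = 500 / freq,
    contrast = spec$contrast,
    bar_level = bar_level,
    white_level = white
  )
  truth <- list(
    kind = "usaf", spec = spec, degradation = NULL,
    elements = elements,
    bar_rows_px = lapply(bar_rows, function(el) lapply(el, function(b) b * ppm)),
    suggested_line = list(p0 = c(0, (width - 1) / 2),
                          p1 = c(height - 1, (width - 1) / 2))
  )
  list(image = img, truth = truth)
}

render_grid <- function(spec) {
  ppm <- spec$px_per_mm
  lw_mm <- spec$line_width_px / ppm
  extent <- spec$n_cells * spec$spacing_mm
  m <- spec$margin_mm
  size <- ceiling((extent + 2 * m) * ppm)
  pos_mm <- m + spec$spacing_mm * (0:spec$n_cells)

  img <- matrix(255, size, size)
  along0 <- (m - spec$overhang_mm - lw_mm / 2) * ppm
  along1 <- (m + extent + spec$overhang_mm + lw_mm / 2) * ppm
  cov_along <- coverage1d(size, along0, along1)
  for (p in pos_mm) {
    cov <- coverage1d(size, (p - lw_mm / 2) * ppm, (p + lw_mm / 2) * ppm)
    img <- pmin(img, 255 - 255 * outer(cov, cov_along))     # horizontal line
    img <- pmin(img, 255 - 255 * outer(cov_along, cov))     # vertical line
  }

  top <- pos_mm[1] * ppm
  bottom <- pos_mm[spec$n_cells + 1] * ppm
  left <- pos_mm[1] * ppm
  mid <- pos_mm[spec$n_cells / 2 + 1] * ppm
  right <- pos_mm[spec$n_cells + 1] * ppm
  landmarks <- rbind(
    top_left = c(top, left), top_mid = c(top, mid), top_right = c(top, right),
    bottom_left = c(bottom, left), bottom_mid = c(bottom, mid),
    bottom_right = c(bottom, right)
  )
  colnames(landmarks) <- c("row", "col")
  truth <- list(
    kind = "grid", spec = spec, degradation = NULL,
    landmarks_pre = landmarks, landmarks_post = landmarks, k1 = 0,
    center = c((size - 1) / 2, (size - 1) / 2),
    norm_radius = sqrt(2) * (size - 1) / 2
  )
  list(image = img, truth = truth)
}

render_colorchecker <- function(spec) {
  ref <- spec$reference
  n <- nrow(ref)
  ncp <- spec$ncol_patches
  nrp <- ceiling(n / ncp)
  p <- spec$patch_px
  b <- spec$border_px
  height <- nrp * (p + b) + b
  width <- ncp * (p + b) + b

  rgb <- lab_to_srgb(as.matrix(ref[, c("L", "a", "b")]))
  img <- array(0, dim = c(height, width, 3L))
  roi <- matrix(NA_integer_, n, 4,
                dimnames = list(NULL, c("r0", "r1", "c0", "c1")))
  for (i in seq_len(n)) {
    gr <- (i - 1) %/% ncp
    gc <- (i - 1) %% ncp
    r0 <- b + gr * (p + b)
    c0 <- b + gc * (p + b)
    roi[i, ] <- c(r0, r0 + p - 1L, c0, c0 + p - 1L)
    for (ch in 1:3) {
      img[(r0 + 1):(r0 + p), (c0 + 1):(c0 + p), ch] <- rgb[i, ch]
    }
  }

  patches <- cbind(ref, as.data.frame(roi),
                   data.frame(R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                              L_eff = ref$L, a_eff = ref$a, b_eff = ref$b))
  truth <- list(
    kind = "colorchecker", spec = spec, degradation = NULL,
    patches = patches,
    layout = list(nrow = nrp, ncol = ncp, patch_px = p, border_px = b)
  )
  list(image = img, truth = truth)
}

# Pattern half-amplitude (about mid-gray) at position x mm along the
# ladder; linear decay reaching zero at amp_zero_mm.
ladder_amplitude <- function(x, amp0, amp_zero_mm) {
  if (!is.finite(amp_zero_mm)) return(rep(amp0, length(x)))
  pmax(0, amp0 * (1 - x / amp_zero_mm))
}

render_dof_ladder <- function(spec) {
  ppm <- spec$px_per_mm
  p <- 1 / spec$lp_per_mm
  # A quarter-period dark lead-in precedes the first light band so the
  # first peak is an interior extremum of any profile drawn from row 0;
  # the ladder's mm origin (x = 0) is the start of the first light band.
  lead <- p / 4
  rows <- round((spec$length_mm + lead) * ppm)
  cols <- round(spec$width_mm * ppm)

  # Pairwise contrast is sampled at pair midpoints p/2 + k*p; a linear
  # amplitude decay hitting zero at amp_zero_mm halves the contrast,
  # relative to the first pair, at (amp_zero_mm + p/2) / 2.
  amp_zero_mm <- if (is.null(spec$contrast_half_mm)) Inf else
    2 * spec$contrast_half_mm - p / 2

  ss <- 4L
  x <- ((seq_len(rows * ss) - 0.5) / ss) / ppm - lead       # mm at subsample
  amp <- ladder_amplitude(pmax(x, 0), spec$amp0, amp_zero_mm)
  phase <- (x / p) %% 1
  light <- x >= 0 & phase < 0.5
  v <- 127.5 + amp * ifelse(light, 1, -1)                   # light band first
  col_profile <- colMeans(matrix(v, nrow = ss))
  img <- matrix(col_profile, rows, cols)

  truth <- list(
    kind = "dof_ladder", spec = spec, degradation = NULL,
    lp_per_mm = spec$lp_per_mm, length_mm = spec$length_mm,
    px_per_mm = ppm,
    n_line_pairs = spec$length_mm * spec$lp_per_mm,
    amp_zero_mm = amp_zero_mm,
    failure_mm = if (is.null(spec$contrast_half_mm)) NA_real_ else
      spec$contrast_half_mm,
    suggested_line = list(p0 = c(0, (cols - 1) / 2),
                          p1 = c(rows - 1, (cols - 1) / 2))
  )
  list(image = img, truth = truth)
}

#' @export
print.lapqc_truth <- function(x, ...) {
  cat("<lapqc_truth>", x$kind,
      sprintf("(%d x %d px)\n", x$height_px, x$width_px))
  invisible(x)
}
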