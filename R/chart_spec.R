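#' USAF-1951 element spatial frequency
#'
#' Frequency of a USAF-1951 bar element in line pairs per millimetre,
#' `2^(group + (element - 1)/6)`. Within a group, successive elements
#' increase frequency by a factor of `2^(1/6)`.
#'
#' @param group Integer group index (may be negative).
#' @param element Integer element index, 1..6.
#' @return Frequency in lp/mm.
#' @export
#' @examples
#' usaf_frequency(2, 3) # 5.04 lp/mm
usaf_frequency <- function(group, element) {
  stopifnot(all(element %in% 1:6))
  2^(group + (element - 1) / 6)
}

#' USAF-1951 element line width in micrometres
#'
#' Width of a single bar, `500 / frequency` where frequency is in lp/mm
#' (one line pair spans one dark and one light bar).
#'
#' @inheritParams usaf_frequency
#' @return Line width in micrometres.
#' @export
usaf_line_width_um <- function(group, element) {
  500 / usaf_frequency(group, element)
}

#' Specify a USAF-1951 resolution chart
#'
#' Describes a vertical stack of USAF bar elements, each rendered as
#' three horizontal dark bars on a white field so that a vertical
#' profile line crosses every bar of every element. Per-element contrast
#' (peak:trough intensity ratio) is configurable to construct charts
#' whose true limit of resolution is known.
#'
#' @param group Integer group index, recycled over `elements`.
#' @param elements Integer vector of element indices (1..6), unique per group.
#' @param px_per_mm Image scale, pixels per millimetre.
#' @param contrast Peak:trough contrast ratio per element (recycled).
#'   `Inf` renders solid black bars.
#' @param white_level Background intensity (default 255).
#' @param bar_length_mm Horizontal bar length in mm.
#' @param margin_mm White margin around the pattern in mm.
#' @return A `chart_spec` of kind `"usaf"`.
#' @export
usaf_chart <- function(group, elements = 1:6, px_per_mm = 40,
                       contrast = Inf, white_level = 255,
                       bar_length_mm = 3, margin_mm = 1) {
  stopifnot(px_per_mm > 0, length(elements) >= 1, white_level > 0,
            bar_length_mm > 0, margin_mm >= 0)
  group <- rep_len(as.integer(group), length(elements))
  contrast <- rep_len(contrast, length(elements))
  if (any(contrast < 1)) stop("contrast ratios must be >= 1")
  key <- paste(group, elements)
  if (anyDuplicated(key)) stop("usaf elements must be unique")
  freq <- usaf_frequency(group, elements)
  bad <- freq > px_per_mm / 2
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "element (group %d, element %d) at %.2f lp/mm exceeds the Nyquist limit %.2f lp/mm for %g px/mm",
      group[i], elements[i], freq[i], px_per_mm / 2, px_per_mm))
  }
  structure(list(kind = "usaf", px_per_mm = px_per_mm, group = group,
                 elements = as.integer(elements), contrast = contrast,
                 white_level = white_level, bar_length_mm = bar_length_mm,
                 margin_mm = margin_mm),
            class = "chart_spec")
}

#' Specify a square-grid distortion chart
#'
#' An `n_cells x n_cells` grid of dark lines on white, used for SMIA TV
#' distortion analysis. The ground truth records the six landmark points
#' (left, middle, right on the outer top and bottom lines).
#'
#' @param n_cells Number of grid cells per side (even, so a centre line
#'   exists).
#' @param spacing_mm Cell pitch in mm.
#' @param line_width_px Grid line width in pixels.
#' @param px_per_mm Image scale.
#' @param margin_mm White margin around the grid in mm.
#' @param overhang_mm How far every line extends past the outer
#'   intersections (so all landmarks sit on symmetric crosses, as on
#'   printed grid targets).
#' @return A `chart_spec` of kind `"grid"`.
#' @export
grid_chart <- function(n_cells = 8, spacing_mm = 1, line_width_px = 3,
                       px_per_mm = 30, margin_mm = 3, overhang_mm = 0.5) {
  stopifnot(px_per_mm > 0, n_cells >= 2, n_cells %% 2 == 0,
            spacing_mm > 0, line_width_px > 0, margin_mm >= 0,
            overhang_mm >= 0, margin_mm >= overhang_mm)
  structure(list(kind = "grid", px_per_mm = px_per_mm, n_cells = n_cells,
                 spacing_mm = spacing_mm, line_width_px = line_width_px,
                 margin_mm = margin_mm, overhang_mm = overhang_mm),
            class = "chart_spec")
}

#' Specify a colour-accuracy patch chart
#'
#' A grid of uniformly coloured patches with known reference CIELAB
#' values, separated by black borders, emulating a ColorChecker-style
#' target.
#'
#' @param reference Data frame with columns `patch_id`, `role`
#'   (`"color"` or `"white_balance"`), `L`, `a`, `b`; see
#'   [read_reference_lab()] for the shipped presets.
#' @param ncol_patches Number of patch columns; rows are derived.
#' @param patch_px Patch side length in pixels.
#' @param border_px Border width between patches in pixels.
#' @param px_per_mm Image scale (metadata only; patch geometry is in px).
#' @return A `chart_spec` of kind `"colorchecker"`.
#' @export
colorchecker_chart <- function(reference, ncol_patches = 6, patch_px = 40,
                               border_px = 10, px_per_mm = 10) {
  stopifnot(is.data.frame(reference),
            all(c("patch_id", "role", "L", "a", "b") %in% names(reference)),
            nrow(reference) >= 1, patch_px >= 4, border_px >= 0,
            px_per_mm > 0)
  if (!all(reference$role %in% c("color", "white_balance"))) {
    stop("reference roles must be 'color' or 'white_balance'")
  }
  if (any(reference$L < 0 | reference$L > 100)) {
    stop("reference L* values must lie in [0, 100]")
  }
  structure(list(kind = "colorchecker", px_per_mm = px_per_mm,
                 reference = reference, ncol_patches = ncol_patches,
                 patch_px = patch_px, border_px = border_px),
            class = "chart_spec")
}

#' Specify a depth-of-field line ladder
#'
#' Horizontal dark/light line pairs at a fixed spatial frequency,
#' running down the image rows, emulating the 5 lp/mm region of a
#' depth-of-field target. An optional linear contrast gradient makes the
#' pairwise peak-trough contrast fall to half its initial value at a
#' known position, giving an analytic ground-truth failure point.
#'
#' @param lp_per_mm Line-pair frequency (default 5).
#' @param length_mm Ladder length in mm (rows direction).
#' @param px_per_mm Image scale.
#' @param width_mm Ladder width in mm (columns direction).
#' @param contrast_half_mm Position (mm from the ladder start) at which
#'   pairwise contrast reaches half the first pair's contrast, or `NULL`
#'   for uniform full contrast.
#' @param amp0 Initial half-amplitude of the pattern about mid-gray
#'   127.5 (default 127.5, i.e. full 0--255 swing).
#' @return A `chart_spec` of kind `"dof_ladder"`.
#' @export
dof_ladder <- function(lp_per_mm = 5, length_mm = 10, px_per_mm = 40,
                       width_mm = 3, contrast_half_mm = NULL,
                       amp0 = 127.5) {
  stopifnot(lp_per_mm > 0, length_mm > 0, px_per_mm > 0, width_mm > 0,
            amp0 > 0, amp0 <= 127.5)
  if (lp_per_mm > px_per_mm / 2) {
    stop(sprintf("ladder frequency %g lp/mm exceeds the Nyquist limit %g lp/mm",
                 lp_per_mm, px_per_mm / 2))
  }
  p <- 1 / lp_per_mm
  if (!is.null(contrast_half_mm)) {
    stopifnot(contrast_half_mm > p)
    if (contrast_half_mm >= length_mm) {
      stop("contrast_half_mm must lie within the ladder length")
    }
  }
  structure(list(kind = "dof_ladder", px_per_mm = px_per_mm,
                 lp_per_mm = lp_per_mm, length_mm = length_mm,
                 width_mm = width_mm, contrast_half_mm = contrast_half_mm,
                 amp0 = amp0),
            class = "chart_spec")
}

#' @export
print.chart_spec <- function(x, ...) {
  cat("<chart_spec>", x$kind, "at", x$px_per_mm, "px/mm\n")
  invisible(x)
}
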