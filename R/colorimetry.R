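#' Convert 8-bit sRGB to CIELAB
#'
#' Standard IEC 61966-2-1 sRGB decoding to CIE XYZ and on to CIELAB
#' under the D65 white point, 2 degree observer.
#'
#' @param rgb Length-3 vector or `n x 3` matrix of 8-bit values
#'   (0--255).
#' @return `n x 3` matrix with columns `L`, `a`, `b`.
#' @export
#' @examples
#' srgb_to_lab(c(255, 255, 255)) # L* = 100
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  stopifnot(ncol(rgb) == 3, all(rgb >= 0), all(rgb <= 255))
  lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  colnames(lab) <- c("L", "a", "b")
  lab
}

#' Convert CIELAB to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]; out-of-gamut colours are clipped to the
#' 8-bit range.
#'
#' @param lab Length-3 vector or `n x 3` matrix of `L`, `a`, `b`.
#' @return `n x 3` matrix of 8-bit values (0--255, unrounded).
#' @export
lab_to_srgb <- function(lab) {
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = 3, byrow = TRUE)
  stopifnot(ncol(lab) == 3)
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  clamp255(rgb * 255)
}

#' CIE76 colour difference
#'
#' Euclidean distance in CIELAB:
#' `sqrt((dL)^2 + (da)^2 + (db)^2)`.
#'
#' @param m,r Measured and reference colours, length-3 vectors or
#'   `n x 3` matrices of `L`, `a`, `b`.
#' @return Numeric vector of distances.
#' @export
delta_e_ab <- function(m, r) {
  d <- lab_diff(m, r)
  sqrt(rowSums(d^2))
}

#' Chroma-only colour difference
#'
#' Euclidean distance in the (a*, b*) plane, ignoring luminance:
#' `sqrt((da)^2 + (db)^2)`.
#'
#' @inheritParams delta_e_ab
#' @return Numeric vector of distances.
#' @export
delta_c_ab <- function(m, r) {
  d <- lab_diff(m, r)
  sqrt(rowSums(d[, 2:3, drop = FALSE]^2))
}

lab_diff <- function(m, r) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3, byrow = TRUE)
  if (is.null(dim(r))) r <- matrix(r, ncol = 3, byrow = TRUE)
  stopifnot(ncol(m) == 3, ncol(r) == 3, nrow(m) == nrow(r))
  m - r
}

#' Define a patch-grid layout
#'
#' Rectangular patch ROIs derived from a grid origin and pitch, in
#' 0-based pixel coordinates. Only the centered `inner_fraction` of
#' each ROI is sampled, to avoid bleed from patch borders.
#'
#' @param nrow,ncol Patch grid dimensions.
#' @param origin `(row, col)` of the first patch's top-left pixel.
#' @param pitch `(row, col)` step between adjacent patch origins.
#' @param patch_px Patch side length in pixels (length 1 or 2).
#' @param inner_fraction Linear fraction of each patch sampled,
#'   in (0, 1].
#' @return A `patch_layout`.
#' @export
patch_layout <- function(nrow, ncol, origin, pitch, patch_px,
                         inner_fraction = 0.5) {
  stopifnot(nrow >= 1, ncol >= 1, length(origin) == 2, length(pitch) == 2,
            inner_fraction > 0, inner_fraction <= 1)
  patch_px <- rep_len(patch_px, 2)
  structure(list(nrow = nrow, ncol = ncol, origin = as.numeric(origin),
                 pitch = as.numeric(pitch), patch_px = patch_px,
                 inner_fraction = inner_fraction),
            class = "patch_layout")
}

#' Layout matching a rendered colour chart
#'
#' Builds the [patch_layout()] that exactly registers a chart produced
#' by [render_chart()] on a [colorchecker_chart()] spec.
#'
#' @param truth The chart's `lapqc_truth`.
#' @param inner_fraction Sampled fraction, see [patch_layout()].
#' @return A `patch_layout`.
#' @export
layout_from_truth <- function(truth, inner_fraction = 0.5) {
  stopifnot(inherits(truth, "lapqc_truth"), truth$kind == "colorchecker")
  l <- truth$layout
  patch_layout(l$nrow, l$ncol, origin = c(l$border_px, l$border_px),
               pitch = rep(l$patch_px + l$border_px, 2),
               patch_px = l$patch_px, inner_fraction = inner_fraction)
}

#' Mean RGB of each patch
#'
#' Averages pixel values over the centered inner region of every patch
#' ROI, row-major over the grid.
#'
#' @param image RGB array (or matrix), 0--255.
#' @param layout A [patch_layout()].
#' @param n_patches Number of patches actually present (defaults to the
#'   full grid; the last grid row may be partial).
#' @return `n_patches x 3` matrix of mean R, G, B.
#' @export
extract_patches <- function(image, layout, n_patches = layout$nrow * layout$ncol) {
  stopifnot(inherits(layout, "patch_layout"))
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(NA_real_, n_patches, 3, dimnames = list(NULL, c("R", "G", "B")))
  for (i in seq_len(n_patches)) {
    gr <- (i - 1) %/% layout$ncol
    gc <- (i - 1) %% layout$ncol
    r0 <- layout$origin[1] + gr * layout$pitch[1]
    c0 <- layout$origin[2] + gc * layout$pitch[2]
    ph <- layout$patch_px[1]; pw <- layout$patch_px[2]
    inset_r <- ph * (1 - layout$inner_fraction) / 2
    inset_c <- pw * (1 - layout$inner_fraction) / 2
    rr <- (ceiling(r0 + inset_r) + 1):(floor(r0 + ph - 1 - inset_r) + 1)
    cc <- (ceiling(c0 + inset_c) + 1):(floor(c0 + pw - 1 - inset_c) + 1)
    if (min(rr) < 1 || max(rr) > h || min(cc) < 1 || max(cc) > w) {
      stop(sprintf("patch %d ROI lies outside the image", i))
    }
    if (is_rgb(image)) {
      for (ch in 1:3) out[i, ch] <- mean(image[rr, cc, ch])
    } else {
      out[i, ] <- mean(image[rr, cc])
    }
  }
  out
}

#' Read a reference CIELAB patch table
#'
#' CSV with columns `patch_id`, `role` (`color` or `white_balance`),
#' `L`, `a`, `b`. Two presets ship with the package (nominal values,
#' see their file headers): `"colorchecker_classic_24"` and
#' `"synthetic_18plus12"`.
#'
#' @param path CSV path, or the bare name of a shipped preset.
#' @return Data frame of reference patches.
#' @export
read_reference_lab <- function(path) {
  if (!file.exists(path)) {
    cand <- system.file("extdata", paste0(path, ".csv"), package = "lapqc")
    if (nzchar(cand)) path <- cand
  }
  if (!file.exists(path)) stop("reference table not found: ", path)
  ref <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("patch_id", "role", "L", "a", "b")
  if (!all(need %in% names(ref))) {
    stop("reference CSV must have columns: ", paste(need, collapse = ", "))
  }
  ref
}

#' Colour accuracy of an imaged patch chart
#'
#' Extracts per-patch mean RGB, converts to CIELAB and reports CIE76
#' delta-E*ab and chroma-only delta-C*ab against the reference table.
#' Means are taken over the colour patches; white-balance patches are
#' summarized separately and excluded from the colour-error mean.
#'
#' @param image RGB chart image, 0--255.
#' @param layout A [patch_layout()].
#' @param reference Reference table from [read_reference_lab()] (or any
#'   data frame with `patch_id`, `role`, `L`, `a`, `b`), ordered
#'   row-major over the grid.
#' @return A `color_diff_result`: per-patch table (measured and
#'   reference Lab, delta_e, delta_c, role), `mean_delta_e`,
#'   `mean_delta_c` (colour patches), `mean_delta_e_wb`,
#'   `mean_delta_c_wb` (white-balance patches, `NA` if none).
#' @export
analyze_color <- function(image, layout, reference) {
  stopifnot(is_rgb(image))
  n <- nrow(reference)
  rgb <- extract_patches(image, layout, n_patches = n)
  lab <- srgb_to_lab(rgb)
  ref <- as.matrix(reference[, c("L", "a", "b")])
  de <- delta_e_ab(lab, ref)
  dc <- delta_c_ab(lab, ref)
  patches <- data.frame(
    patch_id = reference$patch_id, role = reference$role,
    L_ref = ref[, 1], a_ref = ref[, 2], b_ref = ref[, 3],
    L_meas = lab[, 1], a_meas = lab[, 2], b_meas = lab[, 3],
    delta_e = de, delta_c = dc
  )
  col <- reference$role == "color"
  wb <- reference$role == "white_balance"
  structure(list(
    patches = patches,
    mean_delta_e = mean(de[col]),
    mean_delta_c = mean(dc[col]),
    mean_delta_e_wb = if (any(wb)) mean(de[wb]) else NA_real_,
    mean_delta_c_wb = if (any(wb)) mean(dc[wb]) else NA_real_
  ), class = "color_diff_result")
}

#' Reference-vs-measured swatch image
#'
#' Side-by-side raster for visual audit: for each patch, the left half
#' shows the reference colour and the right half the measured colour.
#'
#' @param result A [color_diff_result][analyze_color].
#' @param swatch_px Side length of one swatch cell in pixels.
#' @param ncol Number of swatch columns.
#' @return RGB array (0--255) that can be passed to [write_image()].
#' @export
swatch_image <- function(result, swatch_px = 40, ncol = 6) {
  p <- result$patches
  n <- nrow(p)
  nr <- ceiling(n / ncol)
  img <- array(255, dim = c(nr * swatch_px, ncol * swatch_px, 3))
  ref_rgb <- lab_to_srgb(as.matrix(p[, c("L_ref", "a_ref", "b_ref")]))
  meas_rgb <- lab_to_srgb(as.matrix(p[, c("L_meas", "a_meas", "b_meas")]))
  half <- floor(swatch_px / 2)
  for (i in seq_len(n)) {
    r0 <- ((i - 1) %/% ncol) * swatch_px
    c0 <- ((i - 1) %% ncol) * swatch_px
    for (ch in 1:3) {
      img[(r0 + 1):(r0 + swatch_px), (c0 + 1):(c0 + half), ch] <- ref_rgb[i, ch]
      img[(r0 + 1):(r0 + swatch_px), (c0 + half + 1):(c0 + swatch_px), ch] <-
        meas_rgb[i, ch]
    }
  }
  quantize8(img)
}

#' @export
print.color_diff_result <- function(x, ...) {
  cat("<color_diff_result>\n")
  cat(sprintf("  mean dE*ab %.2f, mean dC*ab %.2f over %d colour patches\n",
              x$mean_delta_e, x$mean_delta_c, sum(x$patches$role == "color")))
  if (!is.na(x$mean_delta_e_wb)) {
    cat(sprintf("  white-balance patches: mean dE*ab %.2f, mean dC*ab %.2f\n",
                x$mean_delta_e_wb, x$mean_delta_c_wb))
  }
  invisible(x)
}
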