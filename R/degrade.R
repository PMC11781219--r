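#' Specify a parametric optical degradation
#'
#' Describes the degradations applied to a rendered chart, in the fixed
#' order blur, radial distortion, CIELAB colour offset, additive noise.
#'
#' @param blur_sigma_px Gaussian blur sigma in pixels (>= 0).
#' @param blur_gradient Length-2 numeric `c(sigma_start, sigma_end)`:
#'   sigma varies linearly along the image rows (used for
#'   depth-of-field ladders). Overrides `blur_sigma_px`.
#' @param k1 One-term Brown--Conrady radial distortion coefficient in
#'   coordinates normalized by half the image diagonal about the image
#'   center. Negative is barrel, positive pincushion.
#' @param lab_offset Length-3 `c(dL, da, db)` added uniformly, in CIELAB,
#'   to every pixel of an RGB chart.
#' @param noise_sigma Additive Gaussian noise sigma in gray levels.
#' @param seed Integer seed for the noise; identical spec + seed gives
#'   bit-identical output.
#' @return A `degradation_spec`.
#' @export
degradation_spec <- function(blur_sigma_px = 0, blur_gradient = NULL,
                             k1 = 0, lab_offset = c(0, 0, 0),
                             noise_sigma = 0, seed = 1L) {
  stopifnot(blur_sigma_px >= 0, noise_sigma >= 0,
            length(lab_offset) == 3, is.numeric(k1), length(k1) == 1)
  if (!is.null(blur_gradient)) {
    stopifnot(length(blur_gradient) == 2, all(blur_gradient >= 0))
  }
  structure(list(blur_sigma_px = blur_sigma_px,
                 blur_gradient = blur_gradient, k1 = k1,
                 lab_offset = as.numeric(lab_offset),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "degradation_spec")
}

is_identity_degradation <- function(deg) {
  deg$blur_sigma_px == 0 && is.null(deg$blur_gradient) && deg$k1 == 0 &&
    all(deg$lab_offset == 0) && deg$noise_sigma == 0
}

#' Apply a degradation to a rendered chart
#'
#' Applies blur, radial distortion, colour offset and noise (in that
#' fixed order) to a chart from [render_chart()], updating the ground
#' truth analytically: distortion landmarks are forward-mapped through
#' the radial model and effective patch CIELAB values include the
#' colour offset.
#'
#' @param image Raster from [render_chart()].
#' @param truth Matching `lapqc_truth`.
#' @param deg A [degradation_spec()].
#' @return List `(image, truth)` with the degraded 8-bit image.
#' @export
apply_degradation <- function(image, truth, deg) {
  stopifnot(inherits(deg, "degradation_spec"), inherits(truth, "lapqc_truth"))
  if (is_identity_degradation(deg)) {
    truth$degradation <- deg
    return(list(image = image, truth = truth))
  }

  if (!is.null(deg$blur_gradient)) {
    image <- per_channel(image, gradient_blur_rows,
                         deg$blur_gradient[1], deg$blur_gradient[2])
  } else if (deg$blur_sigma_px > 0) {
    image <- per_channel(image, function(m)
      EBImage::imageData(EBImage::gblur(m, sigma = deg$blur_sigma_px,
                                        boundary = "replicate")))
  }

  if (deg$k1 != 0) {
    h <- nrow(image)
    w <- if (is_rgb(image)) dim(image)[2] else ncol(image)
    center <- c((h - 1) / 2, (w - 1) / 2)
    norm_r <- sqrt((h - 1)^2 + (w - 1)^2) / 2
    image <- per_channel(image, warp_radial, deg$k1, center, norm_r)
    if (truth$kind == "grid") {
      post <- radial_map(truth$landmarks_pre, deg$k1, center, norm_r)
      out <- post[, 1] < 0 | post[, 1] > h - 1 | post[, 2] < 0 | post[, 2] > w - 1
      if (any(out)) {
        stop("distortion maps landmark(s) outside the frame: ",
             paste(rownames(post)[out], collapse = ", "))
      }
      truth$landmarks_post <- post
      truth$k1 <- deg$k1
      truth$center <- center
      truth$norm_radius <- norm_r
    }
  }

  if (any(deg$lab_offset != 0)) {
    if (!is_rgb(image)) {
      stop("lab_offset requires an RGB chart (colorchecker)")
    }
    image <- shift_lab(image, deg$lab_offset)
    if (truth$kind == "colorchecker") {
      truth$patches$L_eff <- truth$patches$L + deg$lab_offset[1]
      truth$patches$a_eff <- truth$patches$a + deg$lab_offset[2]
      truth$patches$b_eff <- truth$patches$b + deg$lab_offset[3]
    }
  }

  if (deg$noise_sigma > 0) {
    image <- withr::with_seed(deg$seed, {
      image + stats::rnorm(length(image), sd = deg$noise_sigma)
    })
  }

  truth$degradation <- deg
  list(image = quantize8(image), truth = truth)
}

per_channel <- function(image, f, ...) {
  if (!is_rgb(image)) return(f(image, ...))
  for (ch in seq_len(dim(image)[3])) {
    image[, , ch] <- f(image[, , ch], ...)
  }
  image
}

# 1-D Gaussian blur along rows with sigma varying linearly from
# sigma_start (row 1) to sigma_end (last row); replicate padding.
# Used for depth-of-field ladders, where no fixed-kernel filter applies.
gradient_blur_rows <- function(m, sigma_start, sigma_end) {
  n <- nrow(m)
  sigmas <- seq(sigma_start, sigma_end, length.out = n)
  out <- m
  for (i in seq_len(n)) {
    s <- sigmas[i]
    if (s < 1e-6) next
    r <- ceiling(3 * s)
    idx <- pmin(pmax(i + (-r:r), 1L), n)
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    out[i, ] <- crossprod(m[idx, , drop = FALSE], w)
  }
  out
}

# Forward one-term Brown-Conrady map: a point at normalized radius r
# moves to r * (1 + k1 r^2). points is an n x 2 (row, col) matrix.
radial_map <- function(points, k1, center, norm_radius) {
  v <- sweep(points, 2, center)
  r2 <- rowSums(v^2) / norm_radius^2
  mapped <- sweep(v * (1 + k1 * r2), 2, center, `+`)
  dimnames(mapped) <- dimnames(points)
  mapped
}

# Warp an image through the radial model: each output (distorted) pixel
# samples the ideal image at the inverse mapping, solved by Newton
# iteration on r (1 + k1 r^2) = r_d.
warp_radial <- function(m, k1, center, norm_radius) {
  h <- nrow(m); w <- ncol(m)
  rows <- matrix(0:(h - 1), h, w) - center[1]
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE) - center[2]
  rd <- sqrt(rows^2 + cols^2) / norm_radius
  r <- rd
  for (it in 1:12) {
    f <- r * (1 + k1 * r^2) - rd
    fp <- 1 + 3 * k1 * r^2
    r <- r - f / pmax(abs(fp), 1e-8) * sign(fp)
  }
  scale <- ifelse(rd > 0, r / rd, 1)
  bilinear_sample(m, rows * scale + center[1], cols * scale + center[2])
}

# Bilinear interpolation at real-valued 0-based (row, col) coordinates,
# replicate behavior outside the border.
bilinear_sample <- function(m, rows, cols) {
  h <- nrow(m); w <- ncol(m)
  rows <- pmin(pmax(rows, 0), h - 1)
  cols <- pmin(pmax(cols, 0), w - 1)
  r0 <- pmin(floor(rows), h - 2); c0 <- pmin(floor(cols), w - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- rows - r0; fc <- cols - c0
  i00 <- r0 + h * c0 + 1
  v <- (1 - fr) * (1 - fc) * m[i00] + fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + h] + fr * fc * m[i00 + h + 1]
  if (is.matrix(rows)) matrix(v, nrow(rows), ncol(rows)) else v
}

# Uniform CIELAB offset applied per pixel of an RGB image (0-255).
shift_lab <- function(image, offset) {
  d <- dim(image)
  rgb <- matrix(image, ncol = 3) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  lab <- sweep(lab, 2, offset, `+`)
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  array(clamp255(out * 255), dim = d)
}
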