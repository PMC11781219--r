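#' Read an 8-bit raster image
#'
#' Reads a PNG or TIFF file into the plain-array representation used
#' throughout the package: a numeric matrix (grayscale) or a
#' `rows x cols x 3` array (RGB), with intensities on the 0--255 scale.
#' An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix or 3-channel array, values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (expected png or tiff)")
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L) {
      img <- img[, , 1:3, drop = FALSE]
    } else {
      img <- img[, , 1L]
    }
  }
  img * 255
}

#' Write an 8-bit raster image
#'
#' @param image Matrix or `rows x cols x 3` array on the 0--255 scale.
#' @param path Output path; format chosen from the extension (png/tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  x <- clamp255(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format '.", ext, "' (expected png or tiff)")
  )
  invisible(path)
}

#' Convert an RGB image to luminance
#'
#' Rec. 709 luma weights applied to the stored (gamma-encoded) channel
#' values, the convention of common image-analysis tools. Grayscale
#' input is returned unchanged.
#'
#' @param image Matrix or `rows x cols x 3` array, 0--255.
#' @return Numeric matrix, 0--255.
#' @export
to_luminance <- function(image) {
  if (length(dim(image)) == 2L) {
    return(image)
  }
  0.2126 * image[, , 1L] + 0.7152 * image[, , 2L] + 0.0722 * image[, , 3L]
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

is_rgb <- function(image) length(dim(image)) == 3L

#' @keywords internal
quantize8 <- function(x) clamp255(round(x))
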