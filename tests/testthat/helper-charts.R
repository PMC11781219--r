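# Shared fixture builders: all fixtures are rendered in code at test time.

truth_line <- function(truth, width_px = 1L) {
  line_segment(truth$suggested_line$p0, truth$suggested_line$p1,
               width_px = width_px)
}

# Profile object straight from a value vector (unit arc-length steps),
# for tests that exercise extrema/DOF logic on constructed sequences.
profile_from_values <- function(values) {
  structure(list(distances = seq_along(values) - 1,
                 values = as.numeric(values),
                 line = line_segment(c(0, 0), c(0, length(values) - 1))),
            class = "intensity_profile")
}

# Independent oracle for sRGB -> CIELAB: the published IEC 61966-2-1
# decoding and CIE equations evaluated directly (D65, 2 degrees),
# kept free of the package's conversion path.
oracle_srgb_to_lab <- function(rgb255) {
  s <- rgb255 / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  white <- c(0.95047, 1.00000, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / white)
  c(L = 116 * fx[2] - 16, a = 500 * (fx[1] - fx[2]), b = 200 * (fx[2] - fx[3]))
}

classic_ref <- function() read_reference_lab("colorchecker_classic_24")

# Mid-range table comfortably inside the sRGB gamut, for properties that
# should not be confounded by gamut clipping.
gamut_safe_ref <- function() {
  data.frame(
    patch_id = sprintf("p%02d", 1:12),
    role = c(rep("color", 9), rep("white_balance", 3)),
    L = c(40, 55, 70, 45, 60, 50, 65, 35, 55, 30, 50, 70),
    a = c(20, -15, 5, 30, -25, 10, -5, 15, 0, 0, 0, 0),
    b = c(10, 25, -20, -5, 15, -30, 35, -15, 20, 0, 0, 0))
}
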