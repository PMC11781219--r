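test_that("sRGB->Lab endpoints and mid-gray match the published equations", {
  expect_equal(as.numeric(srgb_to_lab(c(255, 255, 255))), c(100, 0, 0),
               tolerance = 1e-6)
  expect_equal(as.numeric(srgb_to_lab(c(0, 0, 0))), c(0, 0, 0),
               tolerance = 1e-6)
  got <- as.numeric(srgb_to_lab(c(119, 119, 119)))
  want <- unname(oracle_srgb_to_lab(c(119, 119, 119)))
  expect_equal(got, want, tolerance = 1e-3)
  expect_lt(abs(got[1] - 50), 0.1)
  # a saturated colour against the independent oracle; small differences
  # in primaries/white precision between implementations are expected
  got2 <- as.numeric(srgb_to_lab(c(200, 30, 120)))
  expect_lt(max(abs(got2 - oracle_srgb_to_lab(c(200, 30, 120)))), 0.5)
})

test_that("delta E / delta C closed forms are exact", {
  r <- c(50, 10, -20)
  expect_equal(delta_e_ab(r, r), 0, tolerance = 1e-9)
  expect_equal(delta_c_ab(r, r), 0, tolerance = 1e-9)
  expect_equal(delta_e_ab(r + c(3, 4, 0), r), 5, tolerance = 1e-9)
  expect_equal(delta_e_ab(r + c(1, 2, 2), r), 3, tolerance = 1e-9)
  expect_equal(delta_c_ab(r + c(7, 3, 4), r), 5, tolerance = 1e-9)
  # pure-luminance difference: dE = |dL|, dC = 0
  expect_equal(delta_e_ab(r + c(10, 0, 0), r), 10, tolerance = 1e-9)
  expect_equal(delta_c_ab(r + c(10, 0, 0), r), 0, tolerance = 1e-9)
})

test_that("delta E is a metric on random Lab triples (triangle inequality)", {
  withr::with_seed(11, {
    for (i in 1:50) {
      m <- c(runif(1, 0, 100), runif(2, -60, 60))
      q <- c(runif(1, 0, 100), runif(2, -60, 60))
      r <- c(runif(1, 0, 100), runif(2, -60, 60))
      expect_lte(delta_e_ab(m, r), delta_e_ab(m, q) + delta_e_ab(q, r) + 1e-12)
      expect_gte(delta_e_ab(m, r), delta_c_ab(m, r))
    }
  })
})

test_that("patch extraction recovers rendered patch colours", {
  ref <- classic_ref()
  ch <- render_chart(colorchecker_chart(ref))
  lay <- layout_from_truth(ch$truth)
  rgb <- extract_patches(ch$image, lay, n_patches = nrow(ref))
  expect_equal(unname(rgb),
               unname(as.matrix(ch$truth$patches[, c("R", "G", "B")])),
               tolerance = 1)
  # uniform image: every patch reports the same mean
  uni <- array(90, dim = dim(ch$image))
  rgbu <- extract_patches(uni, lay, n_patches = nrow(ref))
  expect_true(all(rgbu == 90))
})

test_that("inner sampling fraction avoids border bleed", {
  ref <- classic_ref()
  ch <- render_chart(colorchecker_chart(ref, border_px = 2))
  # sample one patch with fraction 1.0 after smearing its dark border in
  d <- apply_degradation(ch$image, ch$truth,
                         degradation_spec(blur_sigma_px = 1))
  full <- layout_from_truth(ch$truth, inner_fraction = 1)
  half <- layout_from_truth(ch$truth, inner_fraction = 0.5)
  m_full <- extract_patches(d$image, full, n_patches = nrow(ref))
  m_half <- extract_patches(d$image, half, n_patches = nrow(ref))
  # white patch: border bleed darkens the full-ROI mean
  white_row <- which(ref$patch_id == "white")
  expect_lt(mean(m_full[white_row, ]), mean(m_half[white_row, ]))
})

test_that("ROI outside the image names the patch", {
  lay <- patch_layout(2, 2, origin = c(0, 0), pitch = c(50, 50), patch_px = 40)
  expect_error(extract_patches(matrix(0, 60, 60), lay), "patch 2")
})

test_that("zero-degradation round trip keeps mean dE within quantization", {
  ref <- classic_ref()
  ch <- render_chart(colorchecker_chart(ref))
  res <- analyze_color(ch$image, layout_from_truth(ch$truth), ref)
  expect_lte(res$mean_delta_e, 1)
  expect_true(all(res$patches$delta_e >= res$patches$delta_c))
  expect_true(all(res$patches$delta_c >= 0))
})

test_that("a known Lab offset shifts mean dE by its Euclidean norm", {
  # in-gamut table so the property is not confounded by sRGB gamut
  # clipping (the classic chart's cyan lies outside the sRGB gamut)
  ref <- gamut_safe_ref()
  ch <- render_chart(colorchecker_chart(ref, ncol_patches = 4))
  lay <- layout_from_truth(ch$truth)
  d <- apply_degradation(ch$image, ch$truth,
                         degradation_spec(lab_offset = c(0, 3, 4)))
  res <- analyze_color(d$image, lay, ref)
  expect_lte(abs(res$mean_delta_e - 5), 0.5)
  expect_lte(abs(res$mean_delta_c - 5), 0.5)
})

test_that("white-balance squares are excluded from the colour-error mean", {
  ref <- classic_ref()
  ch <- render_chart(colorchecker_chart(ref))
  lay <- layout_from_truth(ch$truth)
  res <- analyze_color(ch$image, lay, ref)
  col_rows <- res$patches$role == "color"
  expect_equal(res$mean_delta_e, mean(res$patches$delta_e[col_rows]))
  expect_equal(res$mean_delta_e_wb, mean(res$patches$delta_e[!col_rows]))
})

test_that("two patches with dE 3 and 5 average to 4", {
  ref <- data.frame(patch_id = c("p1", "p2"), role = "color",
                    L = c(50, 60), a = c(0, 10), b = c(0, -10))
  ch <- render_chart(colorchecker_chart(ref, ncol_patches = 2))
  lay <- layout_from_truth(ch$truth, inner_fraction = 0.5)
  rgb <- extract_patches(ch$image, lay, n_patches = 2)
  meas <- srgb_to_lab(rgb)
  shifted <- ref
  shifted[1, c("L", "a", "b")] <- meas[1, ] + c(3, 0, 0)
  shifted[2, c("L", "a", "b")] <- meas[2, ] + c(0, 0, 5)
  res <- analyze_color(ch$image, lay, shifted)
  expect_equal(res$mean_delta_e, 4, tolerance = 1e-6)
})

test_that("swatch image halves are identical when measured equals reference", {
  ref <- classic_ref()
  ch <- render_chart(colorchecker_chart(ref))
  res <- analyze_color(ch$image, layout_from_truth(ch$truth), ref)
  res$patches[, c("L_meas", "a_meas", "b_meas")] <-
    res$patches[, c("L_ref", "a_ref", "b_ref")]
  sw <- swatch_image(res, swatch_px = 10, ncol = 6)
  for (j in 1:6) {
    left <- (j - 1) * 10 + 1:5
    expect_identical(sw[, left, ], sw[, left + 5, ])
  }
})

test_that("shipped reference presets load with the declared structure", {
  ref24 <- read_reference_lab("colorchecker_classic_24")
  expect_equal(nrow(ref24), 24)
  expect_equal(sum(ref24$role == "color"), 18)
  ref30 <- read_reference_lab("rezchecker_synthetic_18plus12")
  expect_equal(sum(ref30$role == "white_balance"), 12)
})
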