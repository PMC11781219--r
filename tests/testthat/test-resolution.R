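make_run <- function(peaks, troughs) {
  data.frame(index = seq_len(length(peaks) + length(troughs)),
             distance = seq_len(length(peaks) + length(troughs)),
             value = c(peaks, troughs),
             kind = c(rep("peak", length(peaks)), rep("trough", length(troughs))))
}

fake_verdict <- function(passed, group = 2, element = 1) {
  structure(list(element = list(group = group, element = element,
                                frequency_lp_mm = usaf_frequency(group, element),
                                line_width_um = usaf_line_width_um(group, element)),
                 passed = passed),
            class = "element_verdict")
}

test_that("2:1 criterion arithmetic on hand-checked runs", {
  v <- assess_element(make_run(c(200, 200, 200), c(99, 100)))
  expect_equal(v$ratio, 200 / 99.5)
  expect_true(v$passed)            # 2.0101 >= 2
  v2 <- assess_element(make_run(c(200, 200, 200), c(101, 101)))
  expect_equal(v2$ratio, 200 / 101)
  expect_false(v2$passed)          # 1.98 < 2
  # full contrast: the 1-gray-level floor keeps the ratio finite
  v3 <- assess_element(make_run(c(255, 255), c(0, 0)))
  expect_equal(v3$ratio, 255)
  expect_true(v3$passed)
})

test_that("a saturated run (no trough) passes with an infinite-ratio flag", {
  v <- assess_element(make_run(c(250, 250), numeric(0)))
  expect_true(v$passed)
  expect_true(is.infinite(v$ratio))
  expect_true(v$saturated)
})

test_that("worst-pair strategy uses lowest peak over highest trough", {
  v <- assess_element(make_run(c(210, 180, 240), c(80, 100)),
                      strategy = "worst_pair")
  expect_equal(v$ratio, 180 / 100)
})

test_that("limit is the finest element of the leading all-pass prefix", {
  v <- lapply(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), fake_verdict,
              group = 2)
  for (i in seq_along(v)) v[[i]]$element$element <- i
  r <- resolution_limit(v)
  expect_equal(r$limit$element, 3)
  expect_false(r$anomalous)
  # non-monotone verdicts: truncate at the first failure, flag the anomaly
  v2 <- lapply(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE), fake_verdict)
  for (i in seq_along(v2)) v2[[i]]$element$element <- i
  r2 <- resolution_limit(v2)
  expect_equal(r2$limit$element, 2)
  expect_true(r2$anomalous)
  # no pass at all
  r3 <- resolution_limit(lapply(c(FALSE, FALSE), fake_verdict))
  expect_null(r3$limit)
  expect_equal(r3$status, "unresolved")
})

test_that("all-pass group 2 reports element 6 at 7.13 lp/mm i.e. 70.2 um", {
  ch <- render_chart(usaf_chart(2, 1:6, px_per_mm = 72))
  r <- analyze_resolution(ch$image, truth_line(ch$truth), 2, 1:6)
  expect_equal(r$limit$element, 6)
  expect_equal(r$limit$frequency_lp_mm, 7.13, tolerance = 1e-3)
  expect_equal(r$limit_um, 70.2, tolerance = 1e-3)
})

test_that("segmentation yields one 3-trough run per element and errors on merges", {
  ch <- render_chart(usaf_chart(2, 1:6, px_per_mm = 72))
  ex <- detect_extrema(sample_profile(ch$image, truth_line(ch$truth)), 5)
  runs <- segment_elements(ex, 6)
  expect_length(runs, 6)
  for (run in runs) expect_equal(sum(run$kind == "trough"), 3)
  expect_equal(nrow(attr(runs, "leftover")), 0)
  # degenerate segmentation: one element takes the whole sequence
  runs1 <- segment_elements(ex[1:5, ], 1)
  expect_length(runs1, 1)
  # heavy blur merges fine elements: explicit error, not a misassignment
  fine <- render_chart(usaf_chart(3, 1:6, px_per_mm = 40))
  d <- apply_degradation(fine$image, fine$truth,
                         degradation_spec(blur_sigma_px = 3))
  exb <- detect_extrema(sample_profile(d$image, truth_line(fine$truth)), 5)
  expect_error(segment_elements(exb, 6), "expected 18")
})

test_that("constructed contrast limits are recovered exactly", {
  for (lim in 1:5) {
    contrast <- ifelse(1:6 <= lim, 2.5, 1.9)
    ch <- render_chart(usaf_chart(2, 1:6, px_per_mm = 72,
                                  contrast = contrast))
    r <- analyze_resolution(ch$image, truth_line(ch$truth), 2, 1:6)
    expect_equal(r$limit$element, lim)
  }
})

test_that("limit_um is non-decreasing under increasing blur", {
  ch <- render_chart(usaf_chart(2, 1:6, px_per_mm = 72))
  line <- truth_line(ch$truth)
  lims <- vapply(c(0, 0.5, 1, 2, 4), function(s) {
    d <- apply_degradation(ch$image, ch$truth,
                           degradation_spec(blur_sigma_px = s))
    analyze_resolution(d$image, line, 2, 1:6)$limit_um
  }, numeric(1))
  expect_true(all(diff(lims) >= 0))
})

test_that("verdicts are robust to +/- 2 px perpendicular endpoint jitter", {
  ch <- render_chart(usaf_chart(2, 1:6, px_per_mm = 72))
  base <- analyze_resolution(ch$image, truth_line(ch$truth), 2, 1:6)
  l0 <- ch$truth$suggested_line
  for (j in c(-2, 2)) {
    line <- line_segment(l0$p0 + c(0, j), l0$p1 + c(0, -j))
    r <- analyze_resolution(ch$image, line, 2, 1:6)
    expect_equal(vapply(r$verdicts, `[[`, logical(1), "passed"),
                 vapply(base$verdicts, `[[`, logical(1), "passed"))
  }
})
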