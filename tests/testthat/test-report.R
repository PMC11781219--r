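write_fixture_set <- function(dir) {
  u <- render_chart(usaf_chart(2, 1:6, px_per_mm = 72))
  write_image(u$image, file.path(dir, "usaf.png"))
  dl <- render_chart(dof_ladder(length_mm = 13, contrast_half_mm = 8))
  write_image(dl$image, file.path(dir, "dof.png"))
  ref <- classic_ref()
  cc <- render_chart(colorchecker_chart(ref))
  write_image(cc$image, file.path(dir, "cc.png"))
  g <- render_chart(grid_chart())
  write_image(g$image, file.path(dir, "grid.png"))
  pts <- g$truth$landmarks_pre
  jsonlite::write_json(
    stats::setNames(lapply(rownames(pts), function(n) pts[n, ]), rownames(pts)),
    file.path(dir, "points.json"))
  ul <- u$truth$suggested_line
  dll <- dl$truth$suggested_line
  list(
    config = list(
      seed = 1, min_prominence = 5,
      resolution = list(image = "usaf.png", line = c(ul$p0, ul$p1),
                        group = 2, elements = 1:6),
      dof = list(image = "dof.png", line = c(dll$p0, dll$p1)),
      color = list(image = "cc.png", reference = "colorchecker_classic_24",
                   layout = list(nrow = 4, ncol = 6, origin = c(10, 10),
                                 pitch = c(50, 50), patch_px = 40)),
      distortion = list(image = "grid.png", points = "points.json",
                        snap = TRUE)),
    usaf = u, dof = dl, color = cc, grid = g)
}

test_that("partial config runs only its block and marks the rest not_run", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir)
  cfg <- list(seed = 1, color = fx$config$color)
  rep <- run_suite(cfg, base_dir = dir)
  expect_equal(rep$results$color$status, "ok")
  expect_equal(rep$results$resolution$status, "not_run")
  expect_equal(rep$results$dof$status, "not_run")
  expect_equal(rep$results$distortion$status, "not_run")
})

test_that("full suite on undegraded fixtures matches ground truth", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir)
  rep <- run_suite(fx$config, base_dir = dir)
  for (nm in names(rep$results)) {
    expect_equal(rep$results[[nm]]$status, "ok", label = nm)
  }
  expect_equal(rep$results$resolution$result$limit$element, 6)
  expect_equal(rep$results$dof$result$dof_mm, 8)
  expect_lte(rep$results$color$result$mean_delta_e, 1)
  expect_lte(abs(rep$results$distortion$result$percent), 0.05)
})

test_that("one failing test does not abort the others", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir)
  cfg <- fx$config
  cfg$resolution$image <- "missing.png"
  rep <- run_suite(cfg, base_dir = dir)
  expect_equal(rep$results$resolution$status, "error")
  expect_match(rep$results$resolution$error, "not found")
  expect_equal(rep$results$dof$status, "ok")
  expect_equal(rep$results$color$status, "ok")
})

test_that("reports are identical across runs modulo timestamp", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir)
  r1 <- run_suite(fx$config, base_dir = dir)
  r2 <- run_suite(fx$config, base_dir = dir)
  strip <- function(r) r[setdiff(names(r), "timestamp")]
  j1 <- jsonlite::toJSON(strip(r1), auto_unbox = TRUE, digits = NA, force = TRUE)
  j2 <- jsonlite::toJSON(strip(r2), auto_unbox = TRUE, digits = NA, force = TRUE)
  expect_identical(j1, j2)
})

test_that("written reports round-trip and the CSV keeps the serialization contract", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(dir)
  rep <- run_suite(fx$config, base_dir = dir)
  out <- file.path(dir, "out")
  paths <- write_report(rep, out)
  expect_true(all(file.exists(paths)))
  back <- jsonlite::read_json(file.path(out, "qa_report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$version, rep$version)
  expect_equal(back$results$dof$result$dof_mm, rep$results$dof$result$dof_mm)
  expect_equal(back$results$distortion$result$percent,
               rep$results$distortion$result$percent)
  csv <- utils::read.csv(file.path(out, "qa_report.csv"))
  expect_named(csv, c("test", "metric", "value"))
  row <- csv[csv$test == "color" & csv$metric == "mean_delta_e_ab", ]
  expect_equal(row$value, rep$results$color$result$mean_delta_e)
})

test_that("an empty report still summarizes to a valid table", {
  rep <- run_suite(list(seed = 1))
  s <- report_summary(rep)
  expect_named(s, c("test", "metric", "value"))
  expect_equal(nrow(s), 0)
})

test_that("yaml and json configs parse to the same analysis inputs", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 3, min_prominence = 4,
              dof = list(image = "dof.png", line = c(0, 10, 400, 10)))
  yaml::write_yaml(cfg, file.path(dir, "c.yaml"))
  jsonlite::write_json(cfg, file.path(dir, "c.json"), auto_unbox = TRUE)
  a <- read_config(file.path(dir, "c.yaml"))
  b <- read_config(file.path(dir, "c.json"))
  expect_equal(a$dof$line, b$dof$line)
  expect_equal(a$min_prominence, b$min_prominence)
})
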