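test_that("phenology templates peak where and how they should", {
  tmpl <- phenology_template("maize", peak_doy = 205, amplitude = 0.6,
                             base_ndvi = 0.15, width_days = 110)
  # peak within 1% of the plateau
  expect_equal(phenology_value(tmpl, 205), 0.75, tolerance = 0.01)
  # off-season baseline
  expect_equal(phenology_value(tmpl, 20), 0.15, tolerance = 1e-3)
  # dense-evaluation oracle: a +10 day shift moves the argmax by +10 +/- 1
  grid <- seq(100, 320, by = 0.1)
  peak0 <- grid[which.max(phenology_value(tmpl, grid, 0))]
  peak10 <- grid[which.max(phenology_value(tmpl, grid, 10))]
  expect_lt(abs((peak10 - peak0) - 10), 1)
  # values bounded
  expect_true(all(abs(phenology_value(tmpl, seq(1, 366))) <= 1))
})

test_that("rice template carries the early-water signal", {
  tm <- default_phenology_templates()
  expect_true(tm$rice$early_water_signal)
  early <- 145
  expect_lt(phenology_value(tm$rice, early),
            tm$rice$base_ndvi)  # flooding depresses NDVI pre-green-up
})

test_that("scene generation is deterministic and honors no-rotation", {
  cfg <- scene_config(grid_rows = 32, grid_cols = 32, n_fields = 16,
                      years = c("2016", "2017", "2018"), rotation_rate = 0,
                      seed = 5)
  a <- generate_scene_series(cfg)
  b <- generate_scene_series(cfg)
  expect_identical(a$scenes[["2017"]]$bands, b$scenes[["2017"]]$bands)
  expect_identical(a$truth$labels, b$truth$labels)
  # rotation_rate 0: labels identical across years
  expect_identical(a$truth$labels[["2016"]], a$truth$labels[["2018"]])
})

test_that("rotation changes labels at roughly the configured rate", {
  cfg <- scene_config(grid_rows = 60, grid_cols = 60, n_fields = 400,
                      years = c("2017", "2018"), rotation_rate = 0.3,
                      seed = 9)
  sim <- generate_scene_series(cfg)
  changed <- mean(sim$truth$labels[["2017"]] != sim$truth$labels[["2018"]])
  expect_gt(changed, 0.2)
  expect_lt(changed, 0.4)
})

test_that("field shares follow crop proportions at 400 fields (+/- 4 points)", {
  cfg <- scene_config(grid_rows = 100, grid_cols = 100, n_fields = 400,
                      crop_proportions = c(0.5, 0.1, 0.25, 0.15),
                      years = "2018", seed = 3)
  sim <- generate_scene_series(cfg)
  lab <- sim$truth$labels[["2018"]]
  fid <- sim$truth$field_id
  crop_of_field <- tapply(as.vector(lab), as.vector(fid), function(v) v[1])
  share <- prop.table(table(factor(crop_of_field, levels = 1:4)))
  expect_true(all(abs(share - c(0.5, 0.1, 0.25, 0.15)) <= 0.04))
})

test_that("masked observations are NaN-poisoned and flagged invalid", {
  sim <- small_scene(seed = 21, missing_rate = 0.3)
  st <- sim$scenes[["2017"]]
  expect_true(all(is.nan(st$bands[, , , 1][!st$valid])))
  expect_true(all(is.finite(st$bands[, , , 1][st$valid])))
})

test_that("no-noise, no-rotation pixels differ across years only by phase", {
  cfg <- scene_config(grid_rows = 24, grid_cols = 24, n_fields = 9,
                      years = c("2017", "2018"), rotation_rate = 0,
                      noise_sd = 0, missing_rate = 0, phase_shift_sd_days = 0,
                      seed = 2)
  sim <- generate_scene_series(cfg)
  expect_equal(sim$scenes[["2017"]]$bands, sim$scenes[["2018"]]$bands,
               tolerance = 1e-12)
})

test_that("grid too small for the field tiling errors", {
  expect_error(generate_scene_series(
    scene_config(grid_rows = 5, grid_cols = 5, n_fields = 100, years = "2018")),
    "too small")
})

test_that("config invariants are enforced", {
  expect_error(scene_config(crop_proportions = c(0.5, 0.5, 0.1, 0.1)),
               "sum to 1")
  expect_error(scene_config(rotation_rate = 1.2), "rotation_rate")
  expect_error(scene_config(doy_grid = c(150, 150, 160)), "increasing")
})

test_that("field surveys honor labels, spacing and determinism", {
  sim <- small_scene(seed = 4)
  s1 <- draw_field_samples(sim$truth, "2017", 10, min_spacing_px = 6,
                           seed = 8)
  s2 <- draw_field_samples(sim$truth, "2017", 10, min_spacing_px = 6,
                           seed = 8)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 40)
  # labels agree with the truth
  expect_identical(true_class_at(sim$truth, "2017", s1), s1$class)
  # no two samples within a 5x5 window of each other (Chebyshev >= 6)
  cheb <- outer(seq_len(nrow(s1)), seq_len(nrow(s1)), function(i, j)
    pmax(abs(s1$row[i] - s1$row[j]), abs(s1$col[i] - s1$col[j])))
  diag(cheb) <- Inf
  expect_gte(min(cheb), 6)
})

test_that("exhausted classes reduce the count with a warning", {
  sim <- small_scene(seed = 4, grid = 24, n_fields = 9)
  w <- capture_warnings(s <- draw_field_samples(sim$truth, "2017", 500,
                                                seed = 1))
  expect_true(any(grepl("only", w)))
  expect_lt(nrow(s), 2000)
})
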