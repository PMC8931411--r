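test_that("dtw_distance matches hand-derived alignments", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0, 0), c(1, 1, 1)), 3)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  expect_error(dtw_distance(numeric(0), 1), "empty|non-empty")
})

test_that("dtw_distance equals brute-force path enumeration and is symmetric", {
  set.seed(1)
  for (trial in 1:60) {
    a <- runif(sample(1:8, 1), 0, 2)
    b <- runif(sample(1:8, 1), 0, 2)
    expect_identical(dtw_distance(a, b), dtw_brute_force(a, b))
    expect_identical(dtw_distance(a, b), dtw_distance(b, a))
  }
})

test_that("similarity decays correctly with distance", {
  expect_equal(similarity_from_distance(0, 100, 100), 1)
  expect_equal(similarity_from_distance(56, 100, 100), 0.5712, tolerance = 1e-4)
  expect_gt(similarity_from_distance(10, 50, 100),
            similarity_from_distance(20, 50, 100))
  expect_error(similarity_from_distance(-1, 10, 10), ">= 0")
})

test_that("pixel similarity averages per-feature scores over shared features", {
  doys <- seq(139, 294, by = 8)
  lin <- function(a, b) fit_curve(make_series(doys, a + b * doys), "cubic")
  mk <- function(k) list(nir = lin(0.3, 1e-4 * k), ndvi = lin(0.5, 2e-4 * k),
                         ndwi = lin(-0.3, 1e-4 * k))
  a <- mk(1)
  expect_equal(pixel_similarity(a, a)$similarity, 1)
  b <- mk(3)
  sc <- pixel_similarity(a, b)
  expect_equal(sc$similarity, mean(sc$per_feature))
  expect_length(sc$per_feature, 3)
  # partial feature overlap: mean over the remaining features
  b2 <- b
  b2$ndwi <- NULL
  sc2 <- pixel_similarity(a, b2)
  expect_length(sc2$per_feature, 2)
  expect_equal(sc2$similarity, mean(sc$per_feature[c("nir", "ndvi")]))
  # no shared usable feature
  expect_error(pixel_similarity(a, list()), "incomparable")
})

test_that("same-crop pixels score higher than different-crop pixels", {
  sim <- small_scene(seed = 17, noise_sd = 0.02)
  s <- suppressWarnings(draw_field_samples(sim$truth, "2017", 10, seed = 2))
  models <- c(nir = "cubic", ndvi = "harmonic5", ndwi = "cubic")
  lab <- sim$truth$labels[["2018"]]
  st17 <- sim$scenes[["2017"]]; st18 <- sim$scenes[["2018"]]
  wins <- 0; trials <- 0
  set.seed(3)
  for (i in seq_len(nrow(s))) {
    hcur <- fit_pixel_curves(st17, s$row[i], s$col[i], models)
    if (any(vapply(hcur, is.null, logical(1)))) next
    cls <- match(s$class[i], sim$truth$classes)
    same_idx <- which(lab == cls); diff_idx <- which(lab != cls)
    pick <- function(idx) {
      j <- sample(idx, 1)
      c((j - 1) %% nrow(lab), (j - 1) %/% nrow(lab))
    }
    for (rep in 1:3) {
      p1 <- pick(same_idx); p2 <- pick(diff_idx)
      c1 <- fit_pixel_curves(st18, p1[1], p1[2], models)
      c2 <- fit_pixel_curves(st18, p2[1], p2[2], models)
      if (any(vapply(c(c1, c2), is.null, logical(1)))) next
      s1 <- pixel_similarity(hcur, c1)$similarity
      s2 <- pixel_similarity(hcur, c2)$similarity
      trials <- trials + 1
      if (s1 > s2) wins <- wins + 1
    }
  }
  expect_gt(trials, 15)
  expect_gte(wins / trials, 0.9)
})

test_that("potential-sample selection keeps at most one pixel per sample", {
  sim <- small_scene(seed = 23)
  s <- suppressWarnings(draw_field_samples(sim$truth, "2017", 8, seed = 5))
  models <- c(nir = "cubic", ndvi = "harmonic5", ndwi = "cubic")
  pot <- select_potential_samples(s, sim$scenes[["2017"]],
                                  sim$scenes[["2018"]], models)
  expect_lte(nrow(pot$samples), nrow(s))
  expect_equal(nrow(pot$samples) + nrow(pot$skipped), nrow(s))
  expect_true(all(pot$samples$provenance == "potential"))
  expect_true(all(abs(pot$samples$offset_row) <= 2))
  expect_true(all(abs(pot$samples$offset_col) <= 2))
  expect_true(all(pot$samples$similarity > 0 & pot$samples$similarity <= 1))
  # inherited labels
  src <- s[match(pot$samples$source_id, s$id), ]
  expect_identical(pot$samples$class, src$class)
  # clustering features aligned with samples
  expect_equal(nrow(pot$features), nrow(pot$samples))
  expect_equal(ncol(pot$features), 21)
})

test_that("fully masked neighborhoods are skipped and logged", {
  sim <- small_scene(seed = 23, grid = 24, n_fields = 9)
  st18 <- sim$scenes[["2018"]]
  s <- suppressWarnings(draw_field_samples(sim$truth, "2017", 2, seed = 5))[1:2]
  # blot out every date around the first sample in the target year
  r <- s$row[1] + 1; c <- s$col[1] + 1
  rows <- max(1, r - 2):min(24, r + 2); cols <- max(1, c - 2):min(24, c + 2)
  st18$valid[rows, cols, ] <- FALSE
  st18$bands[rows, cols, , ] <- NaN
  models <- c(nir = "cubic", ndvi = "harmonic5", ndwi = "cubic")
  pot <- select_potential_samples(s, sim$scenes[["2017"]], st18, models)
  expect_true(s$id[1] %in% pot$skipped$id)
  expect_false(s$id[1] %in% pot$samples$source_id)
})

test_that("window argument is validated", {
  sim <- small_scene(seed = 23, grid = 16, n_fields = 4)
  s <- suppressWarnings(draw_field_samples(sim$truth, "2017", 1, seed = 5))
  expect_error(select_potential_samples(
    s, sim$scenes[["2017"]], sim$scenes[["2018"]],
    c(ndvi = "cubic"), window = 4), "odd")
})
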