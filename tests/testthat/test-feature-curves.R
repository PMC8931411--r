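test_that("spectral indices follow their definitions and mask degeneracy", {
  bands <- array(0, c(1, 1, 3, 4))
  # dates: nir=red; nir=0.5/red=0.1; green=0.2/nir=0.6
  bands[1, 1, , ] <- rbind(c(0.1, 0.3, 0.2, 0.2),
                           c(0.1, 0.3, 0.1, 0.5),
                           c(0.1, 0.2, 0.1, 0.6))
  st <- new_scene_stack("2018", c(150L, 160L, 170L), bands,
                        array(TRUE, c(1, 1, 3)))
  ndvi <- compute_index(st, "ndvi")
  expect_equal(ndvi$values[1, 1, ], c(0, 0.4 / 0.6, 0.5 / 0.7))
  ndwi <- compute_index(st, "ndwi")
  expect_equal(ndwi$values[1, 1, 3], -0.4 / 0.8)
  # zero denominator is masked, not propagated
  bands[1, 1, 1, ] <- c(0.1, 0.3, 0, 0)
  st0 <- new_scene_stack("2018", c(150L, 160L, 170L), bands,
                         array(TRUE, c(1, 1, 3)))
  n0 <- compute_index(st0, "ndvi")
  expect_false(n0$valid[1, 1, 1])
  expect_true(is.nan(n0$values[1, 1, 1]))
})

test_that("fit_statistics reproduces the sum-of-squares identities", {
  st <- fit_statistics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(st$sse, 1)
  expect_equal(st$sst, 2)
  expect_equal(st$ssr, st$sst - st$sse)
  expect_equal(st$r2, 0.5)
  expect_equal(st$rmse, sqrt(1 / 3), tolerance = 1e-4)
  # perfect fit and null model
  y <- rnorm(10)
  expect_equal(fit_statistics(y, y)$r2, 1)
  expect_equal(fit_statistics(y, y)$rmse, 0)
  expect_equal(fit_statistics(y, rep(mean(y), 10))$r2, 0)
  expect_error(fit_statistics(1:3, 1:4), "length")
})

test_that("cubic and harmonic fits recover noiseless generators exactly", {
  doys <- seq(140, 290, by = 10)
  # cubic
  true_c <- c(0.2, 3e-3, -2e-5, 4e-8)
  y <- true_c[1] + true_c[2] * doys + true_c[3] * doys^2 + true_c[4] * doys^3
  cur <- fit_curve(make_series(doys, y), "cubic")
  expect_equal(cur$coefficients, true_c, tolerance = 1e-8)
  expect_equal(cur$fit_stats$r2, 1, tolerance = 1e-12)
  # constant series
  cc <- fit_curve(make_series(doys, rep(0.4, length(doys))), "cubic")
  expect_equal(cc$coefficients, c(0.4, 0, 0, 0), tolerance = 1e-10)
  expect_equal(cc$fit_stats$rmse, 0, tolerance = 1e-10)
  # harmonic
  w <- 2 * pi / 365
  true_h <- c(0.3, -0.2, 0.25, 0.05, -0.1)
  yh <- drop(cbind(1, cos(w * doys), sin(w * doys), cos(2 * w * doys),
                   sin(2 * w * doys)) %*% true_h)
  ch <- fit_curve(make_series(doys, yh), "harmonic5")
  expect_equal(ch$coefficients, true_h, tolerance = 1e-8)
  expect_equal(ch$fit_stats$r2, 1, tolerance = 1e-12)
})

test_that("gaussian fit matches the grid-search oracle and the generator", {
  doys <- seq(139, 294, by = 8)
  y <- 0.8 * exp(-((doys - 200) / 30)^2)
  cur <- fit_curve(make_series(doys, y), "gaussian")
  expect_true(cur$ok)
  expect_equal(cur$coefficients, c(0.8, 200, 30), tolerance = 1e-6)
  oracle <- gaussian_grid_oracle(doys, y)
  expect_equal(cur$coefficients, oracle, tolerance = 1e-4)
})

test_that("fitting contracts: minimum observations and validity masking", {
  expect_error(fit_curve(make_series(1:5, rnorm(5)), "cubic"), "insufficient")
  s <- make_series(seq(140, 250, by = 10), rnorm(12),
                   valid = rep(c(TRUE, FALSE), c(5, 7)))
  expect_error(fit_curve(s, "harmonic5"), "insufficient")
  # exactly 6 valid observations are enough
  s6 <- make_series(seq(140, 250, by = 10), rnorm(12),
                    valid = rep(c(TRUE, FALSE), 6))
  expect_s3_class(fit_curve(s6, "harmonic5"), "feature_curve")
  # invalid entries are ignored, not used
  doys <- seq(140, 290, by = 10)
  y <- 0.1 + 0.002 * doys
  y_poisoned <- y
  y_poisoned[3] <- 99
  s2 <- make_series(doys, y_poisoned, valid = replace(rep(TRUE, 16), 3, FALSE))
  cur <- fit_curve(s2, "cubic")
  expect_equal(eval_curve(cur, 200), 0.1 + 0.002 * 200, tolerance = 1e-8)
})

test_that("linear-model residuals are orthogonal to the design columns", {
  set.seed(42)
  for (rep in 1:5) {
    doys <- sort(sample(139:294, 18))
    y <- runif(1) + 0.5 * sin(doys / 40) + rnorm(18, 0, 0.05)
    s <- make_series(doys, y)
    cur <- fit_curve(s, "harmonic5")
    w <- 2 * pi / 365
    X <- cbind(1, cos(w * doys), sin(w * doys), cos(2 * w * doys),
               sin(2 * w * doys))
    r <- y - eval_curve(cur, doys)
    expect_lt(max(abs(crossprod(X, r))), 1e-6)
    cur3 <- fit_curve(s, "cubic")
    r3 <- y - eval_curve(cur3, doys)
    u <- (doys - mean(range(doys))) / (diff(range(doys)) / 2)
    expect_lt(max(abs(crossprod(cbind(1, u, u^2, u^3), r3))), 1e-6)
    # training R^2 of intercept models is non-negative
    expect_gte(cur$fit_stats$r2, 0)
    expect_gte(cur3$fit_stats$r2, 0)
  }
})

test_that("sample_curve spans the domain at exactly equal intervals", {
  doys <- seq(150, 280, by = 10)
  y <- 0.1 + 0.003 * doys
  cur <- fit_curve(make_series(doys, y), "cubic")
  v <- sample_curve(cur, 100)
  expect_length(v, 100)
  expect_equal(v[1], eval_curve(cur, 150))
  expect_equal(v[100], eval_curve(cur, 280))
  grid <- seq(150, 280, length.out = 100)
  expect_lt(max(abs(diff(grid) - diff(grid)[1])), 1e-9)
  # linear generator -> exactly linear resampling
  expect_equal(v, 0.1 + 0.003 * grid, tolerance = 1e-8)
  # noiseless generating data reproduced at observation DOYs
  expect_equal(eval_curve(cur, doys), y, tolerance = 1e-6)
})

test_that("model selection picks the generating family and refits on all", {
  w <- 2 * pi / 365
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    doys <- seq(139, 294, by = 8)
    # strong 2nd-harmonic content so no cubic can shadow the generator
    truth <- drop(cbind(1, cos(w * doys), sin(w * doys), cos(2 * w * doys),
                        sin(2 * w * doys)) %*% c(0.4, -0.3, 0.2, 0.3, -0.25))
    y <- truth + rnorm(length(doys), 0, 0.005)
    sel <- select_best_model(make_series(doys, y))
    if (sel$model == "harmonic5") hits <- hits + 1
    expect_s3_class(sel$curve, "feature_curve")
    expect_false(is.null(sel$curve$test_stats))
  }
  expect_gte(hits, 18)
})

test_that("model selection degenerates gracefully and enforces n >= 9", {
  expect_error(select_best_model(make_series(seq(140, 200, 10), rnorm(7))),
               ">= 9")
  # single surviving candidate: constant-ish data kills gaussian convergence
  # rarely; instead verify the tie/fallback path via select_feature_models
  doys <- seq(139, 294, by = 8)
  y <- 0.2 + 0.001 * doys + rnorm(length(doys), 0, 0.005)
  sel <- select_best_model(make_series(doys, y))
  expect_true(sel$model %in% c("cubic", "harmonic5", "gaussian"))
})

test_that("per-feature winners are chosen from pooled sample series", {
  sim <- small_scene(seed = 31, grid = 32, n_fields = 16)
  s <- suppressWarnings(draw_field_samples(sim$truth, "2017", 6, seed = 3))
  sel <- select_feature_models(sample_series(sim$scenes[["2017"]], s))
  expect_named(sel$models, c("nir", "ndvi", "ndwi"))
  expect_true(all(sel$models %in% c("cubic", "harmonic5", "gaussian")))
  expect_equal(nrow(sel$summary), 9)
})
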