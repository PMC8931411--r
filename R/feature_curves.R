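#' Compute a normalized-difference index for a scene stack
#'
#' NDVI = (NIR - Red)/(NIR + Red); NDWI (green/NIR McFeeters form, suitable
#' for sensors without SWIR) = (Green - NIR)/(Green + NIR). Cells whose
#' denominator is zero are masked invalid.
#'
#' @param stack a `scene_stack`.
#' @param which `"ndvi"` or `"ndwi"` (case-insensitive).
#' @return list with `values` (array `[rows, cols, dates]`) and `valid`
#'   (logical array of the same shape).
#' @export
compute_index <- function(stack, which = c("ndvi", "ndwi")) {
  which <- match.arg(tolower(which[1]), c("ndvi", "ndwi"))
  bi <- function(b) {
    v <- stack$bands[, , , match(b, stack$band_names), drop = FALSE]
    dim(v) <- dim(v)[1:3]
    v
  }
  if (which == "ndvi") {
    num <- bi("nir") - bi("red"); den <- bi("nir") + bi("red")
  } else {
    num <- bi("green") - bi("nir"); den <- bi("green") + bi("nir")
  }
  valid <- stack$valid & is.finite(den) & den != 0
  v <- num / den
  v[!valid] <- NaN
  list(values = v, valid = valid)
}

#' Extract one pixel's feature time series
#'
#' @param stack a `scene_stack`.
#' @param row,col 0-based pixel indices.
#' @param feature band name or `"ndvi"`/`"ndwi"`.
#' @return a `feature_series`: list `(feature, doys, values, valid)`.
#' @export
pixel_feature_series <- function(stack, row, col, feature) {
  feature <- norm_feature(feature)
  r <- row + 1L; c <- col + 1L
  valid <- stack$valid[r, c, ]
  if (feature %in% stack$band_names) {
    v <- stack$bands[r, c, , match(feature, stack$band_names)]
  } else {
    b <- function(nm) stack$bands[r, c, , match(nm, stack$band_names)]
    if (feature == "ndvi") { num <- b("nir") - b("red"); den <- b("nir") + b("red") }
    else                   { num <- b("green") - b("nir"); den <- b("green") + b("nir") }
    valid <- valid & is.finite(den) & den != 0
    v <- num / den
  }
  v[!valid] <- NaN
  structure(list(feature = feature, doys = stack$dates, values = v,
                 valid = valid), class = "feature_series")
}

#' Goodness-of-fit statistics
#'
#' `SSE = sum((y - f)^2)`, `SST = sum((y - mean(y))^2)`, `SSR = SST - SSE`,
#' `R^2 = 1 - SSE/SST`, `RMSE = sqrt(SSE/m)` (root-mean-square residual
#' against the predictions). When `SST = 0` (constant observations) `R^2` is
#' defined as 1 for a numerically perfect fit and 0 otherwise.
#'
#' @param y observed values.
#' @param f predicted values (same length).
#' @return a `fit_statistics` list `(sse, sst, ssr, r2, rmse, m)`.
#' @export
fit_statistics <- function(y, f) {
  if (length(y) != length(f) || length(y) == 0)
    stop("y and f must have equal, non-zero length")
  m <- length(y)
  sse <- sum((y - f)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst
        else if (sse <= .Machine$double.eps * max(1, sum(y * y))) 1 else 0
  structure(list(sse = sse, sst = sst, ssr = sst - sse, r2 = r2,
                 rmse = sqrt(sse / m), m = m), class = "fit_statistics")
}

# polynomial basis is built on u = (t - tc)/sc for conditioning; coefficients
# are reported in the raw (1, t, t^2, t^3) basis
.cubic_raw_coefs <- function(b, tc, sc) {
  raw <- numeric(4)
  for (k in 0:3) {
    for (j in 0:k) {
      raw[j + 1] <- raw[j + 1] + b[k + 1] * choose(k, j) * (-tc)^(k - j) / sc^k
    }
  }
  raw
}

.harmonic_design <- function(t) {
  w <- 2 * pi / 365
  cbind(1, cos(w * t), sin(w * t), cos(2 * w * t), sin(2 * w * t))
}

#' Fit a feature curve to one pixel's series
#'
#' Three candidate models of seasonal trajectories:
#' * `cubic` — ordinary least squares on `(1, t, t^2, t^3)`;
#' * `harmonic5` — OLS on `(1, cos wt, sin wt, cos 2wt, sin 2wt)` with
#'   `w = 2*pi/365` (annual period);
#' * `gaussian` — nonlinear least squares on `a*exp(-((t-b)/c)^2)` via
#'   Levenberg-Marquardt with moment-based initialization.
#'
#' `t` is the day of year. At least 6 valid observations are required (the
#' largest model has 5 unknowns). A Gaussian fit that fails to converge is
#' returned with `ok = FALSE` and must not be used.
#'
#' @param series a `feature_series`.
#' @param model one of `"cubic"`, `"harmonic5"`, `"gaussian"`.
#' @param min_obs minimum number of valid observations.
#' @return a `feature_curve`: list
#'   `(feature, model, coefficients, doy_domain, fit_stats, test_stats, ok)`.
#' @export
fit_curve <- function(series, model = c("cubic", "harmonic5", "gaussian"),
                      min_obs = 6L) {
  model <- match.arg(model)
  keep <- series$valid & is.finite(series$values)
  t <- as.numeric(series$doys[keep]); y <- series$values[keep]
  if (length(t) < min_obs)
    stop(sprintf("insufficient data: %d valid observations (< %d) for %s",
                 length(t), min_obs, series$feature))
  ok <- TRUE
  if (model == "cubic") {
    tc <- mean(range(t)); sc <- max(diff(range(t)) / 2, 1)
    u <- (t - tc) / sc
    fit <- stats::lm.fit(cbind(1, u, u^2, u^3), y)
    coefs <- .cubic_raw_coefs(unname(fit$coefficients), tc, sc)
    pred <- y - fit$residuals
  } else if (model == "harmonic5") {
    fit <- stats::lm.fit(.harmonic_design(t), y)
    coefs <- unname(fit$coefficients)
    pred <- y - fit$residuals
  } else {
    res <- .fit_gaussian_cpp(t, y)
    coefs <- res[1:3]
    ok <- res[5] == 1 && all(is.finite(coefs))
    pred <- coefs[1] * exp(-((t - coefs[2]) / coefs[3])^2)
  }
  if (any(!is.finite(coefs))) { ok <- FALSE; coefs[!is.finite(coefs)] <- 0 }
  structure(list(feature = series$feature, model = model,
                 coefficients = coefs, doy_domain = range(t),
                 fit_stats = fit_statistics(y, pred), test_stats = NULL,
                 ok = ok),
            class = "feature_curve")
}

#' Evaluate a fitted feature curve at given DOYs
#'
#' @param curve a `feature_curve`.
#' @param doys days of year (numeric vector).
#' @return predicted feature values.
#' @export
eval_curve <- function(curve, doys) {
  cf <- curve$coefficients
  switch(curve$model,
    cubic = cf[1] + cf[2] * doys + cf[3] * doys^2 + cf[4] * doys^3,
    harmonic5 = drop(.harmonic_design(doys) %*% cf),
    gaussian = cf[1] * exp(-((doys - cf[2]) / cf[3])^2),
    stop("unknown model: ", curve$model))
}

#' Resample a fitted curve at equal intervals
#'
#' Evaluates the curve at `n` equally spaced DOYs spanning its fitted domain
#' inclusively; these resampled "scattered points" are the sequences compared
#' by dynamic time warping.
#'
#' @param curve a `feature_curve`.
#' @param n number of points (default 100).
#' @return numeric vector of length `n`.
#' @export
sample_curve <- function(curve, n = 100L) {
  eval_curve(curve, seq(curve$doy_domain[1], curve$doy_domain[2],
                        length.out = n))
}

# every third observation (chronological order) goes to the test third
.split_23 <- function(n) {
  test <- seq(3L, n, by = 3L)
  list(train = setdiff(seq_len(n), test), test = test)
}

.subset_series <- function(series, idx_valid) {
  keep <- which(series$valid & is.finite(series$values))
  sel <- keep[idx_valid]
  structure(list(feature = series$feature, doys = series$doys[sel],
                 values = series$values[sel],
                 valid = rep(TRUE, length(sel))), class = "feature_series")
}

#' Select the best curve model for a series
#'
#' Splits the valid observations 2:1 (chronologically stratified: every third
#' observation in DOY order is held out), fits each candidate model on the
#' two-thirds, scores it on the held-out third, and picks the highest test
#' `R^2` (ties: lower test RMSE, then the fixed order cubic, harmonic5,
#' gaussian). The winner is refit on all points.
#'
#' @param series a `feature_series` with at least 9 valid observations.
#' @param split_seed accepted for interface stability; unused because the
#'   split is chronological, hence deterministic.
#' @return list `(model, curve, scores)` where `curve` carries `test_stats`
#'   from the held-out third and `scores` is a data.table of per-candidate
#'   test metrics.
#' @export
select_best_model <- function(series, split_seed = NULL) {
  keep <- series$valid & is.finite(series$values)
  n <- sum(keep)
  if (n < 9) stop("model selection needs >= 9 valid observations, got ", n)
  sp <- .split_23(n)
  tr <- .subset_series(series, sp$train)
  te <- .subset_series(series, sp$test)
  rows <- lapply(CURVE_MODELS, function(m) {
    cur <- tryCatch(fit_curve(tr, m, min_obs = 6L), error = function(e) NULL)
    if (is.null(cur) || !cur$ok)
      return(data.table::data.table(model = m, r2_test = NA_real_,
                                    rmse_test = NA_real_))
    st <- fit_statistics(te$values, eval_curve(cur, te$doys))
    data.table::data.table(model = m, r2_test = st$r2, rmse_test = st$rmse)
  })
  scores <- data.table::rbindlist(rows)
  usable <- which(is.finite(scores$r2_test))
  if (!length(usable)) stop("all candidate models failed to fit")
  ord <- usable[order(-scores$r2_test[usable], scores$rmse_test[usable],
                      usable)]
  winner <- scores$model[ord[1]]
  full <- fit_curve(series, winner)
  te_stats <- fit_statistics(te$values, eval_curve(full, te$doys))
  full$test_stats <- te_stats
  list(model = winner, curve = full, scores = scores)
}

#' Select one winning model per feature from pooled sample series
#'
#' Applies the 2:1 split-and-score of [select_best_model()] to every
#' historical sample's series of each feature, averages the held-out `R^2`
#' (and RMSE) per candidate over samples, and declares one winner per feature
#' (ties as in [select_best_model()]). Mirrors selecting a single model per
#' feature on pooled field samples rather than per pixel.
#'
#' @param series_by_feature named list (feature -> list of `feature_series`).
#' @return list with `models` (named character: feature -> model) and
#'   `summary` (data.table: feature, model, mean_r2_test, mean_rmse_test, n).
#' @export
select_feature_models <- function(series_by_feature) {
  rows <- list()
  models <- character(0)
  for (feat in names(series_by_feature)) {
    per_model <- lapply(CURVE_MODELS, function(m) c(r2 = NA, rmse = NA))
    acc <- list()
    for (m in CURVE_MODELS) acc[[m]] <- list(r2 = c(), rmse = c())
    for (s in series_by_feature[[feat]]) {
      n <- sum(s$valid & is.finite(s$values))
      if (n < 9) next
      sp <- .split_23(n)
      tr <- .subset_series(s, sp$train); te <- .subset_series(s, sp$test)
      for (m in CURVE_MODELS) {
        cur <- tryCatch(fit_curve(tr, m, min_obs = 6L),
                        error = function(e) NULL)
        if (is.null(cur) || !cur$ok) next
        st <- fit_statistics(te$values, eval_curve(cur, te$doys))
        acc[[m]]$r2 <- c(acc[[m]]$r2, st$r2)
        acc[[m]]$rmse <- c(acc[[m]]$rmse, st$rmse)
      }
    }
    tab <- data.table::rbindlist(lapply(CURVE_MODELS, function(m) {
      data.table::data.table(
        feature = feat, model = m,
        mean_r2_test = if (length(acc[[m]]$r2)) mean(acc[[m]]$r2) else NA_real_,
        mean_rmse_test = if (length(acc[[m]]$rmse)) mean(acc[[m]]$rmse)
                         else NA_real_,
        n = length(acc[[m]]$r2))
    }))
    usable <- which(is.finite(tab$mean_r2_test))
    if (!length(usable))
      stop("no candidate model usable for feature ", feat)
    ord <- usable[order(-tab$mean_r2_test[usable], tab$mean_rmse_test[usable],
                        usable)]
    models[feat] <- tab$model[ord[1]]
    rows[[feat]] <- tab
  }
  list(models = models, summary = data.table::rbindlist(rows))
}

#' Fit the selected curve for each feature at one pixel
#'
#' @param stack a `scene_stack`.
#' @param row,col 0-based pixel indices.
#' @param feature_models named character vector (feature -> model), e.g. the
#'   `models` element of [select_feature_models()].
#' @param min_obs minimum valid observations per feature.
#' @return named list of `feature_curve` (entries `NULL` when the pixel is
#'   ineligible for that feature or the fit failed).
#' @export
fit_pixel_curves <- function(stack, row, col, feature_models, min_obs = 6L) {
  out <- setNames(vector("list", length(feature_models)),
                  names(feature_models))
  for (feat in names(feature_models)) {
    s <- pixel_feature_series(stack, row, col, feat)
    if (sum(s$valid & is.finite(s$values)) < min_obs) next
    cur <- tryCatch(fit_curve(s, feature_models[[feat]], min_obs = min_obs),
                    error = function(e) NULL)
    if (!is.null(cur) && cur$ok) out[[feat]] <- cur
  }
  out
}
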