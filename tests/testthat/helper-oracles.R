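# Independent oracles used by the test suite. Each reimplements the quantity
# it checks from first principles and stays clear of the package's own code
# paths.

# DTW by exhaustive enumeration of all monotone warping paths (no dynamic
# programming): the cost of aligning a[1..i] with b[1..j] is explored
# recursively over the three predecessor moves. Exponential; fine for n <= 8.
dtw_brute_force <- function(a, b) {
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost + best
  }
  rec(length(a), length(b))
}

# Direct transcription of the silhouette equations: a(i) mean within-cluster
# dissimilarity, b(i) = min over other clusters of the mean dissimilarity,
# S(i) = (b - a)/max(a, b), SC = mean S(i). Singletons get S(i) = 0.
silhouette_brute_force <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    mine <- setdiff(which(labels == labels[i]), i)
    if (!length(mine)) { s[i] <- 0; next }
    a <- mean(vapply(mine, function(j) d(i, j), numeric(1)))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(vapply(which(labels == g), function(j) d(i, j), numeric(1)))
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Gaussian least squares by coarse grid search over (b, c) with the
# conditionally optimal a solved in closed form, refined with Nelder-Mead.
gaussian_grid_oracle <- function(t, y) {
  sse_abc <- function(p) sum((y - p[1] * exp(-((t - p[2]) / p[3])^2))^2)
  best <- NULL
  for (b in seq(min(t), max(t), length.out = 40)) {
    for (c in seq(5, diff(range(t)), length.out = 40)) {
      e <- exp(-((t - b) / c)^2)
      a <- sum(y * e) / sum(e * e)
      s <- sse_abc(c(a, b, c))
      if (is.null(best) || s < best$sse) best <- list(p = c(a, b, c), sse = s)
    }
  }
  fit <- stats::optim(best$p, sse_abc, control = list(reltol = 1e-15,
                                                     maxit = 5000))
  fit <- stats::optim(fit$par, sse_abc, control = list(reltol = 1e-15,
                                                      maxit = 5000))
  fit$par
}

# feature_series construction shorthand
make_series <- function(doys, values, feature = "ndvi",
                        valid = rep(TRUE, length(doys))) {
  structure(list(feature = feature, doys = doys, values = values,
                 valid = valid), class = "feature_series")
}

default_feats <- c(nir = "nir", ndvi = "ndvi", ndwi = "ndwi")

# small standard scene shared by several tests
small_scene <- function(seed = 7, rotation_rate = 0, noise_sd = 0.02,
                        grid = 48, n_fields = 36, missing_rate = 0.1,
                        phase_shift_sd_days = 10) {
  cfg <- scene_config(grid_rows = grid, grid_cols = grid, n_fields = n_fields,
                      years = c("2017", "2018"), rotation_rate = rotation_rate,
                      missing_rate = missing_rate, noise_sd = noise_sd,
                      phase_shift_sd_days = phase_shift_sd_days, seed = seed)
  generate_scene_series(cfg)
}

# pooled per-feature series of a sample table, for model selection
sample_series <- function(stack, samples,
                          features = default_feats) {
  lapply(features, function(f)
    lapply(seq_len(nrow(samples)), function(i)
      pixel_feature_series(stack, samples$row[i], samples$col[i], f)))
}

true_class_at <- function(truth, year, samples) {
  lab <- truth$labels[[year]]
  truth$classes[lab[cbind(samples$row + 1, samples$col + 1)]]
}
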