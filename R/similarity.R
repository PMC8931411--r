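#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW between two numeric sequences with local
#' cost `|a_i - b_j|` and the symmetric match/insert/delete step pattern; no
#' warping window, no normalization inside the recursion. DTW absorbs
#' phenological shift between years: the same curve sown earlier or later
#' still aligns at low cost.
#'
#' @param a,b non-empty numeric vectors.
#' @return cumulative alignment cost (>= 0).
#' @export
dtw_distance <- function(a, b) {
  if (!length(a) || !length(b)) stop("dtw_distance: empty input")
  .dtw_distance_cpp(as.numeric(a), as.numeric(b))
}

#' Similarity from a DTW distance
#'
#' `S = exp(-D / max(m, n))` where `m`, `n` are the two sequence lengths;
#' strictly decreasing in `D`, with `S(0) = 1` and `S in (0, 1]`.
#'
#' @param d DTW distance (>= 0).
#' @param m,n sequence lengths (>= 1).
#' @return similarity in `(0, 1]`.
#' @export
similarity_from_distance <- function(d, m, n) {
  if (any(d < 0)) stop("distance must be >= 0")
  if (any(m < 1) || any(n < 1)) stop("lengths must be >= 1")
  exp(-d / pmax(m, n))
}

#' Curve-set similarity between two pixels
#'
#' For every feature usable at both pixels (among the similarity features,
#' default NIR/NDVI/NDWI): resample both fitted curves at `n_points` equal
#' intervals over their own DOY domains, compute the DTW distance, convert to
#' similarity with `m = n = n_points`, then aggregate by the unweighted mean
#' over shared features.
#'
#' @param hist_curves,target_curves named lists of `feature_curve` (entries
#'   may be `NULL` for unusable features).
#' @param n_points resampling length (default 100).
#' @param features features considered (default `c("nir","ndvi","ndwi")`).
#' @return a `similarity_score`: list
#'   `(similarity, per_feature, dtw_distance, len_a, len_b)` where
#'   `dtw_distance` is the per-feature distance vector.
#' @export
pixel_similarity <- function(hist_curves, target_curves, n_points = 100L,
                             features = SIMILARITY_FEATURES) {
  usable <- function(cs, f) !is.null(cs[[f]]) && isTRUE(cs[[f]]$ok)
  shared <- features[vapply(features, function(f)
    usable(hist_curves, f) && usable(target_curves, f), logical(1))]
  if (!length(shared))
    stop("incomparable pixels: no shared usable feature")
  d <- vapply(shared, function(f)
    dtw_distance(sample_curve(hist_curves[[f]], n_points),
                 sample_curve(target_curves[[f]], n_points)), numeric(1))
  s <- similarity_from_distance(d, n_points, n_points)
  structure(list(similarity = mean(s), per_feature = s, dtw_distance = d,
                 len_a = n_points, len_b = n_points),
            class = "similarity_score")
}

#' Transfer historical samples to a target year as potential samples
#'
#' For each historical sample: fit its feature curves in the historical-year
#' stack, fit curves for every eligible pixel of the centered
#' `window x window` neighborhood in the target-year stack, score each
#' neighbor with [pixel_similarity()], and keep exactly the most similar
#' pixel as a potential sample carrying the historical crop label. Ties break
#' in row-major order (top-left first). Samples with no eligible neighbor (or
#' an unusable historical pixel) are skipped and logged.
#'
#' Pixel eligibility requires at least `min_obs` valid dates per feature; a
#' 5x5 window at 16 m pixels corresponds to the 80 m x 80 m "same growing
#' environment" neighborhood.
#'
#' @param hist_samples sample table for the historical year.
#' @param hist_stack,target_stack `scene_stack`s of the two years.
#' @param feature_models named character vector (feature -> winning model).
#' @param window odd neighborhood width in pixels (default 5).
#' @param n_points curve resampling length (default 100).
#' @param min_obs minimum valid dates per feature for eligibility.
#' @return list with `samples` (potential-sample table: columns of the sample
#'   format plus `source_id`, `offset_row`, `offset_col`), `features` (matrix
#'   of clustering features, one row per potential sample, see
#'   [curve_summary_features()]), and `skipped` (data.table `id, reason`).
#' @export
select_potential_samples <- function(hist_samples, hist_stack, target_stack,
                                     feature_models, window = 5L,
                                     n_points = 100L, min_obs = 6L) {
  if (window %% 2 != 1) stop("window must be odd")
  half <- (window - 1L) %/% 2L
  nr <- dim(target_stack)[1]; nc <- dim(target_stack)[2]
  res <- list(); feats <- list(); skipped <- list()
  for (i in seq_len(nrow(hist_samples))) {
    sid <- hist_samples$id[i]
    hr <- hist_samples$row[i]; hc <- hist_samples$col[i]
    hcur <- fit_pixel_curves(hist_stack, hr, hc, feature_models, min_obs)
    if (!any(vapply(hcur, Negate(is.null), logical(1)))) {
      skipped[[length(skipped) + 1L]] <-
        data.table::data.table(id = sid, reason = "historical pixel unusable")
      next
    }
    best <- NULL
    for (dr in -half:half) for (dc in -half:half) {
      r <- hr + dr; c <- hc + dc
      if (r < 0 || r >= nr || c < 0 || c >= nc) next
      tcur <- fit_pixel_curves(target_stack, r, c, feature_models, min_obs)
      sc <- tryCatch(pixel_similarity(hcur, tcur, n_points),
                     error = function(e) NULL)
      if (is.null(sc)) next
      if (is.null(best) || sc$similarity > best$similarity)
        best <- list(similarity = sc$similarity, row = r, col = c,
                     dr = dr, dc = dc, curves = tcur)
    }
    if (is.null(best)) {
      skipped[[length(skipped) + 1L]] <-
        data.table::data.table(id = sid, reason = "no eligible neighbor")
      next
    }
    res[[length(res) + 1L]] <- data.table::data.table(
      id = sprintf("p_%s", sid), year = target_stack$year,
      row = best$row, col = best$col, class = hist_samples$class[i],
      provenance = "potential", similarity = best$similarity,
      source_id = sid, offset_row = best$dr, offset_col = best$dc)
    feats[[length(feats) + 1L]] <- tryCatch(
      curve_summary_features(best$curves, n_points,
                             features = names(feature_models)),
      error = function(e)
        rep(NA_real_, 7L * length(feature_models)))  # partial-feature pixel
  }
  samples <- if (length(res)) data.table::rbindlist(res)
             else data.table::data.table()
  list(samples = samples,
       features = if (length(feats)) do.call(rbind, feats) else NULL,
       skipped = if (length(skipped)) data.table::rbindlist(skipped)
                 else data.table::data.table(id = character(0),
                                             reason = character(0)))
}
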