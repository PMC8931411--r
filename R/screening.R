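#' Summary-statistic clustering features of fitted growth curves
#'
#' For each feature (fixed order, default NIR, NDVI, NDWI) the fitted curve is
#' resampled at `n_points` equal intervals and summarized by
#' `(mean, sd, min, max, p25, p50, p75)` (percentiles by linear
#' interpolation); the per-feature blocks are concatenated, giving a
#' `7 * n_features` vector (21 for the default three).
#'
#' @param curves named list of `feature_curve`.
#' @param n_points resampling length (default 100).
#' @param features feature order (default `c("nir","ndvi","ndwi")`).
#' @return named numeric vector, e.g. `nir.mean, nir.sd, ..., ndwi.p75`.
#' @export
curve_summary_features <- function(curves, n_points = 100L,
                                   features = SIMILARITY_FEATURES) {
  stat_names <- c("mean", "sd", "min", "max", "p25", "p50", "p75")
  out <- numeric(0)
  for (f in features) {
    cur <- curves[[f]]
    if (is.null(cur) || !isTRUE(cur$ok))
      stop("unusable curve for feature: ", f)
    v <- sample_curve(cur, n_points)
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    out <- c(out, setNames(c(mean(v), sd(v), min(v), max(v), q),
                           paste(f, stat_names, sep = ".")))
  }
  out
}

#' Cluster feature vectors with k-means
#'
#' K-means on per-dimension z-scored features (zero-variance dimensions are
#' left at 0), 10 random restarts, best within-cluster sum of squares,
#' deterministic per seed. A degenerate input (fewer distinct points than
#' `k`) is flagged instead of clustered so silhouette scoring can skip that
#' `k`.
#'
#' @param features numeric matrix (rows = points).
#' @param k number of clusters, `2 <= k <= n - 1`.
#' @param seed integer seed.
#' @param nstart random restarts (default 10).
#' @return integer cluster labels (length `nrow(features)`), with attribute
#'   `degenerate = TRUE` when clustering was not possible.
#' @export
cluster_points <- function(features, k, seed = 1L, nstart = 10L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 2 || k > n - 1) stop("need 2 <= k <= n - 1")
  z <- scale(features)
  z[, !is.finite(colSums(z))] <- 0  # zero-variance dimensions
  if (nrow(unique(z)) < k) {
    labels <- rep(1L, n)
    attr(labels, "degenerate") <- TRUE
    return(labels)
  }
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(z, centers = k, nstart = nstart,
                                       iter.max = 100))
  as.integer(km$cluster)
}

#' Silhouette coefficient of a clustering
#'
#' Euclidean dissimilarity; for each point `i`, `a(i)` is the mean distance to
#' the other members of its cluster and `b(i)` the minimum over other
#' clusters of the mean distance to that cluster's members;
#' `S(i) = (b(i) - a(i)) / max(a(i), b(i))`, and the silhouette coefficient
#' `SC` is the mean of `S(i)`. Points in singleton clusters get `S(i) = 0`.
#'
#' @param features numeric matrix (rows = points).
#' @param labels cluster labels (>= 2 non-empty clusters).
#' @return a `silhouette_result`: list
#'   `(k, per_point_a, per_point_b, per_point_s, sc, n)`.
#' @export
silhouette_coefficient <- function(features, labels) {
  features <- as.matrix(features)
  n <- nrow(features)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette needs >= 2 clusters")
  D <- as.matrix(dist(features))
  a <- b <- s <- numeric(n)
  sizes <- tabulate(labels, k)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[li] == 1) { a[i] <- 0; b[i] <- 0; s[i] <- 0; next }
    a[i] <- sum(D[i, labels == li]) / (sizes[li] - 1)
    b[i] <- min(vapply(setdiff(seq_len(k), li),
                       function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  structure(list(k = k, per_point_a = a, per_point_b = b, per_point_s = s,
                 sc = mean(s), n = n), class = "silhouette_result")
}

#' Screen potential samples by per-crop clustering
#'
#' Per crop class: cluster the summary features for every `k` in
#' `[k_min, min(k_max, n - 1)]`, score each clustering with the silhouette
#' coefficient, pick the `k` with the highest SC (ties: smaller `k`), and
#' retain only the members of the largest cluster (ties: the cluster with the
#' higher mean similarity) as `provenance = "generated"` samples. Crops with
#' fewer than 4 potential samples pass through unscreened with a warning.
#'
#' @param potential potential-sample table (from
#'   [select_potential_samples()]).
#' @param features matrix of clustering features aligned with `potential`
#'   rows.
#' @param k_min,k_max cluster-count search range (defaults 2 and 20).
#' @param seed integer seed (k-means restarts use `seed + k`).
#' @return list with `samples` (generated-sample table) and `report` (per
#'   crop: `n_in`, `k_star`, `sc_by_k`, `n_out`, `retained_fraction`).
#' @export
screen_samples <- function(potential, features, k_min = 2L, k_max = 20L,
                           seed = 1L) {
  if (!nrow(potential)) {
    warning("no potential samples to screen")
    return(list(samples = potential, report = list()))
  }
  stopifnot(nrow(features) == nrow(potential))
  keep_rows <- stats::complete.cases(features)
  if (any(!keep_rows)) {
    warning(sum(!keep_rows), " potential sample(s) dropped: incomplete curves")
    potential <- potential[keep_rows, ]
    features <- features[keep_rows, , drop = FALSE]
  }
  out <- list(); report <- list()
  for (cl in unique(potential$class)) {
    sel <- which(potential$class == cl)
    n <- length(sel)
    if (n < 4) {
      warning(sprintf("class %s: only %d potential samples; passed unscreened",
                      cl, n))
      g <- potential[sel, ]
      g$provenance <- "generated"
      out[[cl]] <- g
      report[[cl]] <- list(n_in = n, k_star = NA_integer_,
                           sc_by_k = numeric(0), n_out = n,
                           retained_fraction = 1)
      next
    }
    X <- features[sel, , drop = FALSE]
    ks <- seq.int(k_min, min(k_max, n - 1L))
    sc <- setNames(rep(NA_real_, length(ks)), ks)
    labs <- vector("list", length(ks))
    for (j in seq_along(ks)) {
      lab <- cluster_points(X, ks[j], seed = seed + ks[j])
      if (isTRUE(attr(lab, "degenerate"))) next
      sc[j] <- silhouette_coefficient(X, lab)$sc
      labs[[j]] <- lab
    }
    if (all(is.na(sc))) {  # all k degenerate: retain everything
      jstar <- NA
      retained <- sel
      kstar <- NA_integer_
    } else {
      jstar <- which(sc == max(sc, na.rm = TRUE))[1]  # ties: smaller k
      kstar <- ks[jstar]
      lab <- labs[[jstar]]
      csize <- tabulate(lab, kstar)
      big <- which(csize == max(csize))
      if (length(big) > 1) {  # tie: higher mean similarity
        msim <- vapply(big, function(g)
          mean(potential$similarity[sel[lab == g]]), numeric(1))
        big <- big[which.max(msim)]
      }
      retained <- sel[lab == big[1]]
    }
    g <- potential[retained, ]
    g$provenance <- "generated"
    out[[cl]] <- g
    report[[cl]] <- list(n_in = n, k_star = kstar,
                         sc_by_k = sc[!is.na(sc)],
                         n_out = length(retained),
                         retained_fraction = length(retained) / n)
  }
  list(samples = data.table::rbindlist(out), report = report)
}
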