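#' Tree-ensemble configuration
#'
#' Bagged CART classification forest: 150 trees by default, per-tree
#' bootstrap whose size equals the training-set size, and `floor(sqrt(p))`
#' candidate features at each split.
#'
#' @param n_trees number of trees (default 150).
#' @param mtry candidate features per split; `NULL` means `floor(sqrt(p))`.
#' @param seed integer seed.
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 150L, mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)), class = "forest_config")
}

#' Build the classification feature matrix
#'
#' One row per sample point (or per pixel when `points = NULL`): each
#' feature's selected curve model is fitted to the pixel's series and
#' evaluated on a fixed DOY grid, so rows are comparable across years even
#' when observation dates differ. Default grid DOY 140..290 step 10 (16
#' points) over NIR/NDVI/NDWI gives 48 columns. Pixels ineligible for any
#' feature are flagged unclassifiable (all-`NA` row).
#'
#' @param points sample table with `row`, `col` (0-based) and optionally
#'   `class`; `NULL` means every pixel of the stack.
#' @param stack a `scene_stack`.
#' @param feature_models named character vector (feature -> model).
#' @param doy_grid evaluation DOYs (default `seq(140, 290, 10)`).
#' @param min_obs eligibility threshold (valid dates per feature).
#' @return a `feature_matrix`: list `(x, column_spec, labels, eligible)`
#'   where `x` is `n x (n_features * length(doy_grid))`.
#' @export
build_feature_matrix <- function(points, stack, feature_models,
                                 doy_grid = seq(140, 290, by = 10),
                                 min_obs = 6L) {
  if (!length(doy_grid)) stop("empty doy_grid")
  if (is.null(points)) {
    nr <- dim(stack)[1]; nc <- dim(stack)[2]
    points <- data.table::data.table(
      row = rep(seq_len(nr) - 1L, nc),
      col = rep(seq_len(nc) - 1L, each = nr))
  }
  feats <- names(feature_models)
  spec <- data.table::data.table(
    feature = rep(feats, each = length(doy_grid)),
    doy = rep(doy_grid, times = length(feats)))
  n <- nrow(points)
  x <- matrix(NA_real_, n, nrow(spec))
  colnames(x) <- paste0(spec$feature, "_d", spec$doy)
  eligible <- rep(FALSE, n)
  for (i in seq_len(n)) {
    curves <- fit_pixel_curves(stack, points$row[i], points$col[i],
                               feature_models, min_obs)
    if (any(vapply(curves, is.null, logical(1)))) next
    x[i, ] <- unlist(lapply(feats, function(f)
      eval_curve(curves[[f]], doy_grid)), use.names = FALSE)
    eligible[i] <- TRUE
  }
  structure(list(x = x, column_spec = spec,
                 labels = if ("class" %in% names(points)) points$class
                          else NULL,
                 eligible = eligible),
            class = "feature_matrix")
}

#' Train the bagged decision-tree ensemble
#'
#' Grows `n_trees` CART trees, each on a bootstrap resample of size equal to
#' the training-set size, choosing each split among `floor(sqrt(p))` randomly
#' drawn candidate features (Gini impurity, grown to purity). Prediction is
#' by majority vote with ties broken toward the first class. Deterministic
#' per seed. Rows flagged ineligible are excluded from training.
#'
#' @param matrix a `feature_matrix` with labels and at least 2 classes.
#' @param config a [forest_config()].
#' @param classes optional fixed class order (default: sorted unique labels).
#' @return a `crop_forest` classifier.
#' @export
train_forest <- function(matrix, config = forest_config(), classes = NULL) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (is.null(matrix$labels)) stop("training matrix has no labels")
  keep <- matrix$eligible & !is.na(matrix$labels)
  x <- matrix$x[keep, , drop = FALSE]
  y <- matrix$labels[keep]
  classes <- classes %||% sort(unique(y))
  if (length(unique(y)) < 2) stop("training data must contain >= 2 classes")
  yi <- match(y, classes) - 1L
  if (anyNA(yi)) stop("labels outside the class list")
  p <- ncol(x)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
  trees <- .train_forest_cpp(x, yi, length(classes), config$n_trees,
                             as.integer(mtry), nrow(x), config$seed)
  structure(list(trees = trees, classes = classes,
                 column_spec = matrix$column_spec, n_train = nrow(x),
                 config = config), class = "crop_forest")
}

#' Predict classes for a feature matrix
#'
#' @param object a `crop_forest`.
#' @param newdata a `feature_matrix` with identical `column_spec`.
#' @param ... unused.
#' @return character vector of predicted classes (`NA` for ineligible rows).
#' @export
predict.crop_forest <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_matrix"))
  if (!identical(as.data.frame(object$column_spec),
                 as.data.frame(newdata$column_spec)))
    stop("column_spec mismatch between training and prediction matrices")
  out <- rep(NA_character_, nrow(newdata$x))
  keep <- newdata$eligible
  if (any(keep)) {
    votes <- .predict_forest_cpp(object$trees,
                                 newdata$x[keep, , drop = FALSE],
                                 length(object$classes))
    out[keep] <- object$classes[max.col(votes, ties.method = "first")]
  }
  out
}

#' Classify every pixel of a scene
#'
#' @param classifier a `crop_forest`.
#' @param stack a `scene_stack`.
#' @param feature_models named character vector (feature -> model); must match
#'   what the classifier was trained with.
#' @param doy_grid evaluation DOYs (must reproduce the training
#'   `column_spec`).
#' @param min_obs eligibility threshold.
#' @return list with `labels` (character matrix, `NA` where unclassifiable)
#'   and `unclassifiable` (logical matrix); georeferencing is the input's.
#' @export
classify_scene <- function(classifier, stack, feature_models,
                           doy_grid = seq(140, 290, by = 10), min_obs = 6L) {
  fm <- build_feature_matrix(NULL, stack, feature_models, doy_grid, min_obs)
  pred <- predict(classifier, fm)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  list(labels = matrix(pred, nr, nc),
       unclassifiable = matrix(!fm$eligible, nr, nc),
       transform = stack$transform)
}

#' Serialize / restore a trained forest as JSON
#'
#' Plain-text container embedding the trees, class order and `column_spec`,
#' so models survive text-only storage and cross-session reuse.
#'
#' @param forest a `crop_forest`.
#' @param path JSON file path.
#' @return `write_forest` the path invisibly; `read_forest` a `crop_forest`.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "crop_forest"))
  payload <- list(classes = forest$classes,
                  column_spec = forest$column_spec,
                  n_train = forest$n_train,
                  config = unclass(forest$config),
                  feature_models = as.list(forest$feature_models),
                  trees = forest$trees)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite may simplify the tree list to a data.frame of list columns
  trees <- if (is.data.frame(p$trees)) {
    lapply(seq_len(nrow(p$trees)), function(i)
      list(feature = as.integer(p$trees$feature[[i]]),
           threshold = as.numeric(p$trees$threshold[[i]]),
           left = as.integer(p$trees$left[[i]]),
           right = as.integer(p$trees$right[[i]]),
           pred = as.integer(p$trees$pred[[i]])))
  } else {
    lapply(p$trees, function(t)
      list(feature = as.integer(t$feature),
           threshold = as.numeric(t$threshold),
           left = as.integer(t$left), right = as.integer(t$right),
           pred = as.integer(t$pred)))
  }
  cfg <- structure(p$config, class = "forest_config")
  fmods <- if (length(p$feature_models)) unlist(p$feature_models) else NULL
  structure(list(trees = trees, classes = p$classes,
                 column_spec = data.table::as.data.table(p$column_spec),
                 n_train = p$n_train, config = cfg, feature_models = fmods),
            class = "crop_forest")
}
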