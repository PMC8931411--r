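#' Stratified train/validation split
#'
#' Splits a sample table into a training and a validation part (default
#' 70/30), stratified by class, deterministic per seed, disjoint and
#' exhaustive. Classes too small to appear on both sides get at least one
#' sample on each, with a warning.
#'
#' @param samples sample table with a `class` column.
#' @param train_fraction fraction per class assigned to training.
#' @param seed integer seed.
#' @return list `(train, test)` of sample tables.
#' @export
split_validation <- function(samples, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  tr_idx <- integer(0)
  for (cl in unique(samples$class)) {
    idx <- which(samples$class == cl)
    n <- length(idx)
    if (n < 2) {
      warning("class ", cl, " has < 2 samples; kept on both sides impossible,",
              " assigned to training")
      tr_idx <- c(tr_idx, idx)
      next
    }
    n_tr <- min(max(round(train_fraction * n), 1L), n - 1L)
    tr_idx <- c(tr_idx, sample(idx, n_tr))
  }
  list(train = samples[sort(tr_idx), ],
       test = samples[setdiff(seq_len(nrow(samples)), tr_idx), ])
}

#' Confusion matrix
#'
#' Rows are reference labels, columns predicted labels, in the fixed
#' `class_order`.
#'
#' @param reference,predicted equal-length label vectors.
#' @param class_order fixed class list; labels outside it error.
#' @return a `confusion_matrix`: list `(counts, class_order, n)`.
#' @export
confusion_matrix <- function(reference, predicted, class_order) {
  if (length(reference) != length(predicted))
    stop("reference and predicted lengths differ")
  r <- match(reference, class_order); p <- match(predicted, class_order)
  if (anyNA(r) || anyNA(p))
    stop("labels outside class_order: ",
         paste(unique(c(reference[is.na(r)], predicted[is.na(p)])),
               collapse = ", "))
  k <- length(class_order)
  counts <- matrix(0L, k, k, dimnames = list(class_order, class_order))
  for (i in seq_along(r)) counts[r[i], p[i]] <- counts[r[i], p[i]] + 1L
  structure(list(counts = counts, class_order = class_order,
                 n = length(reference)), class = "confusion_matrix")
}

#' Accuracy metrics from a confusion matrix
#'
#' Overall accuracy `OA = trace/N`; per class (one-vs-rest):
#' producer's accuracy `PA = TP/(TP+FN)` (recall), user's accuracy
#' `UA = TP/(TP+FP)` (precision) and `F1 = 2*PA*UA/(PA+UA)`. Empty
#' denominators yield 0 and are flagged.
#'
#' @param cm a [confusion_matrix()].
#' @return an `accuracy_report`: list `(oa, per_class, flags)` with
#'   `per_class` a data.table of `class, pa, ua, f1`.
#' @export
accuracy_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$n == 0) stop("empty confusion matrix")
  counts <- cm$counts
  oa <- sum(diag(counts)) / sum(counts)
  flags <- character(0)
  per <- lapply(seq_along(cm$class_order), function(i) {
    tp <- counts[i, i]
    fn <- sum(counts[i, ]) - tp
    fp <- sum(counts[, i]) - tp
    pa <- if (tp + fn > 0) tp / (tp + fn) else 0
    ua <- if (tp + fp > 0) tp / (tp + fp) else 0
    if (tp + fn == 0 || tp + fp == 0)
      flags <<- c(flags, cm$class_order[i])
    f1 <- if (pa + ua > 0) 2 * pa * ua / (pa + ua) else 0
    data.table::data.table(class = cm$class_order[i], pa = pa, ua = ua,
                           f1 = f1)
  })
  structure(list(oa = oa, per_class = data.table::rbindlist(per),
                 flags = unique(flags)), class = "accuracy_report")
}
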