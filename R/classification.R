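#' Random-forest classifier configuration
#'
#' Defaults mirror the conventional defaults of the randomForest package:
#' 500 trees and `mtry = sqrt(p)` for classification. `rfcv_step` is the
#' multiplicative feature reduction of the feature-count search; `top_k` the
#' size of the importance-ranked feature set used by [fit_topk_model()].
#'
#' @param n_trees number of trees
#' @param mtry variables tried per split; `"sqrt"` resolves to
#'   `floor(sqrt(p))`
#' @param n_folds cross-validation folds (stratified by class)
#' @param cv_stratified stratify folds by class?
#' @param rfcv_folds folds for the feature-count search
#' @param rfcv_step multiplicative reduction per elimination step, in (0,1)
#' @param top_k number of top-importance features retained
#' @param seed RNG seed; every fitting routine is deterministic given it
#' @return an object of class `classifier_config`
#' @export
classifier_config <- function(n_trees = 500, mtry = "sqrt", n_folds = 10,
                              cv_stratified = TRUE, rfcv_folds = 5,
                              rfcv_step = 0.5, top_k = 30, seed = 1) {
  stopifnot(
    n_trees >= 1, n_folds >= 2, rfcv_folds >= 2,
    rfcv_step > 0, rfcv_step < 1, top_k >= 1
  )
  structure(
    list(
      n_trees = as.integer(n_trees), mtry = mtry,
      n_folds = as.integer(n_folds), cv_stratified = isTRUE(cv_stratified),
      rfcv_folds = as.integer(rfcv_folds), rfcv_step = rfcv_step,
      top_k = as.integer(top_k), seed = as.integer(seed)
    ),
    class = "classifier_config"
  )
}

#' Binary labels from group metadata
#'
#' Samples in `positive` become the positive class, samples in `negative` the
#' negative class (typically the pooled benign + normal "non-cancer" class);
#' all other samples are excluded.
#'
#' @param meta a metadata tibble
#' @param positive,negative disjoint sets of group labels
#' @param sample_type optional filter to one sample type
#' @return a tibble `sample_id`, `label` (factor with levels `neg`, `pos`)
#' @export
label_binary <- function(meta, positive = "cancer",
                         negative = c("normal", "benign"),
                         sample_type = NULL) {
  stopifnot(length(intersect(positive, negative)) == 0)
  meta <- validate_sample_metadata(meta)
  if (!is.null(sample_type)) meta <- meta[meta$sample_type %in% sample_type, ]
  keep <- meta$group %in% c(positive, negative)
  meta <- meta[keep, , drop = FALSE]
  lab <- factor(ifelse(meta$group %in% positive, "pos", "neg"),
    levels = c("neg", "pos")
  )
  if (!all(c("neg", "pos") %in% lab)) {
    stop("both classes must be non-empty after labelling", call. = FALSE)
  }
  tibble::tibble(sample_id = meta$sample_id, label = lab)
}

#' Mann-Whitney AUC
#'
#' Probability that a random positive outranks a random negative, with ties
#' counting one half: the rank-sum form of the area under the ROC curve.
#'
#' @param scores numeric classifier scores
#' @param labels logical / 0-1 / `neg`-`pos` factor, `TRUE` = positive
#' @return AUC in `[0, 1]`
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- .as_binary(labels)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("need both classes to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.as_binary <- function(labels) {
  if (is.factor(labels)) {
    return(labels == levels(labels)[2])
  }
  if (is.logical(labels)) {
    return(labels)
  }
  labels > 0
}

#' Empirical ROC curve
#'
#' @param scores numeric classifier scores
#' @param labels see [auc_mann_whitney()]
#' @return tibble `threshold`, `fpr`, `tpr`, monotone from (0,0) to (1,1)
#' @export
roc_curve <- function(scores, labels) {
  y <- .as_binary(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  # group tied scores into single ROC steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / sum(!y)),
    tpr = c(0, tp[last] / sum(y))
  )
}

# resolve mtry and fit one forest; callers control the RNG
.fit_rf <- function(x, y, config) {
  mtry <- config$mtry
  if (identical(mtry, "sqrt")) mtry <- max(1L, floor(sqrt(ncol(x))))
  randomForest::randomForest(
    x = as.data.frame(x), y = y,
    ntree = config$n_trees, mtry = mtry, importance = TRUE
  )
}

# stratified fold assignment; falls back to fewer folds when a class is small
.stratified_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  min_class <- min(table(y))
  if (stratified && min_class < k) {
    warning("smallest class (", min_class, ") < n_folds; reducing folds")
    k <- max(2L, min_class)
  }
  folds <- integer(n)
  if (stratified) {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    folds[sample(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

#' Stratified cross-validated random forest
#'
#' Fits one forest per fold, pools the out-of-fold predicted probabilities
#' (fraction of trees voting positive) into a single ROC/AUC, and averages
#' permutation importances (mean decrease in accuracy) over folds.
#' Deterministic given `config$seed`.
#'
#' @param data a tibble with `sample_id` plus one numeric column per feature
#'   (e.g. a CLR table), or a samples-by-features matrix
#' @param labels tibble from [label_binary()]; samples absent from it are
#'   ignored
#' @param config a [classifier_config()]
#' @return an object of class `rf_result`: `auc`, `roc`, `importance`
#'   (tibble `feature`, `mean_decrease_accuracy`), `selected_features`,
#'   `per_fold_auc`, `scores` (tibble `sample_id`, `score`, `label`)
#' @export
cv_random_forest <- function(data, labels, config = classifier_config()) {
  xy <- .align_xy(data, labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  folds <- .stratified_folds(xy$y, config$n_folds, config$cv_stratified)
  k <- max(folds)
  score <- rep(NA_real_, length(xy$y))
  imp <- NULL
  per_fold <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    stopifnot(!any(tr & te)) # train and test never share a sample
    fit <- .fit_rf(xy$x[tr, , drop = FALSE], xy$y[tr], config)
    score[te] <- stats::predict(fit,
      newdata = as.data.frame(xy$x[te, , drop = FALSE]),
      type = "prob"
    )[, "pos"]
    mda <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
    imp <- if (is.null(imp)) mda else imp + mda
    if (length(unique(xy$y[te])) == 2) {
      per_fold[f] <- auc_mann_whitney(score[te], xy$y[te])
    }
  }
  imp <- imp / k
  .rf_result(score, xy, imp, per_fold, config)
}

.align_xy <- function(data, labels) {
  m <- if (is.matrix(data)) data else .tbl_to_mat(data)
  stopifnot(all(c("sample_id", "label") %in% names(labels)))
  ids <- intersect(rownames(m), labels$sample_id)
  if (length(ids) == 0) stop("no samples shared between data and labels", call. = FALSE)
  y <- labels$label[match(ids, labels$sample_id)]
  y <- factor(as.character(y), levels = c("neg", "pos"))
  if (length(unique(y)) < 2) stop("need both classes present", call. = FALSE)
  list(x = m[ids, , drop = FALSE], y = y, ids = ids)
}

.rf_result <- function(score, xy, imp, per_fold, config,
                       selected = colnames(xy$x)) {
  structure(
    list(
      auc = auc_mann_whitney(score, xy$y),
      roc = roc_curve(score, xy$y),
      importance = tibble::tibble(
        feature = names(imp),
        mean_decrease_accuracy = unname(imp)
      ) |> dplyr::arrange(dplyr::desc(.data$mean_decrease_accuracy)),
      selected_features = selected,
      per_fold_auc = per_fold,
      scores = tibble::tibble(
        sample_id = xy$ids, score = score,
        label = xy$y
      ),
      n_samples = length(xy$y),
      n_features = ncol(xy$x),
      config = config
    ),
    class = "rf_result"
  )
}

#' @export
print.rf_result <- function(x, ...) {
  cat(
    "random-forest result: AUC", sprintf("%.4f", x$auc), "on", x$n_samples,
    "samples,", x$n_features, "features,",
    length(x$selected_features), "selected\n"
  )
  invisible(x)
}

#' Cross-validated feature-count search
#'
#' Recursive feature elimination with cross-validated error at each feature
#' count (the `rfcv` procedure of the randomForest package, which backs this
#' function): features are repeatedly reduced to the top `rfcv_step` fraction
#' by importance and the misclassification error estimated by
#' `rfcv_folds`-fold CV at every count.
#'
#' @inheritParams cv_random_forest
#' @return list with `curve` (tibble `n_features`, `cv_error`) and
#'   `best_count` (smallest count attaining the minimum error)
#' @export
select_feature_count <- function(data, labels, config = classifier_config()) {
  xy <- .align_xy(data, labels)
  stopifnot(ncol(xy$x) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  if (ncol(xy$x) == 1) {
    fit <- .fit_rf(xy$x, xy$y, config)
    err <- mean(stats::predict(fit) != xy$y)
    curve <- tibble::tibble(n_features = 1L, cv_error = err)
    return(list(curve = curve, best_count = 1L))
  }
  res <- randomForest::rfcv(
    trainx = as.data.frame(xy$x), trainy = xy$y,
    cv.fold = config$rfcv_folds, step = config$rfcv_step,
    ntree = config$n_trees
  )
  curve <- tibble::tibble(
    n_features = as.integer(res$n.var),
    cv_error = unname(res$error.cv)
  )
  best <- min(curve$n_features[curve$cv_error == min(curve$cv_error)])
  list(curve = curve, best_count = as.integer(best))
}

#' Top-k importance model
#'
#' Ranks features by mean decrease in accuracy from a single full-data fit,
#' keeps the `top_k` best, and re-estimates performance with
#' [cv_random_forest()] restricted to them. The single ranked list matches
#' how a headline importance figure is built, at the price of a mild
#' selection optimism relative to per-fold re-selection (see
#' `per_fold_selection`).
#'
#' @inheritParams cv_random_forest
#' @param per_fold_selection if `TRUE`, re-select the top-k inside every
#'   training fold instead (no selection leakage; no single ranked list)
#' @return an `rf_result` whose `selected_features` is the ranked top-k
#'   list; `full_importance` carries the full-data ranking
#' @export
fit_topk_model <- function(data, labels, config = classifier_config(),
                           per_fold_selection = FALSE) {
  xy <- .align_xy(data, labels)
  if (config$top_k > ncol(xy$x)) {
    stop("top_k (", config$top_k, ") exceeds feature count (", ncol(xy$x), ")",
      call. = FALSE
    )
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  if (per_fold_selection) {
    res <- .cv_with_fold_selection(xy, config)
    return(res)
  }
  full <- .fit_rf(xy$x, xy$y, config)
  mda <- randomForest::importance(full, type = 1, scale = FALSE)[, 1]
  ranked <- names(sort(mda, decreasing = TRUE))
  top <- ranked[seq_len(config$top_k)]
  res <- cv_random_forest(xy$x[, top, drop = FALSE],
    tibble::tibble(sample_id = xy$ids, label = xy$y),
    config = config
  )
  res$selected_features <- top
  res$full_importance <- tibble::tibble(
    feature = ranked,
    mean_decrease_accuracy = unname(mda[ranked])
  )
  res
}

# per-fold top-k re-selection variant: selection never sees test folds
.cv_with_fold_selection <- function(xy, config) {
  folds <- .stratified_folds(xy$y, config$n_folds, config$cv_stratified)
  k <- max(folds)
  score <- rep(NA_real_, length(xy$y))
  per_fold <- rep(NA_real_, k)
  imp <- stats::setNames(rep(0, ncol(xy$x)), colnames(xy$x))
  for (f in seq_len(k)) {
    tr <- folds != f
    fit0 <- .fit_rf(xy$x[tr, , drop = FALSE], xy$y[tr], config)
    mda <- randomForest::importance(fit0, type = 1, scale = FALSE)[, 1]
    top <- names(sort(mda, decreasing = TRUE))[seq_len(config$top_k)]
    fit <- .fit_rf(xy$x[tr, top, drop = FALSE], xy$y[tr], config)
    score[!tr] <- stats::predict(fit,
      newdata = as.data.frame(xy$x[!tr, top, drop = FALSE]),
      type = "prob"
    )[, "pos"]
    imp[top] <- imp[top] + randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
    if (length(unique(xy$y[!tr])) == 2) {
      per_fold[f] <- auc_mann_whitney(score[!tr], xy$y[!tr])
    }
  }
  res <- .rf_result(score, xy, imp / k, per_fold, config)
  res$selected_features <- res$importance$feature[seq_len(config$top_k)]
  res
}

#' Re-evaluate an inherited feature list on new labels
#'
#' Trains and cross-validates a classifier for a second contrast (canonically
#' cancer-adjacent vs non-cancer) using exactly the feature list selected by
#' an earlier model — no re-selection.
#'
#' @param data feature tibble or matrix covering all samples involved
#' @param meta metadata tibble
#' @param features_from an `rf_result` whose `selected_features` to reuse
#' @param config a [classifier_config()]
#' @param positive,negative group sets for the new contrast
#' @param sample_type optional sample-type filter
#' @return an `rf_result` on the inherited features
#' @export
adjacent_reuse_model <- function(data, meta, features_from,
                                 config = classifier_config(),
                                 positive = "cancer_adjacent",
                                 negative = c("normal", "benign"),
                                 sample_type = NULL) {
  feats <- features_from$selected_features
  m <- if (is.matrix(data)) data else .tbl_to_mat(data)
  missing <- setdiff(feats, colnames(m))
  if (length(missing) > 0) {
    stop("feature(s) absent from data: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  labels <- label_binary(meta, positive = positive, negative = negative,
    sample_type = sample_type)
  res <- cv_random_forest(m[, feats, drop = FALSE], labels, config = config)
  res$selected_features <- feats
  res
}
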