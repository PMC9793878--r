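#' Cohort-to-cohort transfer matrix
#'
#' Trains a top-k random forest on each cohort (feature selection strictly
#' inside that cohort) and scores every other cohort, filling the off-diagonal
#' of a train-by-test AUC matrix. The diagonal is the within-study estimate:
#' either the mean AUC of repeated stratified 70/30 train/test splits
#' (`split_70_30`, feature selection inside each 70% training part) or
#' stratified cross-validation with per-fold feature selection (`nested_cv`).
#' Cohorts with a single class are flagged missing (`NA`) rather than dropped.
#' Every single evaluation re-derives its RNG stream from `config$seed`, so
#' the matrix is deterministic and independent of evaluation order.
#'
#' @param data feature tibble (`sample_id` + features) or matrix
#' @param meta metadata tibble supplying the `study` of each sample
#' @param labels tibble from [label_binary()]
#' @param config a [classifier_config()]
#' @param diagonal_mode `"split_70_30"` or `"nested_cv"`
#' @param n_repeats number of 70/30 splits averaged on the diagonal
#' @param include_diagonal compute the diagonal at all?
#' @param loco also compute the leave-one-cohort-out row?
#' @return an object of class `transfer_matrix`: `cohorts`, `auc` (train x
#'   test matrix), `loco_row`, `diagonal_mode`, `avg_transfer` (mean of
#'   non-missing off-diagonal), `avg_loco`
#' @export
cohort_to_cohort <- function(data, meta, labels, config = classifier_config(),
                             diagonal_mode = c("split_70_30", "nested_cv"),
                             n_repeats = 10, include_diagonal = TRUE,
                             loco = TRUE) {
  diagonal_mode <- match.arg(diagonal_mode)
  parts <- .cohort_parts(data, meta, labels)
  cohorts <- names(parts)
  if (length(cohorts) < 2) stop("need at least two cohorts", call. = FALSE)
  usable <- purrr::map_lgl(parts, ~ nlevels(droplevels(.x$y)) == 2)
  auc <- matrix(NA_real_,
    nrow = length(cohorts), ncol = length(cohorts),
    dimnames = list(train = cohorts, test = cohorts)
  )
  for (i in cohorts) {
    if (!usable[[i]]) next
    for (j in cohorts) {
      if (i == j || !usable[[j]]) next
      auc[i, j] <- .train_eval(
        parts[[i]]$x, parts[[i]]$y,
        parts[[j]]$x, parts[[j]]$y, config
      )
    }
    if (include_diagonal) {
      auc[i, i] <- .diagonal_auc(parts[[i]], config, diagonal_mode, n_repeats)
    }
  }
  loco_row <- NULL
  if (loco) {
    loco_row <- loco_validation(data, meta, labels, config)$auc_by_cohort
    loco_row <- loco_row[cohorts]
  }
  off <- auc
  diag(off) <- NA_real_
  structure(
    list(
      cohorts = cohorts,
      auc = auc,
      loco_row = loco_row,
      diagonal_mode = if (include_diagonal) diagonal_mode else NA_character_,
      avg_transfer = mean(off, na.rm = TRUE),
      avg_loco = if (loco) mean(loco_row, na.rm = TRUE) else NA_real_
    ),
    class = "transfer_matrix"
  )
}

# split data into per-cohort design matrices aligned with labels
.cohort_parts <- function(data, meta, labels) {
  xy <- .align_xy(data, labels)
  meta <- validate_sample_metadata(meta)
  study <- meta$study[match(xy$ids, meta$sample_id)]
  stopifnot(!anyNA(study))
  out <- list()
  for (s in unique(study)) {
    idx <- which(study == s)
    out[[s]] <- list(
      x = xy$x[idx, , drop = FALSE],
      y = factor(as.character(xy$y[idx]), levels = c("neg", "pos")),
      ids = xy$ids[idx]
    )
  }
  out
}

# one evaluation: top-k selection + fit on the training pool, AUC on the test
# set; train/test disjointness is asserted structurally on sample IDs
.train_eval <- function(x_tr, y_tr, x_te, y_te, config) {
  stopifnot(length(intersect(rownames(x_tr), rownames(x_te))) == 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  k <- min(config$top_k, ncol(x_tr))
  fit0 <- .fit_rf(x_tr, y_tr, config)
  mda <- randomForest::importance(fit0, type = 1, scale = FALSE)[, 1]
  top <- names(sort(mda, decreasing = TRUE))[seq_len(k)]
  fit <- .fit_rf(x_tr[, top, drop = FALSE], y_tr, config)
  score <- stats::predict(fit,
    newdata = as.data.frame(x_te[, top, drop = FALSE]),
    type = "prob"
  )[, "pos"]
  if (nlevels(droplevels(y_te)) < 2) {
    return(NA_real_)
  }
  auc_mann_whitney(score, y_te)
}

# within-study diagonal: repeated stratified 70/30 splits or nested CV
.diagonal_auc <- function(part, config, mode, n_repeats) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  if (mode == "nested_cv") {
    res <- tryCatch(
      suppressWarnings(fit_topk_model(
        part$x, tibble::tibble(sample_id = part$ids, label = part$y),
        config = classifier_config(
          n_trees = config$n_trees, mtry = config$mtry,
          n_folds = config$n_folds, cv_stratified = config$cv_stratified,
          rfcv_folds = config$rfcv_folds, rfcv_step = config$rfcv_step,
          top_k = min(config$top_k, ncol(part$x)), seed = config$seed
        ),
        per_fold_selection = TRUE
      )),
      error = function(e) NULL
    )
    return(if (is.null(res)) NA_real_ else res$auc)
  }
  aucs <- rep(NA_real_, n_repeats)
  for (r in seq_len(n_repeats)) {
    tr_idx <- integer(0)
    for (cls in levels(part$y)) {
      idx <- which(part$y == cls)
      n_tr <- max(1L, floor(0.7 * length(idx)))
      tr_idx <- c(tr_idx, sample(idx, n_tr))
    }
    te_idx <- setdiff(seq_along(part$y), tr_idx)
    if (nlevels(droplevels(part$y[te_idx])) < 2) next
    aucs[r] <- .train_eval(
      part$x[tr_idx, , drop = FALSE], part$y[tr_idx],
      part$x[te_idx, , drop = FALSE], part$y[te_idx], config
    )
  }
  mean(aucs, na.rm = TRUE)
}

#' Leave-one-cohort-out validation
#'
#' For every cohort: train a top-k model on the pooled remaining cohorts
#' (feature selection inside that training pool only) and score the held-out
#' cohort. Held-out cohorts with a single class are skipped with a warning.
#'
#' @inheritParams cohort_to_cohort
#' @return list with `auc_by_cohort` (named vector, `NA` where skipped) and
#'   `average` (mean over non-missing entries)
#' @export
loco_validation <- function(data, meta, labels, config = classifier_config()) {
  xy <- .align_xy(data, labels)
  meta <- validate_sample_metadata(meta)
  study <- meta$study[match(xy$ids, meta$sample_id)]
  cohorts <- unique(study)
  if (length(cohorts) < 2) stop("need at least two cohorts", call. = FALSE)
  aucs <- stats::setNames(rep(NA_real_, length(cohorts)), cohorts)
  for (s in cohorts) {
    te <- study == s
    y_te <- xy$y[te]
    if (nlevels(droplevels(y_te)) < 2) {
      warning("held-out cohort '", s, "' has a single class; skipped")
      next
    }
    aucs[[s]] <- .train_eval(
      xy$x[!te, , drop = FALSE], xy$y[!te],
      xy$x[te, , drop = FALSE], y_te, config
    )
  }
  list(auc_by_cohort = aucs, average = mean(aucs, na.rm = TRUE))
}

#' Summaries of a transfer matrix
#'
#' @param m a `transfer_matrix`
#' @return list with `avg_transfer` (mean non-missing off-diagonal),
#'   `avg_loco`, `avg_diagonal`, and `per_train_cohort` (tibble ranking each
#'   cohort by the mean AUC it achieves as a training set on the others)
#' @export
summarize_matrix <- function(m) {
  stopifnot(inherits(m, "transfer_matrix"))
  off <- m$auc
  diag(off) <- NA_real_
  if (all(is.na(off))) stop("transfer matrix has no off-diagonal entries", call. = FALSE)
  per_train <- tibble::tibble(
    train_cohort = rownames(off),
    mean_test_auc = rowMeans(off, na.rm = TRUE),
    n_tested = rowSums(!is.na(off))
  ) |> dplyr::arrange(dplyr::desc(.data$mean_test_auc))
  list(
    avg_transfer = mean(off, na.rm = TRUE),
    avg_loco = if (is.null(m$loco_row)) NA_real_ else mean(m$loco_row, na.rm = TRUE),
    avg_diagonal = mean(diag(m$auc), na.rm = TRUE),
    per_train_cohort = per_train
  )
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("cohort-to-cohort transfer matrix (train rows x test cols):\n")
  print(round(x$auc, 3))
  if (!is.null(x$loco_row)) {
    cat("LOCO row:\n")
    print(round(x$loco_row, 3))
  }
  cat(
    "avg transfer:", sprintf("%.3f", x$avg_transfer),
    " avg LOCO:", sprintf("%.3f", x$avg_loco), "\n"
  )
  invisible(x)
}

#' Write a transfer matrix to TSV
#'
#' Square AUC block (train rows by test columns), a LOCO row when present,
#' and an averages footer; missing entries are written as `NA`, never 0.
#'
#' @param m a `transfer_matrix`
#' @param path output path
#' @export
write_transfer_matrix <- function(m, path) {
  stopifnot(inherits(m, "transfer_matrix"))
  block <- tibble::as_tibble(m$auc, rownames = "row")
  add_row <- function(label, values) {
    extra <- stats::setNames(
      as.list(c(values, rep(NA_real_, ncol(m$auc) - length(values)))),
      colnames(m$auc)
    )
    dplyr::bind_rows(block, dplyr::bind_cols(tibble::tibble(row = label), extra))
  }
  if (!is.null(m$loco_row)) block <- add_row("LOCO", unname(m$loco_row))
  block <- add_row("avg_transfer", m$avg_transfer)
  block <- add_row("avg_loco", m$avg_loco)
  readr::write_tsv(block, path, progress = FALSE)
  invisible(path)
}
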