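test_that("Mann-Whitney AUC matches hand cases and the pair-counting oracle", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mann_whitney(rep(0.5, 6), rep(c(1, 0), 3)), 0.5)
  expect_equal(auc_mann_whitney(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)), "both classes")

  set.seed(111)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # deliberate ties
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(
      auc_mann_whitney(scores, labels),
      oracle_auc_pairs(scores, labels),
      tolerance = 1e-10
    )
  }
})

test_that("rank-sum AUC equals the trapezoidal area under the ROC curve", {
  set.seed(112)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), 2)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    roc <- roc_curve(scores, labels)
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(trapezoid_auc(roc), auc_mann_whitney(scores, labels),
      tolerance = 1e-10
    )
  }
})

test_that("binary labelling follows the non-cancer pooling convention", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:5), study = "x",
    group = c("cancer", "benign", "normal", "cancer_adjacent", "cancer"),
    sample_type = "tissue", age = NA_real_, bmi = NA_real_
  )
  lab <- label_binary(meta)
  expect_equal(as.character(lab$label), c("pos", "neg", "neg", "pos"))
  expect_false("s4" %in% lab$sample_id) # adjacent excluded from main contrast

  adj <- label_binary(meta, positive = "cancer_adjacent")
  expect_equal(adj$sample_id[adj$label == "pos"], "s4")
  expect_error(
    label_binary(meta[meta$group == "cancer", , drop = FALSE]),
    "both classes"
  )
})

test_that("cross-validated forests are deterministic and separate planted signal", {
  set.seed(120)
  n <- 40
  x <- matrix(rnorm(n * 10), n, 10,
    dimnames = list(paste0("s", 1:n), paste0("f", 1:10))
  )
  y <- rep(c("pos", "neg"), each = n / 2)
  x[, 1] <- ifelse(y == "pos", 3, -3) + rnorm(n, 0, 0.1) # separating feature
  labels <- tibble::tibble(sample_id = rownames(x), label = factor(y, c("neg", "pos")))
  cfg <- classifier_config(n_trees = 200, n_folds = 5, seed = 9)
  r1 <- cv_random_forest(x, labels, cfg)
  expect_gte(r1$auc, 0.99)
  r2 <- cv_random_forest(x, labels, cfg)
  expect_identical(r1$roc, r2$roc)
  expect_identical(r1$auc, r2$auc)
  # the separating feature tops the averaged importance
  expect_equal(r1$importance$feature[1], "f1")
})

test_that("out-of-fold AUC sits near 0.5 when labels carry no signal", {
  set.seed(121)
  n <- 60
  x <- matrix(rnorm(n * 20), n, 20,
    dimnames = list(paste0("s", 1:n), paste0("f", 1:20))
  )
  aucs <- vapply(1:5, function(s) {
    y <- sample(rep(c("pos", "neg"), each = n / 2))
    labels <- tibble::tibble(
      sample_id = rownames(x),
      label = factor(y, c("neg", "pos"))
    )
    cv_random_forest(x, labels, classifier_config(
      n_trees = 200, n_folds = 5,
      seed = s
    ))$auc
  }, double(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("fold assignment is stratified and shrinks when a class is tiny", {
  set.seed(122)
  y <- factor(rep(c("pos", "neg"), c(30, 6)), c("neg", "pos"))
  folds <- crossbiome:::.stratified_folds(y, 3)
  for (f in unique(folds)) {
    expect_true(all(table(y[folds == f]) >= 1))
  }
  expect_warning(
    crossbiome:::.stratified_folds(y, 10),
    "reducing folds"
  )
})

test_that("feature-count search returns a curve and a parsimonious minimum", {
  set.seed(123)
  n <- 60
  x <- matrix(rnorm(n * 32), n, 32,
    dimnames = list(paste0("s", 1:n), paste0("f", 1:32))
  )
  y <- rep(c("pos", "neg"), each = n / 2)
  x[, 1:4] <- x[, 1:4] + ifelse(y == "pos", 1.5, -1.5)
  labels <- tibble::tibble(sample_id = rownames(x), label = factor(y, c("neg", "pos")))
  cfg <- classifier_config(n_trees = 150, seed = 4)
  sel <- select_feature_count(x, labels, cfg)
  expect_true(all(diff(sel$curve$n_features) < 0))
  expect_true(sel$best_count %in% sel$curve$n_features)
  # informative features exist, so error at the best count beats all-noise
  expect_lt(min(sel$curve$cv_error), 0.4)
  sel2 <- select_feature_count(x, labels, cfg)
  expect_identical(sel$curve, sel2$curve)

  one <- select_feature_count(x[, 1, drop = FALSE], labels, cfg)
  expect_equal(nrow(one$curve), 1)
  expect_equal(one$best_count, 1L)
})

test_that("top-k selection recovers planted features and ranks them", {
  sh <- shared_clr()
  labels <- label_binary(sh$meta)
  cfg <- classifier_config(top_k = 20, seed = 14)
  model <- fit_topk_model(sh$clr, labels, cfg)
  expect_length(model$selected_features, 20)
  # ranked by the full-data importance, descending
  imp <- model$full_importance
  expect_equal(model$selected_features, imp$feature[1:20])
  expect_true(all(diff(imp$mean_decrease_accuracy) <= 1e-12))
  expect_gte(sum(sh$truth$planted_taxa %in% model$selected_features), 6)
  expect_error(
    fit_topk_model(sh$clr, labels, classifier_config(top_k = 1000)),
    "top_k"
  )
})

test_that("per-fold selection mode never sees test folds yet still performs", {
  sh <- shared_clr()
  labels <- label_binary(sh$meta)
  cfg <- classifier_config(top_k = 20, n_folds = 5, seed = 14)
  model <- fit_topk_model(sh$clr, labels, cfg, per_fold_selection = TRUE)
  expect_length(model$selected_features, 20)
  expect_gt(model$auc, 0.7)
})

test_that("the adjacent-reuse model inherits features verbatim", {
  sh <- shared_clr()
  labels <- label_binary(sh$meta)
  cfg <- classifier_config(top_k = 20, seed = 14)
  cancer_model <- fit_topk_model(sh$clr, labels, cfg)
  adj <- adjacent_reuse_model(sh$clr, sh$meta, cancer_model, cfg)
  expect_identical(adj$selected_features, cancer_model$selected_features)
  # adjacent samples share the cancer shift, so performance is comparable
  expect_gt(adj$auc, cancer_model$auc - 0.1)

  fake <- cancer_model
  fake$selected_features <- c("not_a_genus", cancer_model$selected_features)
  expect_error(adjacent_reuse_model(sh$clr, sh$meta, fake, cfg), "not_a_genus")
})

test_that("adjacent samples drawn from the control distribution give chance AUC", {
  sim <- generate_cohorts(synthetic_spec(
    n_cohorts = 2,
    samples_per_cohort_per_group = c(
      normal = 20, benign = 10, cancer = 20, cancer_adjacent = 10
    ),
    n_taxa = 60, n_planted = 6, disease_log2fc = 2,
    adjacent_log2fc = 0, # adjacent tissue without the tumour shift
    seed = 77
  ))
  genus <- aggregate_to_genus(drop_unmapped_samples(filter_taxa(sim$table)))
  clr <- clr_transform(genus)
  cfg <- classifier_config(top_k = 20, seed = 77)
  cancer_model <- fit_topk_model(clr, label_binary(sim$metadata), cfg)
  adj <- adjacent_reuse_model(clr, sim$metadata, cancer_model, cfg)
  expect_gt(adj$auc, 0.3)
  expect_lt(adj$auc, 0.7)
})
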