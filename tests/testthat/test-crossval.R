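# compact planted multi-cohort dataset for transfer tests
cv_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_cohorts(synthetic_spec(
        n_cohorts = 3,
        samples_per_cohort_per_group = c(normal = 15, cancer = 15),
        n_taxa = 60, n_planted = 6, disease_log2fc = 2,
        batch_sd = 0.3, seed = 2024
      ))
      genus <- aggregate_to_genus(drop_unmapped_samples(filter_taxa(sim$table)))
      cache <<- list(
        clr = clr_transform(genus), meta = sim$metadata,
        labels = label_binary(sim$metadata),
        cfg = classifier_config(n_trees = 300, top_k = 20, seed = 31)
      )
    }
    cache
  }
})

test_that("transfer matrices have the declared structure", {
  fx <- cv_fixture()
  tm <- cohort_to_cohort(fx$clr, fx$meta, fx$labels, fx$cfg, n_repeats = 3)
  expect_s3_class(tm, "transfer_matrix")
  expect_equal(dim(tm$auc), c(3, 3))
  expect_true(all(tm$auc >= 0 & tm$auc <= 1, na.rm = TRUE))
  off <- tm$auc
  diag(off) <- NA
  expect_equal(tm$avg_transfer, mean(off, na.rm = TRUE))
  expect_length(tm$loco_row, 3)
  # strong planted signal, mild batch: transfer generalizes
  expect_gt(tm$avg_transfer, 0.8)
})

test_that("transfer evaluation is deterministic and order-independent", {
  fx <- cv_fixture()
  t1 <- cohort_to_cohort(fx$clr, fx$meta, fx$labels, fx$cfg,
    include_diagonal = FALSE, loco = FALSE
  )
  t2 <- cohort_to_cohort(fx$clr, fx$meta, fx$labels, fx$cfg,
    include_diagonal = FALSE, loco = FALSE
  )
  expect_identical(t1$auc, t2$auc)
})

test_that("the matrix is not forced symmetric", {
  fx <- cv_fixture()
  tm <- cohort_to_cohort(fx$clr, fx$meta, fx$labels, fx$cfg,
    include_diagonal = FALSE, loco = FALSE
  )
  expect_false(isTRUE(all.equal(tm$auc, t(tm$auc))))
})

test_that("LOCO with two cohorts equals the transfer off-diagonal exactly", {
  sim <- generate_cohorts(synthetic_spec(
    n_cohorts = 2,
    samples_per_cohort_per_group = c(normal = 12, cancer = 12),
    n_taxa = 40, n_planted = 4, disease_log2fc = 1.5, seed = 555
  ))
  genus <- aggregate_to_genus(drop_unmapped_samples(filter_taxa(sim$table)))
  clr <- clr_transform(genus)
  labels <- label_binary(sim$metadata)
  cfg <- classifier_config(n_trees = 300, top_k = 15, seed = 8)
  tm <- cohort_to_cohort(clr, sim$metadata, labels, cfg,
    include_diagonal = FALSE, loco = FALSE
  )
  lo <- loco_validation(clr, sim$metadata, labels, cfg)
  # training pool of "all other cohorts" is the single other cohort
  expect_equal(lo$auc_by_cohort[["cohort01"]], tm$auc["cohort02", "cohort01"])
  expect_equal(lo$auc_by_cohort[["cohort02"]], tm$auc["cohort01", "cohort02"])
})

test_that("single-class cohorts are flagged missing, never zero", {
  fx <- cv_fixture()
  meta <- fx$meta
  # make cohort03 cancer-only by relabelling its normals as a different study's
  drop_ids <- meta$sample_id[meta$study == "cohort03" & meta$group == "normal"]
  keep <- !(fx$labels$sample_id %in% drop_ids)
  labels <- fx$labels[keep, , drop = FALSE]
  tm <- suppressWarnings(cohort_to_cohort(
    fx$clr, meta, labels, fx$cfg,
    include_diagonal = FALSE, loco = FALSE
  ))
  expect_true(all(is.na(tm$auc["cohort03", ])))
  expect_true(all(is.na(tm$auc[, "cohort03"])))
  expect_false(any(tm$auc == 0, na.rm = TRUE))
  # off-diagonal among the healthy cohorts still present
  expect_false(is.na(tm$auc["cohort01", "cohort02"]))
})

test_that("matrix summaries do the advertised arithmetic", {
  m <- structure(
    list(
      cohorts = c("a", "b"),
      auc = matrix(c(0.9, 0.7, 0.6, 0.95), 2, 2,
        dimnames = list(c("a", "b"), c("a", "b"))
      ),
      loco_row = c(a = 0.8, b = 0.7),
      diagonal_mode = "split_70_30",
      avg_transfer = 0.65, avg_loco = 0.75
    ),
    class = "transfer_matrix"
  )
  s <- summarize_matrix(m)
  expect_equal(s$avg_transfer, mean(c(0.7, 0.6)))
  expect_equal(s$avg_loco, 0.75)
  expect_equal(s$avg_diagonal, mean(c(0.9, 0.95)))
  expect_equal(s$per_train_cohort$train_cohort[1], "b") # 0.7 beats 0.6
  m$auc[1, 2] <- NA
  expect_equal(summarize_matrix(m)$avg_transfer, 0.7)
})

test_that("diagonal modes differ only on the diagonal", {
  fx <- cv_fixture()
  a <- cohort_to_cohort(fx$clr, fx$meta, fx$labels, fx$cfg,
    diagonal_mode = "split_70_30", n_repeats = 2, loco = FALSE
  )
  b <- cohort_to_cohort(fx$clr, fx$meta, fx$labels, fx$cfg,
    diagonal_mode = "nested_cv", loco = FALSE
  )
  off <- function(m) {
    x <- m$auc
    diag(x) <- NA
    x
  }
  expect_identical(off(a), off(b))
  expect_false(identical(diag(a$auc), diag(b$auc)))
})

test_that("larger training cohorts make better training sets on average", {
  sim <- generate_cohorts(synthetic_spec(
    n_cohorts = 1,
    samples_per_cohort_per_group = c(normal = 40, cancer = 40),
    n_taxa = 50, n_planted = 5, disease_log2fc = 1.2,
    batch_sd = 0.6, seed = 3100
  ))
  small1 <- generate_cohorts(synthetic_spec(
    n_cohorts = 2,
    samples_per_cohort_per_group = c(normal = 8, cancer = 8),
    n_taxa = 50, n_planted = 5, disease_log2fc = 1.2,
    batch_sd = 0.6, seed = 3100
  ))
  # same seed: same planted taxa and lineages; relabel to three studies
  small1$metadata$study <- sub("cohort0", "small0", small1$metadata$study)
  rename <- function(x) sub("cohort0", "small0", x)
  small1$metadata$sample_id <- rename(small1$metadata$sample_id)
  names(small1$table) <- ifelse(
    names(small1$table) %in% c("taxon_id", "lineage"),
    names(small1$table), rename(names(small1$table))
  )
  merged <- merge_tables(
    list(sim$table, small1$table),
    list(sim$metadata, small1$metadata)
  )
  genus <- aggregate_to_genus(drop_unmapped_samples(filter_taxa(merged$table)))
  clr <- clr_transform(genus)
  labels <- label_binary(merged$metadata)
  tm <- cohort_to_cohort(clr, merged$metadata, labels,
    classifier_config(n_trees = 300, top_k = 20, seed = 12),
    include_diagonal = FALSE, loco = FALSE
  )
  s <- summarize_matrix(tm)
  expect_equal(s$per_train_cohort$train_cohort[1], "cohort01")
})
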