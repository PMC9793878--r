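test_that("TSV round-trip preserves a toy table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- toy_table()
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back, tab)
  expect_equal(dim(ft_counts(back)), c(3, 3))
})

test_that("malformed counts files produce errors naming the offender", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "taxon_id\tlineage\ts1",
    "tA\tk__Bacteria;p__;c__;o__;f__;g__A\t3",
    "tA\tk__Bacteria;p__;c__;o__;f__;g__A\t4"
  ), path)
  expect_error(read_feature_table(path), "tA")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "taxon_id\tlineage\ts1",
    "tA\tk__Bacteria;p__;c__;o__;f__;g__A\toops"
  ), path2)
  expect_error(read_feature_table(path2), "non-numeric")

  m <- matrix(-1, 1, 1, dimnames = list("s1", "tA"))
  expect_error(
    validate_feature_table(tibble::tibble(taxon_id = "tA", lineage = "", s1 = -1)),
    "negative"
  )
  expect_error(read_feature_table(tempfile()), "no such file")
})

test_that("taxonomy filter removes organelles and kingdom-unclassified taxa", {
  m <- matrix(1, 4, 5, dimnames = list(
    paste0("s", 1:4),
    paste0("t", 1:5)
  ))
  tab <- feature_table(t(t(m)), c(
    "k__Bacteria;p__Cyanobacteria;c__Chloroplast;o__;f__;g__X",
    "k__Bacteria;p__Proteobacteria;c__;o__;f__Mitochondria;g__",
    "k__;p__;c__;o__;f__;g__Y",
    "k__Bacteria;p__Firmicutes;c__;o__;f__;g__",
    "k__Bacteria;p__Firmicutes;c__;o__;f__;g__Z"
  ))
  out <- filter_taxa(tab)
  # kingdom-classified, non-organelle taxa survive even with empty genus
  expect_equal(out$taxon_id, c("t4", "t5"))
  expect_equal(ft_sample_ids(out), ft_sample_ids(tab))
  # a clean table passes through unchanged
  expect_identical(filter_taxa(out), out)
})

test_that("all-zero samples are dropped and only those", {
  tab <- toy_table()
  tab$s2 <- 0
  out <- drop_unmapped_samples(tab)
  expect_setequal(ft_sample_ids(out), c("s1", "s3"))
  expect_identical(drop_unmapped_samples(toy_table()), toy_table())
})

test_that("genus aggregation sums shared genera and drops unnamed ones", {
  m <- matrix(c(3, 4, 5, 2), 1, 4, dimnames = list("s1", paste0("asv", 1:4)))
  tab <- feature_table(m, c(
    "k__Bacteria;p__F;c__;o__;f__;g__Blautia",
    "k__Bacteria;p__F;c__;o__;f__;g__Blautia",
    "k__Bacteria;p__F;c__;o__;f__Lachnospiraceae;g__",
    "k__Bacteria;p__F;c__;o__;f__;g__Dorea"
  ))
  out <- aggregate_to_genus(tab)
  expect_setequal(out$taxon_id, c("Blautia", "Dorea"))
  expect_equal(out$s1[out$taxon_id == "Blautia"], 7)
  expect_equal(sum(ft_counts(out)), 9) # asv3 dropped

  kept <- aggregate_to_genus(tab, keep_unclassified = TRUE)
  expect_true("unclassified_Lachnospiraceae" %in% kept$taxon_id)
  expect_equal(sum(ft_counts(kept)), sum(ft_counts(tab)))
})

test_that("total counts never increase through the filtering pipeline", {
  sim <- shared_sim()
  t0 <- sum(ft_counts(sim$table))
  t1 <- filter_taxa(sim$table)
  t2 <- drop_unmapped_samples(t1)
  t3 <- aggregate_to_genus(t2)
  expect_lte(sum(ft_counts(t1)), t0)
  expect_lte(sum(ft_counts(t2)), sum(ft_counts(t1)))
  expect_lte(sum(ft_counts(t3)), sum(ft_counts(t2)))
})

test_that("merging takes the taxon union, fills zeros and keeps totals", {
  m1 <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a1", "a2"), c("tA", "tB")))
  m2 <- matrix(c(5, 6, 7, 8), 2, 2, dimnames = list(c("b1", "b2"), c("tC", "tD")))
  lin <- function(g) sprintf("k__Bacteria;p__;c__;o__;f__;g__%s", g)
  meta1 <- tibble::tibble(
    sample_id = c("a1", "a2"), study = "s1", group = "normal",
    sample_type = "tissue", age = NA_real_, bmi = NA_real_
  )
  meta2 <- dplyr::mutate(meta1, sample_id = c("b1", "b2"), study = "s2")
  out <- merge_tables(
    list(feature_table(m1, lin(c("A", "B"))), feature_table(m2, lin(c("C", "D")))),
    list(meta1, meta2)
  )
  expect_equal(sort(ft_taxon_ids(out$table)), c("tA", "tB", "tC", "tD"))
  expect_length(ft_sample_ids(out$table), 4)
  expect_equal(sum(ft_counts(out$table)), sum(m1) + sum(m2))
  expect_equal(unname(ft_counts(out$table)["b1", "tA"]), 0)
  expect_equal(out$metadata$sample_id, ft_sample_ids(out$table))
})

test_that("merging is associative up to row and column order", {
  lin <- function(g) sprintf("k__Bacteria;p__;c__;o__;f__;g__%s", g)
  mk <- function(ids, taxa, study) {
    m <- matrix(seq_along(ids) + 1, length(ids), length(taxa),
      dimnames = list(ids, taxa)
    )
    list(
      tab = feature_table(m, lin(taxa)),
      meta = tibble::tibble(
        sample_id = ids, study = study, group = "normal",
        sample_type = "tissue", age = NA_real_, bmi = NA_real_
      )
    )
  }
  x <- mk(c("x1", "x2"), c("tA", "tB"), "s1")
  y <- mk(c("y1"), c("tB", "tC"), "s2")
  z <- mk(c("z1", "z2"), c("tA", "tD"), "s3")
  left <- merge_tables(
    list(merge_tables(list(x$tab, y$tab), list(x$meta, y$meta))$table, z$tab),
    list(merge_tables(list(x$tab, y$tab), list(x$meta, y$meta))$metadata, z$meta)
  )
  right <- merge_tables(
    list(x$tab, merge_tables(list(y$tab, z$tab), list(y$meta, z$meta))$table),
    list(x$meta, merge_tables(list(y$tab, z$tab), list(y$meta, z$meta))$metadata)
  )
  ids <- sort(ft_sample_ids(left$table))
  taxa <- sort(ft_taxon_ids(left$table))
  expect_equal(
    ft_counts(left$table)[ids, taxa],
    ft_counts(right$table)[ids, taxa]
  )
})

test_that("conflicting lineages for one taxon ID abort the merge", {
  m <- matrix(1, 1, 1, dimnames = list("s1", "tA"))
  meta <- tibble::tibble(
    sample_id = "s1", study = "s", group = "normal",
    sample_type = "tissue", age = NA_real_, bmi = NA_real_
  )
  meta2 <- dplyr::mutate(meta, sample_id = "s2")
  m2 <- matrix(1, 1, 1, dimnames = list("s2", "tA"))
  expect_error(
    merge_tables(
      list(
        feature_table(m, "k__Bacteria;p__X;c__;o__;f__;g__A"),
        feature_table(m2, "k__Bacteria;p__Y;c__;o__;f__;g__A")
      ),
      list(meta, meta2)
    ),
    "conflicting lineages"
  )
})
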