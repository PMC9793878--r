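#' Read a counts table from TSV
#'
#' The canonical dialect has taxa as rows; the first column is the taxon ID,
#' the second the semicolon-delimited lineage, and every remaining column one
#' sample of non-negative counts. Input taxon order is preserved.
#'
#' @param path path to the TSV file
#' @param lineage_required if `TRUE` (default) a missing/empty lineage column
#'   is an error; if `FALSE` an empty lineage is filled in
#' @return a feature table tibble (see [feature_table()])
#' @export
read_feature_table <- function(path, lineage_required = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(raw) < 2) stop("counts TSV needs at least taxon_id + lineage columns", call. = FALSE)
  names(raw)[1] <- "taxon_id"
  if (names(raw)[2] != "lineage") {
    if (lineage_required) {
      stop("second column must be 'lineage' (got '", names(raw)[2], "')", call. = FALSE)
    }
    raw <- dplyr::mutate(raw, lineage = "", .after = "taxon_id")
  }
  raw$taxon_id <- as.character(raw$taxon_id)
  raw$lineage <- dplyr::coalesce(as.character(raw$lineage), "")
  sample_cols <- setdiff(names(raw), c("taxon_id", "lineage"))
  for (s in sample_cols) {
    v <- raw[[s]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop("non-numeric count at taxon '", raw$taxon_id[bad[1]],
          "', sample '", s, "'",
          call. = FALSE
        )
      }
      raw[[s]] <- vn
    }
  }
  validate_feature_table(raw)
}

#' Read sample metadata from TSV
#'
#' Expected columns: `sample_id`, `study`, `group`, `sample_type`, `age`,
#' `bmi`. `group` must come from `{normal, benign, cancer, cancer_adjacent}`
#' and `sample_type` from `{tissue, stool}`; `age`/`bmi` may be missing (NA).
#'
#' @param path path to the metadata TSV
#' @return a tibble of per-sample metadata
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    study = readr::col_character(),
    group = readr::col_character(),
    sample_type = readr::col_character(),
    age = readr::col_double(),
    bmi = readr::col_double()
  ), progress = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta a candidate metadata tibble
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "study", "group", "sample_type")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  bad_g <- setdiff(unique(meta$group), c("normal", "benign", "cancer", "cancer_adjacent"))
  if (length(bad_g) > 0) {
    stop("unknown group label(s): ", paste(bad_g, collapse = ", "), call. = FALSE)
  }
  bad_t <- setdiff(unique(meta$sample_type), c("tissue", "stool"))
  if (length(bad_t) > 0) {
    stop("unknown sample_type label(s): ", paste(bad_t, collapse = ", "), call. = FALSE)
  }
  if (!"age" %in% names(meta)) meta$age <- NA_real_
  if (!"bmi" %in% names(meta)) meta$bmi <- NA_real_
  tibble::as_tibble(meta)
}

#' Remove organelle and kingdom-unclassified taxa
#'
#' Drops taxa whose lineage contains "Chloroplast" or "Mitochondria" at any
#' rank, and taxa unclassified at the kingdom level (empty `k__`). All samples
#' and the order of the remaining taxa are preserved.
#'
#' @param table a feature table tibble
#' @return the filtered feature table (possibly with zero rows)
#' @export
filter_taxa <- function(table) {
  validate_feature_table(table)
  kingdom <- lineage_rank(table$lineage, "kingdom")
  organelle <- stringr::str_detect(table$lineage, "Chloroplast|Mitochondria")
  keep <- !organelle & kingdom != ""
  table[keep, , drop = FALSE]
}

#' Drop samples with no mapped reads
#'
#' Removes samples whose total count is zero (typically after [filter_taxa()]
#' has removed every taxon they contained).
#'
#' @param table a feature table tibble
#' @return the table without all-zero samples
#' @export
drop_unmapped_samples <- function(table) {
  validate_feature_table(table)
  samples <- ft_sample_ids(table)
  if (length(samples) == 0 || nrow(table) == 0) {
    return(table)
  }
  totals <- colSums(table[, samples, drop = FALSE])
  drop <- samples[totals == 0]
  if (length(drop) == 0) {
    return(table)
  }
  table[, setdiff(names(table), drop), drop = FALSE]
}

#' Aggregate a feature table to genus level
#'
#' Sums counts over taxa sharing a (non-empty) genus label. Taxa with an empty
#' genus are dropped by default, or kept as `"unclassified_<family>"` bins.
#' Output taxon IDs are genus names; the lineage kept for a genus is the first
#' lineage seen for it, with any finer detail beyond genus irrelevant.
#'
#' @param table a feature table tibble with lineages
#' @param keep_unclassified keep empty-genus taxa as `unclassified_<family>`?
#' @return a genus-level feature table
#' @export
aggregate_to_genus <- function(table, keep_unclassified = FALSE) {
  validate_feature_table(table)
  genus <- lineage_rank(table$lineage, "genus")
  if (keep_unclassified) {
    fam <- lineage_rank(table$lineage, "family")
    genus <- ifelse(genus == "", paste0("unclassified_", fam), genus)
  }
  keep <- genus != "" & genus != "unclassified_"
  tab <- table[keep, , drop = FALSE]
  genus <- genus[keep]
  if (nrow(tab) == 0) {
    return(tab)
  }
  samples <- ft_sample_ids(tab)
  tab |>
    dplyr::mutate(.genus = genus) |>
    dplyr::group_by(.data$.genus) |>
    dplyr::summarise(
      lineage = dplyr::first(.data$lineage),
      dplyr::across(dplyr::all_of(samples), sum),
      .groups = "drop"
    ) |>
    dplyr::rename(taxon_id = ".genus") |>
    dplyr::arrange(match(.data$taxon_id, unique(genus))) |>
    validate_feature_table()
}

#' Merge per-cohort feature tables and metadata
#'
#' Takes the union of taxa (absent counts become 0) and the concatenation of
#' samples. Sample IDs must be globally unique; pass `prefix_study = TRUE` to
#' prefix each cohort's sample IDs with its study label first. Conflicting
#' lineages for a shared taxon ID are an error.
#'
#' @param tables list of feature table tibbles
#' @param metas list of metadata tibbles, aligned with `tables`
#' @param prefix_study prefix sample IDs with the study label?
#' @return a list with elements `table` and `metadata`
#' @export
merge_tables <- function(tables, metas, prefix_study = FALSE) {
  stopifnot(length(tables) == length(metas), length(tables) >= 1)
  tables <- purrr::map(tables, validate_feature_table)
  metas <- purrr::map(metas, validate_sample_metadata)
  if (prefix_study) {
    for (i in seq_along(tables)) {
      study <- unique(metas[[i]]$study)
      stopifnot(length(study) == 1)
      old <- ft_sample_ids(tables[[i]])
      new <- paste(study, old, sep = "_")
      names(tables[[i]])[match(old, names(tables[[i]]))] <- new
      metas[[i]]$sample_id <- paste(study, metas[[i]]$sample_id, sep = "_")
    }
  }
  all_samples <- unlist(purrr::map(tables, ft_sample_ids))
  if (anyDuplicated(all_samples)) {
    stop("sample IDs collide across cohorts; use prefix_study = TRUE", call. = FALSE)
  }
  lin <- dplyr::bind_rows(purrr::map(tables, ~ .x[, c("taxon_id", "lineage")]))
  conflict <- lin |>
    dplyr::distinct() |>
    dplyr::count(.data$taxon_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    stop("conflicting lineages for taxon ID(s): ",
      paste(conflict$taxon_id, collapse = ", "),
      call. = FALSE
    )
  }
  merged <- purrr::reduce(tables, function(a, b) {
    out <- dplyr::full_join(a, b, by = c("taxon_id", "lineage"))
    out |> dplyr::mutate(dplyr::across(-c("taxon_id", "lineage"), ~ tidyr::replace_na(.x, 0)))
  })
  meta <- dplyr::bind_rows(metas)
  stopifnot(all(ft_sample_ids(merged) %in% meta$sample_id))
  meta <- meta[match(ft_sample_ids(merged), meta$sample_id), , drop = FALSE]
  list(table = validate_feature_table(merged), metadata = meta)
}

#' Write a feature table / metadata pair to TSV
#'
#' Inverse of [read_feature_table()] / [read_sample_metadata()].
#'
#' @param table a feature table tibble
#' @param path output TSV path
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param meta a metadata tibble
#' @export
write_sample_metadata <- function(meta, path) {
  validate_sample_metadata(meta)
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}
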