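#' Feature tables
#'
#' A feature table is an ordinary tibble in the same shape as the on-disk TSV:
#' one row per taxon with a `taxon_id` column, a `lineage` column holding the
#' ranked semicolon-delimited lineage string
#' (`"k__...;p__...;c__...;o__...;f__...;g__..."`), and one numeric column per
#' sample. Keeping the table a plain tibble means every dplyr verb works on it
#' directly; the helpers below move between that shape and the samples-by-taxa
#' matrix the numerical routines want.
#'
#' @param counts a samples-by-taxa numeric matrix with dimnames
#' @param lineages character vector of lineage strings, one per taxon
#'   (column of `counts`)
#' @return `feature_table()` returns a tibble with columns `taxon_id`,
#'   `lineage`, then one column per sample.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("gA", "gB"))
#' )
#' feature_table(m, c("k__Bacteria;p__;c__;o__;f__;g__gA",
#'                    "k__Bacteria;p__;c__;o__;f__;g__gB"))
#' @export
feature_table <- function(counts, lineages = NULL) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)), !is.null(rownames(counts)))
  if (is.null(lineages)) lineages <- rep("", ncol(counts))
  stopifnot(length(lineages) == ncol(counts))
  out <- tibble::tibble(
    taxon_id = colnames(counts),
    lineage = unname(lineages)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(t(counts)))
  validate_feature_table(out)
}

#' @rdname feature_table
#' @param table a feature table tibble
#' @return `ft_sample_ids()` the sample (column) names; `ft_taxon_ids()` the
#'   taxon IDs; `ft_counts()` the samples-by-taxa numeric matrix;
#'   `ft_lineages()` a named character vector of lineages.
#' @export
ft_sample_ids <- function(table) {
  setdiff(names(table), c("taxon_id", "lineage"))
}

#' @rdname feature_table
#' @export
ft_taxon_ids <- function(table) table$taxon_id

#' @rdname feature_table
#' @export
ft_counts <- function(table) {
  samples <- ft_sample_ids(table)
  m <- t(as.matrix(table[, samples, drop = FALSE]))
  dimnames(m) <- list(samples, table$taxon_id)
  m
}

#' @rdname feature_table
#' @export
ft_lineages <- function(table) {
  stats::setNames(table$lineage, table$taxon_id)
}

#' Validate a feature table
#'
#' Checks the structural invariants: unique taxon and sample IDs, numeric
#' non-negative counts, a lineage column. Returns the table invisibly-castable
#' (so it can sit in a pipe) or throws with coordinates of the offence.
#'
#' @param table a candidate feature table tibble
#' @return the validated table
#' @export
validate_feature_table <- function(table) {
  if (!all(c("taxon_id", "lineage") %in% names(table))) {
    stop("feature table needs 'taxon_id' and 'lineage' columns", call. = FALSE)
  }
  dup_t <- table$taxon_id[duplicated(table$taxon_id)]
  if (length(dup_t) > 0) {
    stop("duplicated taxon ID(s): ", paste(unique(dup_t), collapse = ", "),
      call. = FALSE
    )
  }
  samples <- ft_sample_ids(table)
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s) > 0) {
    stop("duplicated sample ID(s): ", paste(unique(dup_s), collapse = ", "),
      call. = FALSE
    )
  }
  for (s in samples) {
    col <- table[[s]]
    if (!is.numeric(col)) {
      stop("non-numeric counts in sample '", s, "'", call. = FALSE)
    }
    bad <- which(is.na(col) | col < 0)
    if (length(bad) > 0) {
      stop(
        "negative or missing count at taxon '", table$taxon_id[bad[1]],
        "', sample '", s, "'",
        call. = FALSE
      )
    }
  }
  table
}

# Ranks understood in lineage strings, in order.
.lineage_ranks <- c(
  kingdom = "k__", phylum = "p__", class = "c__",
  order = "o__", family = "f__", genus = "g__"
)

#' Extract one rank from lineage strings
#'
#' @param lineages character vector of `"k__...;p__...;...;g__..."` strings
#' @param rank one of kingdom, phylum, class, order, family, genus
#' @return character vector of rank labels, `""` where the rank is empty or
#'   absent
#' @export
lineage_rank <- function(lineages, rank = c(
                           "kingdom", "phylum", "class",
                           "order", "family", "genus"
                         )) {
  rank <- match.arg(rank)
  prefix <- .lineage_ranks[[rank]]
  idx <- match(rank, names(.lineage_ranks))
  parts <- stringr::str_split(lineages, ";")
  purrr::map_chr(parts, function(p) {
    p <- stringr::str_trim(p)
    hit <- p[stringr::str_starts(p, stringr::fixed(prefix))]
    if (length(hit) >= 1) {
      return(stringr::str_remove(hit[1], stringr::fixed(prefix)))
    }
    if (length(p) >= idx && !any(stringr::str_detect(p, "__"))) {
      return(p[idx])
    }
    ""
  })
}
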