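#' Per-sample relative abundance
#'
#' Divides each sample's counts by its total, so every sample (row of the
#' returned matrix view) sums to 1. Samples with zero total are an error —
#' they should have been removed by [drop_unmapped_samples()].
#'
#' @param table a feature table tibble
#' @return a tibble with a `sample_id` column and one column per taxon,
#'   rows summing to 1
#' @export
relative_abundance <- function(table) {
  m <- ft_counts(validate_feature_table(table))
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop(
      "zero-total sample(s): ",
      paste(rownames(m)[totals == 0], collapse = ", "),
      call. = FALSE
    )
  }
  .mat_to_tbl(m / totals)
}

#' Centered log-ratio transform
#'
#' `clr(s, t) = log(c(s, t) + pseudocount) - mean_t log(c(s, .) + pseudocount)`.
#' The pseudocount is added to every count (not only zeros), which preserves
#' within-sample rank order; rows of the result sum to zero. On all-positive
#' counts the transform becomes scale-invariant as the pseudocount tends to 0.
#'
#' @param table a feature table tibble (typically genus-aggregated)
#' @param pseudocount positive value added to all counts before the log
#' @return a tibble with `sample_id` plus one column per taxon of CLR values;
#'   the pseudocount used is attached as attribute `"pseudocount"`
#' @examples
#' m <- matrix(c(1, 3), 1, 2, dimnames = list("s1", c("a", "b")))
#' clr_transform(feature_table(m)) # -0.4236, +0.4236
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive", call. = FALSE)
  }
  m <- ft_counts(validate_feature_table(table))
  lg <- log(m + pseudocount)
  out <- lg - rowMeans(lg)
  res <- .mat_to_tbl(out)
  attr(res, "pseudocount") <- pseudocount
  res
}

#' Mid-rank transform
#'
#' Ranks a vector with ties given mid-ranks, so that the ranks always sum to
#' `n (n + 1) / 2`.
#'
#' @param values numeric vector (length >= 1)
#' @return numeric vector of mid-ranks
#' @export
rank_transform <- function(values) {
  stopifnot(length(values) >= 1)
  rank(values, ties.method = "average")
}

# samples-by-features matrix -> tibble with sample_id first column
.mat_to_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

# tibble with sample_id column -> samples-by-features matrix
.tbl_to_mat <- function(tbl) {
  stopifnot("sample_id" %in% names(tbl))
  m <- as.matrix(tbl[, setdiff(names(tbl), "sample_id"), drop = FALSE])
  rownames(m) <- tbl$sample_id
  m
}
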