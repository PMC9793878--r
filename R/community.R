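#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = 1 - 2 * sum_t min(c_it, c_jt) / (sum_t c_it + sum_t c_jt)`,
#' computed on raw counts (CLR values can be negative and are not valid
#' input). Backed by `vegan::vegdist`.
#'
#' @param table a feature table tibble
#' @param proportions divide each sample by its total first? Bray-Curtis on
#'   proportions removes library-size differences from the distance.
#' @return a symmetric numeric matrix with sample IDs as dimnames, zero
#'   diagonal, entries in `[0, 1]`
#' @export
bray_curtis <- function(table, proportions = FALSE) {
  m <- ft_counts(validate_feature_table(table))
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop(
      "zero-total sample(s): ",
      paste(rownames(m)[totals == 0], collapse = ", "),
      call. = FALSE
    )
  }
  if (proportions) m <- m / totals
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  d
}

#' Principal coordinate analysis
#'
#' Classical metric multidimensional scaling of a distance matrix:
#' eigendecomposition of the double-centered matrix `-1/2 J D^2 J`. Negative
#' eigenvalues are reported but excluded from the `proportion_explained`
#' denominator. For a reproducible orientation, each axis is flipped so its
#' first nonzero coordinate is positive.
#'
#' @param d symmetric distance matrix with sample IDs as dimnames
#' @param n_axes number of axes to return (capped at the number available)
#' @return an object of class `crossbiome_ordination`: list with
#'   `coordinates` (tibble `sample_id`, `Axis1`, ...), `eigenvalues` and
#'   `proportion_explained`
#' @export
pcoa_ordination <- function(d, n_axes = 2) {
  stopifnot(n_axes >= 1)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(d)
  ids <- rownames(d) %||% paste0("s", seq_len(n))
  if (n == 1) {
    return(structure(
      list(
        coordinates = tibble::tibble(sample_id = ids, Axis1 = 0),
        eigenvalues = 0,
        proportion_explained = NA_real_
      ),
      class = "crossbiome_ordination"
    ))
  }
  # double centering of squared distances
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eig <- eigen(g, symmetric = TRUE)
  vals <- eig$values
  keep <- seq_len(min(n_axes, sum(vals > 1e-10)))
  if (length(keep) == 0) keep <- 1
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(pmax(vals[keep], 0)), nrow = length(keep))
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  pos <- sum(vals[vals > 1e-10])
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(sample_id = ids),
        tibble::as_tibble(coords)
      ),
      eigenvalues = vals,
      proportion_explained = if (pos > 0) vals[keep] / pos else rep(NA_real_, length(keep))
    ),
    class = "crossbiome_ordination"
  )
}

#' @export
print.crossbiome_ordination <- function(x, ...) {
  cat(
    "PCoA ordination:", nrow(x$coordinates), "samples,",
    ncol(x$coordinates) - 1, "axes\n"
  )
  pe <- round(100 * x$proportion_explained, 1)
  cat("proportion explained:", paste0(pe, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Per-group mean composition at a taxonomic rank
#'
#' Aggregates counts at the requested rank, converts each sample to relative
#' abundances and averages within groups, so each group's composition sums
#' to 1.
#'
#' @param table a feature table tibble with lineages covering `rank`
#' @param meta a metadata tibble
#' @param rank `"phylum"` or `"genus"`
#' @param group_by metadata column to average within (default `"group"`)
#' @return a tibble `group`, `taxon`, `mean_rel_abundance`
#' @export
composition_summary <- function(table, meta, rank = c("phylum", "genus"),
                                group_by = "group") {
  rank <- match.arg(rank)
  meta <- validate_sample_metadata(meta)
  table <- validate_feature_table(table)
  labels <- lineage_rank(table$lineage, rank)
  if (all(labels == "")) stop("lineages carry no ", rank, " labels", call. = FALSE)
  keep <- labels != ""
  m <- ft_counts(table[keep, , drop = FALSE])
  agg <- t(rowsum(t(m), group = labels[keep])) # samples x rank-levels
  totals <- rowSums(agg)
  if (any(totals == 0)) {
    agg <- agg[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  rel <- agg / totals
  meta <- meta[match(rownames(rel), meta$sample_id), , drop = FALSE]
  .mat_to_tbl(rel) |>
    dplyr::mutate(group = meta[[group_by]]) |>
    tidyr::pivot_longer(-c("sample_id", "group"),
      names_to = "taxon", values_to = "rel_abundance"
    ) |>
    dplyr::group_by(.data$group, .data$taxon) |>
    dplyr::summarise(
      mean_rel_abundance = mean(.data$rel_abundance),
      .groups = "drop"
    )
}

#' Per-group 2D summary of an ordination
#'
#' Mean and covariance of the first two ordination axes within each group —
#' the numbers a 95% confidence ellipse is drawn from.
#'
#' @param ord a `crossbiome_ordination`
#' @param meta a metadata tibble
#' @param group_by metadata column defining the groups
#' @return tibble `group`, `mean_Axis1`, `mean_Axis2`, `var_Axis1`,
#'   `var_Axis2`, `cov_Axis12`, `n`
#' @export
ordination_group_summary <- function(ord, meta, group_by = "group") {
  co <- ord$coordinates
  stopifnot(all(c("Axis1", "Axis2") %in% names(co)))
  meta <- validate_sample_metadata(meta)
  co$group <- meta[[group_by]][match(co$sample_id, meta$sample_id)]
  co |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_Axis1 = mean(.data$Axis1), mean_Axis2 = mean(.data$Axis2),
      var_Axis1 = stats::var(.data$Axis1), var_Axis2 = stats::var(.data$Axis2),
      cov_Axis12 = stats::cov(.data$Axis1, .data$Axis2), n = dplyr::n(),
      .groups = "drop"
    )
}
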