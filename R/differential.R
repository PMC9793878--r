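#' Define a two-group comparison
#'
#' @param name comparison label, e.g. `"cancer_tissue_vs_normal_tissue"`
#' @param sample_type `"tissue"` or `"stool"`
#' @param group_a,group_b disjoint, non-empty sets of group labels
#' @return an object of class `comparison`
#' @export
comparison <- function(name, sample_type, group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("comparison groups overlap", call. = FALSE)
  }
  structure(
    list(
      name = name, sample_type = match.arg(sample_type, c("tissue", "stool")),
      group_a = group_a, group_b = group_b
    ),
    class = "comparison"
  )
}

#' The five standard comparison strategies
#'
#' Cancer tissue vs normal tissue, cancer-adjacent tissue vs normal tissue,
#' cancer tissue vs benign tissue, cancer stool vs normal stool, and cancer
#' stool vs benign stool.
#'
#' @return a named list of [comparison()] objects
#' @export
default_comparisons <- function() {
  list(
    cancer_tissue_vs_normal_tissue =
      comparison("cancer_tissue_vs_normal_tissue", "tissue", "cancer", "normal"),
    adjacent_tissue_vs_normal_tissue =
      comparison("adjacent_tissue_vs_normal_tissue", "tissue", "cancer_adjacent", "normal"),
    cancer_tissue_vs_benign_tissue =
      comparison("cancer_tissue_vs_benign_tissue", "tissue", "cancer", "benign"),
    cancer_stool_vs_normal_stool =
      comparison("cancer_stool_vs_normal_stool", "stool", "cancer", "normal"),
    cancer_stool_vs_benign_stool =
      comparison("cancer_stool_vs_benign_stool", "stool", "cancer", "benign")
  )
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t statistic with Welch-Satterthwaite degrees of freedom.
#' Degenerate inputs are resolved explicitly: if both samples are constant
#' with equal means the result is `t = 0, p = 1`; constant samples with
#' different means give `t = +/-Inf` and `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b numeric vectors, each of length >= 2
#' @return a one-row tibble `t`, `df`, `p`, `degenerate`
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a)
  nb <- length(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(tibble::tibble(
      t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
      p = 0, degenerate = TRUE
    ))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tibble::tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Differential abundance for one comparison
#'
#' Welch's t-test per genus on CLR values between the comparison's two
#' strata. Significance follows the raw `p < alpha` rule; Benjamini-Hochberg
#' q-values are reported alongside but do not drive the flag.
#'
#' @param clr a CLR tibble from [clr_transform()]
#' @param meta a metadata tibble
#' @param cmp a [comparison()]
#' @param alpha raw p-value threshold for the `significant` flag
#' @param fdr_method method for [stats::p.adjust()]
#' @return a tibble with one row per genus: `genus`, `t_stat`, `p_value`,
#'   `q_value`, `mean_clr_a`, `mean_clr_b`, `direction`
#'   (`enriched_in_a`/`enriched_in_b`), `significant`, `comparison`
#' @export
run_comparison <- function(clr, meta, cmp, alpha = 0.05, fdr_method = "BH") {
  stopifnot(inherits(cmp, "comparison"))
  meta <- validate_sample_metadata(meta)
  m <- .tbl_to_mat(clr)
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  in_type <- meta$sample_type == cmp$sample_type
  ia <- which(in_type & meta$group %in% cmp$group_a)
  ib <- which(in_type & meta$group %in% cmp$group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop(
      "comparison '", cmp$name, "' needs >= 2 samples per side (got ",
      length(ia), " vs ", length(ib), ")",
      call. = FALSE
    )
  }
  res <- purrr::map_dfr(colnames(m), function(g) {
    wt <- welch_t(m[ia, g], m[ib, g])
    tibble::tibble(
      genus = g, t_stat = wt$t, p_value = wt$p,
      mean_clr_a = mean(m[ia, g]), mean_clr_b = mean(m[ib, g])
    )
  })
  res |>
    dplyr::mutate(
      q_value = stats::p.adjust(.data$p_value, method = fdr_method),
      direction = ifelse(.data$mean_clr_a >= .data$mean_clr_b,
        "enriched_in_a", "enriched_in_b"
      ),
      significant = .data$p_value < alpha,
      comparison = cmp$name,
      .after = "p_value"
    )
}

#' Wilcoxon rank-sum biomarker identification
#'
#' A genus qualifies as a disease biomarker when its two-sided Wilcoxon
#' rank-sum p-value between cancer and healthy-control samples (within one
#' sample type) is below `alpha` AND its mean (or median) CLR value is higher
#' in the cancer group. The exact null distribution is used when the smaller
#' group has at most `exact_max` samples and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param clr a CLR tibble
#' @param meta a metadata tibble
#' @param sample_type `"tissue"` or `"stool"`
#' @param alpha p-value threshold
#' @param location `"mean"` or `"median"` for the high-abundance rule
#' @param exact_max largest group size for the exact test
#' @return a tibble `genus`, `w_stat`, `p_value`, `location_cancer`,
#'   `location_control`, `biomarker`, `sample_type`
#' @export
wilcoxon_biomarkers <- function(clr, meta, sample_type = c("tissue", "stool"),
                                alpha = 0.05, location = c("mean", "median"),
                                exact_max = 25) {
  sample_type <- match.arg(sample_type)
  location <- match.arg(location)
  locfun <- if (location == "mean") mean else stats::median
  meta <- validate_sample_metadata(meta)
  m <- .tbl_to_mat(clr)
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  in_type <- meta$sample_type == sample_type
  ic <- which(in_type & meta$group == "cancer")
  ih <- which(in_type & meta$group == "normal")
  if (length(ic) == 0 || length(ih) == 0) {
    stop("need both cancer and normal samples of type ", sample_type, call. = FALSE)
  }
  purrr::map_dfr(colnames(m), function(g) {
    a <- m[ic, g]
    b <- m[ih, g]
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- min(length(a), length(b)) <= exact_max && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    tibble::tibble(
      genus = g, w_stat = unname(wt$statistic), p_value = wt$p.value,
      location_cancer = locfun(a), location_control = locfun(b)
    )
  }) |>
    dplyr::mutate(
      biomarker = .data$p_value < alpha &
        .data$location_cancer > .data$location_control,
      sample_type = sample_type
    )
}

#' Intersections of named genus sets
#'
#' All pairwise intersections and the full intersection with membership
#' lists — the data behind a Venn diagram of biomarker or differential sets.
#'
#' @param sets named list (length >= 2) of character vectors
#' @return a list: `sets` (inputs, de-duplicated), `pairwise` (tibble
#'   `set_a`, `set_b`, `n_overlap`, `members` list-column), `full`
#'   (character vector in every set), `union`
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- purrr::map(sets, unique)
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    ov <- intersect(sets[[p[1]]], sets[[p[2]]])
    tibble::tibble(
      set_a = p[1], set_b = p[2],
      n_overlap = length(ov), members = list(ov)
    )
  })
  list(
    sets = sets,
    pairwise = pairwise,
    full = purrr::reduce(sets, intersect),
    union = sort(unique(unlist(sets)))
  )
}
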