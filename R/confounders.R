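#' Encode a metadata field as a categorical confounder
#'
#' `study` and `sample_type` pass through as factors. `age` is cut into
#' quartile bins computed on the non-missing values of the analyzed set
#' (labels `Q1`..`Q4`). `bmi` is cut at 25 and 30 into `under_25`, `25_to_30`
#' and `over_30` (the conventional normal / overweight / obese cut points;
#' neutral bin names are used and any display labelling is left to the
#' caller). Missing values encode as `NA` and are excluded from
#' decompositions pairwise.
#'
#' @param meta a metadata tibble
#' @param name one of `"study"`, `"age"`, `"bmi"`, `"sample_type"`
#' @return a factor of length `nrow(meta)` (with `NA` for missing values)
#' @export
encode_confounder <- function(meta, name) {
  meta <- validate_sample_metadata(meta)
  if (!name %in% c("study", "age", "bmi", "sample_type")) {
    stop("unknown confounder: ", name, call. = FALSE)
  }
  switch(name,
    study = factor(meta$study),
    sample_type = factor(meta$sample_type),
    bmi = cut(meta$bmi,
      breaks = c(-Inf, 25, 30, Inf),
      labels = c("under_25", "25_to_30", "over_30"),
      right = TRUE
    ),
    age = {
      x <- meta$age
      if (all(is.na(x))) {
        factor(rep(NA_character_, length(x)), levels = paste0("Q", 1:4))
      } else {
        q <- stats::quantile(x, probs = seq(0, 1, 0.25), na.rm = TRUE, type = 7)
        q[1] <- -Inf
        q[5] <- Inf
        cut(x, breaks = unique(q), labels = paste0("Q", seq_len(length(unique(q)) - 1)))
      }
    }
  )
}

#' Variance explained by a categorical factor (eta squared)
#'
#' Between-group sum of squares over total sum of squares. Returns 0 when the
#' response has no variance at all; errors when fewer than two groups are
#' present.
#'
#' @param values numeric response (typically mid-ranks of abundances)
#' @param groups categorical factor, same length
#' @return eta squared in `[0, 1]`
#' @examples
#' eta_squared(c(1, 2, 3, 4), factor(c("A", "A", "B", "B"))) # 0.8
#' @export
eta_squared <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  mu <- mean(values)
  sst <- sum((values - mu)^2)
  if (sst == 0) {
    return(0)
  }
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mu)^2)
  ssb / sst
}

#' Variance decomposition for one feature
#'
#' One-way eta squared of the (recomputed) mid-ranks against disease status
#' and against the confounder, plus the disease p-value from a main-effects
#' two-way ANOVA (disease + confounder, no interaction, Type II sums of
#' squares) on those ranks. Samples with a missing confounder value are
#' excluded, and ranks are recomputed over exactly the samples analyzed.
#'
#' @param values numeric abundances (CLR or counts) for one feature
#' @param disease factor of disease status
#' @param confounder factor of the encoded confounder (may contain `NA`)
#' @return one-row tibble: `eta2_disease`, `eta2_confounder`, `p_disease`,
#'   `n_samples`, `degenerate` (flag set when either factor collapses to a
#'   single level, in which case the row should be excluded from plots)
#' @export
decompose_feature <- function(values, disease, confounder) {
  keep <- !is.na(values) & !is.na(disease) & !is.na(confounder)
  v <- values[keep]
  d <- droplevels(factor(disease[keep]))
  cf <- droplevels(factor(confounder[keep]))
  n <- length(v)
  if (n == 0 || nlevels(d) < 2 || nlevels(cf) < 2) {
    return(tibble::tibble(
      eta2_disease = NA_real_, eta2_confounder = NA_real_,
      p_disease = NA_real_, n_samples = n, degenerate = TRUE
    ))
  }
  r <- rank_transform(v)
  if (stats::var(r) == 0) {
    return(tibble::tibble(
      eta2_disease = 0, eta2_confounder = 0,
      p_disease = 1, n_samples = n, degenerate = FALSE
    ))
  }
  e_d <- eta_squared(r, d)
  e_c <- eta_squared(r, cf)
  fit <- stats::lm(r ~ d + cf)
  p <- tryCatch(
    {
      a2 <- car::Anova(fit, type = 2)
      a2[["Pr(>F)"]][rownames(a2) == "d"]
    },
    error = function(e) NA_real_
  )
  if (length(p) == 0 || is.na(p)) p <- 1
  tibble::tibble(
    eta2_disease = e_d, eta2_confounder = e_c,
    p_disease = max(p, .Machine$double.xmin), n_samples = n, degenerate = FALSE
  )
}

#' Variance decomposition across all features
#'
#' Runs [decompose_feature()] per feature of a CLR table (or a feature table,
#' in which case each taxon's counts are used directly) against disease status
#' and one named confounder, and flags features whose two-way-ANOVA disease
#' p-value falls under `alpha`.
#'
#' @param data a CLR tibble (from [clr_transform()]) or a feature table tibble
#' @param meta a metadata tibble covering the samples of `data`
#' @param confounder one of `"study"`, `"age"`, `"bmi"`, `"sample_type"`
#' @param alpha significance threshold for the plotting flag
#' @return a tibble with one row per feature: `feature`, `eta2_disease`,
#'   `eta2_confounder`, `p_disease`, `n_samples`, `degenerate`,
#'   `significant`, `confounder`
#' @export
decompose_all <- function(data, meta, confounder, alpha = 0.05) {
  meta <- validate_sample_metadata(meta)
  m <- if ("sample_id" %in% names(data)) .tbl_to_mat(data) else ft_counts(data)
  if (ncol(m) == 0 || nrow(m) == 0) {
    return(tibble::tibble(
      feature = character(), eta2_disease = double(),
      eta2_confounder = double(), p_disease = double(),
      n_samples = integer(), degenerate = logical(),
      significant = logical(), confounder = character()
    ))
  }
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  stopifnot(!anyNA(meta$sample_id))
  cf <- encode_confounder(meta, confounder)
  if (all(is.na(cf))) {
    warning("confounder '", confounder, "' is entirely missing; nothing to decompose")
    return(tibble::tibble(
      feature = character(), eta2_disease = double(),
      eta2_confounder = double(), p_disease = double(),
      n_samples = integer(), degenerate = logical(),
      significant = logical(), confounder = character()
    ))
  }
  disease <- factor(meta$group)
  purrr::map_dfr(colnames(m), function(f) {
    dplyr::mutate(decompose_feature(m[, f], disease, cf), feature = f, .before = 1)
  }) |>
    dplyr::mutate(
      significant = !.data$degenerate & .data$p_disease < alpha,
      confounder = confounder
    )
}
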