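#' Specification for the multi-cohort synthetic data generator
#'
#' Collects the knobs of the generative model behind [generate_cohorts()].
#' Defaults describe the study conditions the analysis pipeline is designed
#' for: several cohorts whose study-level batch effects are visible next to a
#' disease signal carried by a small minority of genera, heavy zero inflation,
#' and library sizes spread over roughly an order of magnitude.
#'
#' @param n_cohorts number of cohorts (studies)
#' @param samples_per_cohort_per_group named integer vector mapping group
#'   labels (subset of `normal`, `benign`, `cancer`, `cancer_adjacent`) to the
#'   per-cohort sample count for that group
#' @param n_taxa number of genera simulated
#' @param n_planted number of genera carrying a true disease effect
#'   (`0 <= n_planted <= n_taxa`)
#' @param disease_log2fc log2 fold-change added to planted genera in `cancer`
#'   samples (>= 0)
#' @param adjacent_log2fc log2 fold-change for `cancer_adjacent` samples;
#'   defaults to `disease_log2fc`, reflecting tumour-adjacent tissue carrying
#'   the same microbial shift as the tumour itself
#' @param batch_sd standard deviation of per-cohort, per-taxon log-scale
#'   offsets (the batch effect)
#' @param base_log_mean_sd spread of baseline taxon log-abundances
#' @param library_size_mean mean sequencing depth per sample
#' @param library_size_dispersion log-scale s.d. of library sizes
#' @param confound_age target correlation between age and the cancer
#'   indicator, in `[0, 1]`
#' @param sample_type `"tissue"` or `"stool"`; a mixed design is produced by
#'   two calls plus [merge_tables()]
#' @param n_phyla number of phyla the simulated genera are spread over (only
#'   affects lineage strings and composition summaries)
#' @param seed integer seed; the generator is deterministic given the spec
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_cohorts = 5,
                           samples_per_cohort_per_group = c(
                             normal = 30, benign = 15,
                             cancer = 30, cancer_adjacent = 15
                           ),
                           n_taxa = 200,
                           n_planted = 10,
                           disease_log2fc = 1.5,
                           adjacent_log2fc = disease_log2fc,
                           batch_sd = 0.3,
                           base_log_mean_sd = 1,
                           library_size_mean = 10000,
                           library_size_dispersion = 0.5,
                           confound_age = 0.3,
                           sample_type = c("tissue", "stool"),
                           n_phyla = 5,
                           seed = 1) {
  sample_type <- match.arg(sample_type)
  spec <- list(
    n_cohorts = as.integer(n_cohorts),
    samples_per_cohort_per_group = samples_per_cohort_per_group,
    n_taxa = as.integer(n_taxa),
    n_planted = as.integer(n_planted),
    disease_log2fc = disease_log2fc,
    adjacent_log2fc = adjacent_log2fc,
    batch_sd = batch_sd,
    base_log_mean_sd = base_log_mean_sd,
    library_size_mean = library_size_mean,
    library_size_dispersion = library_size_dispersion,
    confound_age = confound_age,
    sample_type = sample_type,
    n_phyla = as.integer(n_phyla),
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  g <- spec$samples_per_cohort_per_group
  if (length(g) == 0 || is.null(names(g)) || any(names(g) == "")) {
    stop("samples_per_cohort_per_group must be a non-empty named vector", call. = FALSE)
  }
  bad <- setdiff(names(g), c("normal", "benign", "cancer", "cancer_adjacent"))
  if (length(bad) > 0) stop("unknown group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(g < 1)) stop("group sizes must be positive", call. = FALSE)
  if (spec$n_planted > spec$n_taxa) stop("n_planted exceeds n_taxa", call. = FALSE)
  if (spec$n_planted < 0 || spec$n_taxa < 1 || spec$n_cohorts < 1) {
    stop("n_cohorts, n_taxa must be positive; n_planted non-negative", call. = FALSE)
  }
  stopifnot(
    spec$disease_log2fc >= 0, spec$batch_sd >= 0, spec$base_log_mean_sd >= 0,
    spec$library_size_mean > 0, spec$library_size_dispersion > 0,
    spec$confound_age >= 0, spec$confound_age <= 1
  )
  spec
}

#' Generate multi-cohort synthetic count data
#'
#' Generative model, per sample *s* in cohort *c*: the log-abundance of taxon
#' *t* is `base_t + batch_ct + effect_t(group_s) + N(0, 1)`, with
#' `base_t ~ N(0, base_log_mean_sd^2)` shared across the run,
#' `batch_ct ~ N(0, batch_sd^2)` shared within a cohort, and
#' `effect_t = disease_log2fc * log(2)` for planted taxa in `cancer` samples
#' (`adjacent_log2fc * log(2)` in `cancer_adjacent` samples, 0 otherwise).
#' The sample's composition is the softmax of these log-abundances and counts
#' are drawn `Multinomial(L_s, composition)` with
#' `L_s ~ lognormal(log library_size_mean, library_size_dispersion)`. Ages are
#' drawn so that the correlation between age and the cancer indicator is
#' approximately `confound_age`; BMI is drawn independently of disease.
#' Deterministic given the spec (including its seed).
#'
#' @param spec a [synthetic_spec()]
#' @return a list with elements `table` (feature table tibble), `metadata`
#'   (tibble) and `truth` (list with `planted_taxa`, `per_cohort_offsets`,
#'   `group_assignments`)
#' @examples
#' sim <- generate_cohorts(synthetic_spec(
#'   n_cohorts = 2,
#'   samples_per_cohort_per_group = c(normal = 4, cancer = 4),
#'   n_taxa = 20, n_planted = 2, seed = 7
#' ))
#' dim(sim$table)
#' @export
generate_cohorts <- function(spec) {
  spec <- validate_synthetic_spec(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  taxa <- sprintf("g_%03d", seq_len(spec$n_taxa))
  phyla <- sprintf("Phylum%02d", sample.int(spec$n_phyla, spec$n_taxa, replace = TRUE))
  lineages <- sprintf("k__Bacteria;p__%s;c__;o__;f__;g__%s", phyla, taxa)

  planted <- sort(sample.int(spec$n_taxa, spec$n_planted))
  base_log <- stats::rnorm(spec$n_taxa, 0, spec$base_log_mean_sd)
  effect <- rep(0, spec$n_taxa)
  effect[planted] <- spec$disease_log2fc * log(2)
  effect_adj <- rep(0, spec$n_taxa)
  effect_adj[planted] <- spec$adjacent_log2fc * log(2)

  groups <- names(spec$samples_per_cohort_per_group)
  cohorts <- sprintf("cohort%02d", seq_len(spec$n_cohorts))
  batch <- matrix(stats::rnorm(spec$n_cohorts * spec$n_taxa, 0, spec$batch_sd),
    nrow = spec$n_cohorts,
    dimnames = list(cohorts, taxa)
  )

  rows <- list()
  counts <- list()
  for (ci in seq_len(spec$n_cohorts)) {
    for (g in groups) {
      n <- spec$samples_per_cohort_per_group[[g]]
      eff <- switch(g,
        cancer = effect,
        cancer_adjacent = effect_adj,
        rep(0, spec$n_taxa)
      )
      for (k in seq_len(n)) {
        sid <- sprintf("%s_%s_%02d", cohorts[ci], g, k)
        loga <- base_log + batch[ci, ] + eff + stats::rnorm(spec$n_taxa)
        comp <- exp(loga - max(loga))
        comp <- comp / sum(comp)
        lib <- max(1L, round(stats::rlnorm(
          1, log(spec$library_size_mean),
          spec$library_size_dispersion
        )))
        counts[[sid]] <- as.integer(stats::rmultinom(1, lib, comp))
        rows[[sid]] <- tibble::tibble(
          sample_id = sid, study = cohorts[ci], group = g,
          sample_type = spec$sample_type
        )
      }
    }
  }
  meta <- dplyr::bind_rows(rows)
  cmat <- do.call(rbind, counts) # samples x taxa
  dimnames(cmat) <- list(names(counts), taxa)

  # age with target correlation to the cancer indicator
  is_cancer <- as.numeric(meta$group == "cancer")
  p <- mean(is_cancer)
  sd_age <- 10
  r <- spec$confound_age
  delta <- if (r >= 1 || p %in% c(0, 1)) {
    0
  } else {
    r * sd_age / sqrt((1 - r^2) * p * (1 - p))
  }
  meta$age <- round(pmin(90, pmax(
    18,
    50 + delta * (is_cancer - p) + stats::rnorm(nrow(meta), 0, sd_age)
  )), 1)
  meta$bmi <- round(pmin(45, pmax(16, stats::rnorm(nrow(meta), 27, 4))), 1)

  truth <- list(
    planted_taxa = taxa[planted],
    per_cohort_offsets = batch,
    group_assignments = stats::setNames(meta$group, meta$sample_id)
  )
  list(
    table = feature_table(cmat, lineages),
    metadata = validate_sample_metadata(meta),
    truth = truth
  )
}

# Save/restore the global RNG state so generators don't disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, globalenv())
  }
}

#' Write a synthetic fixture to disk
#'
#' Writes `counts.tsv`, `metadata.tsv` and `truth.json` under `dir` in the
#' formats the readers understand; the table/metadata round-trip losslessly
#' through [read_feature_table()] / [read_sample_metadata()].
#'
#' @param sim output of [generate_cohorts()] (or a compatible list)
#' @param dir output directory (created if needed)
#' @return invisibly, the three file paths
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_feature_table(sim$table, paths[["counts"]])
  write_sample_metadata(sim$metadata, paths[["metadata"]])
  truth <- sim$truth
  jsonlite::write_json(
    list(
      planted_taxa = as.list(truth$planted_taxa),
      per_cohort_offsets = truth$per_cohort_offsets,
      group_assignments = as.list(truth$group_assignments)
    ),
    paths[["truth"]],
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"))
  offsets <- do.call(rbind, purrr::map(truth_raw$per_cohort_offsets, unlist))
  list(
    table = read_feature_table(file.path(dir, "counts.tsv")),
    metadata = read_sample_metadata(file.path(dir, "metadata.tsv")),
    truth = list(
      planted_taxa = unlist(truth_raw$planted_taxa) %||% character(),
      per_cohort_offsets = offsets,
      group_assignments = unlist(truth_raw$group_assignments)
    )
  )
}
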