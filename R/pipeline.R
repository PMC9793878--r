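#' Pipeline run configuration
#'
#' A run is driven either by input files (`counts`/`metadata` TSV paths) or
#' by a synthetic spec. All analysis thresholds live here so a run can be
#' audited from one object; every value has the package default.
#'
#' @param input either `list(counts = path, metadata = path)` or
#'   `list(synthetic = synthetic_spec(...))`
#' @param out_dir output directory for artifacts and the manifest
#' @param sample_types which strata to analyze
#' @param comparisons named list of [comparison()] objects
#' @param confounders confounder names passed to [decompose_all()]
#' @param classifier a [classifier_config()]
#' @param diagonal_mode within-study diagonal estimator for the transfer
#'   matrix
#' @param pseudocount CLR pseudocount
#' @param alpha significance threshold used throughout
#' @param seed global seed fanned out to each stage
#' @return an object of class `run_config`
#' @export
run_config <- function(input, out_dir,
                       sample_types = c("tissue", "stool"),
                       comparisons = default_comparisons(),
                       confounders = c("study", "age", "bmi"),
                       classifier = classifier_config(),
                       diagonal_mode = "split_70_30",
                       pseudocount = 0.5,
                       alpha = 0.05,
                       seed = 1) {
  cfg <- structure(
    list(
      input = input, out_dir = out_dir, sample_types = sample_types,
      comparisons = comparisons, confounders = confounders,
      classifier = classifier, diagonal_mode = diagonal_mode,
      pseudocount = pseudocount, alpha = alpha, seed = as.integer(seed)
    ),
    class = "run_config"
  )
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg a candidate `run_config`
#' @export
validate_run_config <- function(cfg) {
  known_groups <- c("normal", "benign", "cancer", "cancer_adjacent")
  for (cmp in cfg$comparisons) {
    stopifnot(inherits(cmp, "comparison"))
    bad <- setdiff(c(cmp$group_a, cmp$group_b), known_groups)
    if (length(bad) > 0) {
      stop("comparison '", cmp$name, "' names unknown group(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  bad_cf <- setdiff(cfg$confounders, c("study", "age", "bmi", "sample_type"))
  if (length(bad_cf) > 0) {
    stop("unknown confounder(s): ", paste(bad_cf, collapse = ", "), call. = FALSE)
  }
  if (!(is.list(cfg$input) &&
    (all(c("counts", "metadata") %in% names(cfg$input)) ||
      "synthetic" %in% names(cfg$input)))) {
    stop("input must give counts+metadata paths or a synthetic spec", call. = FALSE)
  }
  cfg
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]'s arguments; `comparisons` entries are
#' mappings with `name`, `sample_type`, `group_a`, `group_b`, and a
#' `synthetic` input block passes its fields to [synthetic_spec()].
#'
#' @param path YAML file path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$input$synthetic)) {
    sp <- y$input$synthetic
    if (!is.null(sp$samples_per_cohort_per_group)) {
      sp$samples_per_cohort_per_group <- unlist(sp$samples_per_cohort_per_group)
    }
    list(synthetic = do.call(synthetic_spec, sp))
  } else {
    list(counts = y$input$counts, metadata = y$input$metadata)
  }
  cmps <- if (is.null(y$comparisons)) {
    default_comparisons()
  } else {
    cl <- purrr::map(y$comparisons, ~ comparison(
      .x$name, .x$sample_type,
      unlist(.x$group_a), unlist(.x$group_b)
    ))
    stats::setNames(cl, purrr::map_chr(cl, "name"))
  }
  cls <- if (is.null(y$classifier)) {
    classifier_config(seed = y$seed %||% 1)
  } else {
    do.call(classifier_config, y$classifier)
  }
  run_config(
    input = input,
    out_dir = y$out_dir %||% ".",
    sample_types = y$sample_types %||% c("tissue", "stool"),
    comparisons = cmps,
    confounders = y$confounders %||% c("study", "age", "bmi"),
    classifier = cls,
    diagonal_mode = y$diagonal_mode %||% "split_70_30",
    pseudocount = y$pseudocount %||% 0.5,
    alpha = y$alpha %||% 0.05,
    seed = y$seed %||% 1
  )
}

#' Run the full analysis pipeline
#'
#' Stages, in order: input (read or simulate), taxonomy filtering, removal of
#' unmapped samples, genus aggregation, CLR, confounder variance
#' decomposition, Bray-Curtis + PCoA, differential abundance over the
#' configured comparisons, Wilcoxon biomarkers with tissue/stool overlap,
#' top-k random-forest classification per sample type (plus the
#' cancer-adjacent reuse model when adjacent samples exist), and LOCO +
#' cohort-to-cohort transfer validation. Each artifact is written under
#' `out_dir` and listed in `manifest.json` with an MD5 hash; identical
#' config + seed reproduce identical hashes.
#'
#' @param cfg a [run_config()]
#' @return invisibly, the manifest as a tibble (`artifact`, `path`, `md5`)
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    artifacts[[name]] <<- path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- input ----------------------------------------------------------------
  dat <- stage("input", {
    if (!is.null(cfg$input$synthetic)) {
      generate_cohorts(cfg$input$synthetic)
    } else {
      list(
        table = read_feature_table(cfg$input$counts),
        metadata = read_sample_metadata(cfg$input$metadata),
        truth = NULL
      )
    }
  })

  # -- filters / aggregation / CLR ------------------------------------------
  genus <- stage("prep", {
    dat$table |>
      filter_taxa() |>
      drop_unmapped_samples() |>
      aggregate_to_genus()
  })
  meta <- dat$metadata[dat$metadata$sample_id %in% ft_sample_ids(genus), , drop = FALSE]
  clr <- stage("clr", clr_transform(genus, pseudocount = cfg$pseudocount))
  emit("genus_counts.tsv", \(p) write_feature_table(genus, p))
  emit("metadata.tsv", \(p) write_sample_metadata(meta, p))

  by_type <- function(type) {
    ids <- meta$sample_id[meta$sample_type == type]
    list(
      clr = clr[clr$sample_id %in% ids, , drop = FALSE],
      genus = genus[, c("taxon_id", "lineage", ids), drop = FALSE] |>
        drop_unmapped_samples(),
      meta = meta[meta$sample_id %in% ids, , drop = FALSE]
    )
  }
  types <- intersect(cfg$sample_types, unique(meta$sample_type))

  # -- confounders ----------------------------------------------------------
  stage("confounders", {
    vd <- purrr::map_dfr(types, function(ty) {
      st <- by_type(ty)
      purrr::map_dfr(
        cfg$confounders,
        ~ tryCatch(
          dplyr::mutate(decompose_all(st$clr, st$meta, .x, alpha = cfg$alpha),
            sample_type = ty
          ),
          warning = function(w) NULL
        )
      )
    })
    emit("variance_decomposition.tsv", \(p) readr::write_tsv(vd, p, progress = FALSE))
  })

  # -- community ------------------------------------------------------------
  stage("community", {
    for (ty in types) {
      st <- by_type(ty)
      d <- bray_curtis(st$genus)
      ord <- pcoa_ordination(d, n_axes = 2)
      emit(paste0("pcoa_", ty, ".tsv"), \(p) {
        readr::write_tsv(ord$coordinates, p, progress = FALSE)
      })
      cs <- composition_summary(st$genus, st$meta, rank = "phylum")
      emit(paste0("composition_phylum_", ty, ".tsv"), \(p) {
        readr::write_tsv(cs, p, progress = FALSE)
      })
    }
  })

  # -- differential + biomarkers --------------------------------------------
  biomarker_sets <- list()
  stage("differential", {
    da <- purrr::map_dfr(cfg$comparisons, function(cmp) {
      tryCatch(run_comparison(clr, meta, cmp, alpha = cfg$alpha),
        error = function(e) NULL
      )
    })
    emit("differential_abundance.tsv", \(p) readr::write_tsv(da, p, progress = FALSE))
    for (ty in types) {
      bm <- tryCatch(wilcoxon_biomarkers(clr, meta, ty, alpha = cfg$alpha),
        error = function(e) NULL
      )
      if (is.null(bm)) next
      emit(paste0("biomarkers_", ty, ".tsv"), \(p) readr::write_tsv(bm, p, progress = FALSE))
      biomarker_sets[[ty]] <- bm$genus[bm$biomarker]
    }
    if (length(biomarker_sets) >= 2) {
      ov <- overlap_sets(biomarker_sets)
      emit("biomarker_overlap.json", \(p) {
        jsonlite::write_json(
          list(
            sets = ov$sets, full_intersection = as.list(ov$full),
            union = as.list(ov$union)
          ),
          p,
          auto_unbox = TRUE, digits = NA
        )
      })
    }
  })

  # -- classification + crossval --------------------------------------------
  stage("classification", {
    for (ty in types) {
      st <- by_type(ty)
      labels <- tryCatch(label_binary(st$meta), error = function(e) NULL)
      if (is.null(labels)) next
      cls <- cfg$classifier
      cls$top_k <- min(cls$top_k, length(setdiff(names(st$clr), "sample_id")))
      model <- fit_topk_model(st$clr, labels, config = cls)
      emit(paste0("importance_", ty, ".tsv"), \(p) {
        readr::write_tsv(tidy(model), p, progress = FALSE)
      })
      emit(paste0("roc_", ty, ".tsv"), \(p) {
        readr::write_tsv(model$roc, p, progress = FALSE)
      })
      emit(paste0("model_", ty, ".json"), \(p) {
        jsonlite::write_json(
          list(
            auc = model$auc,
            selected_features = as.list(model$selected_features),
            per_fold_auc = model$per_fold_auc
          ),
          p,
          auto_unbox = TRUE, digits = NA
        )
      })
      if ("cancer_adjacent" %in% st$meta$group) {
        adj <- tryCatch(
          adjacent_reuse_model(st$clr, st$meta, model, config = cls),
          error = function(e) NULL
        )
        if (!is.null(adj)) {
          emit(paste0("model_adjacent_", ty, ".json"), \(p) {
            jsonlite::write_json(
              list(
                auc = adj$auc,
                selected_features = as.list(adj$selected_features)
              ),
              p,
              auto_unbox = TRUE, digits = NA
            )
          })
        }
      }
      if (length(unique(st$meta$study)) >= 2) {
        tm <- tryCatch(
          suppressWarnings(cohort_to_cohort(st$clr, st$meta, labels,
            config = cls, diagonal_mode = cfg$diagonal_mode
          )),
          error = function(e) NULL
        )
        if (!is.null(tm)) {
          emit(paste0("transfer_matrix_", ty, ".tsv"), \(p) write_transfer_matrix(tm, p))
        }
      }
    }
  })

  manifest <- tibble::tibble(
    artifact = names(artifacts),
    path = unname(artifacts),
    md5 = unname(tools::md5sum(unname(artifacts)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
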