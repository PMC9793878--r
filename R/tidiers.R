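#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a random-forest result
#'
#' One row per feature with its averaged permutation importance (mean
#' decrease in accuracy) and whether it was in the selected set.
#'
#' @param x an `rf_result`
#' @param ... unused
#' @return a tibble `feature`, `mean_decrease_accuracy`, `selected`
#' @method tidy rf_result
#' @export
tidy.rf_result <- function(x, ...) {
  x$importance |>
    dplyr::mutate(selected = .data$feature %in% x$selected_features)
}

#' @rdname tidy.rf_result
#' @return `glance()`: a one-row tibble `auc`, `n_samples`, `n_features`,
#'   `n_selected`, `n_folds`, `mean_fold_auc`
#' @method glance rf_result
#' @export
glance.rf_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    n_samples = x$n_samples,
    n_features = x$n_features,
    n_selected = length(x$selected_features),
    n_folds = x$config$n_folds,
    mean_fold_auc = mean(x$per_fold_auc, na.rm = TRUE)
  )
}

#' Tidy a transfer matrix
#'
#' Long form of the train-by-test AUC grid, with the LOCO row appended as
#' `train = "LOCO"` rows.
#'
#' @param x a `transfer_matrix`
#' @param ... unused
#' @return a tibble `train`, `test`, `auc`, `kind`
#'   (`transfer`/`within`/`loco`)
#' @method tidy transfer_matrix
#' @export
tidy.transfer_matrix <- function(x, ...) {
  grid <- tibble::as_tibble(x$auc, rownames = "train") |>
    tidyr::pivot_longer(-"train", names_to = "test", values_to = "auc") |>
    dplyr::mutate(kind = ifelse(.data$train == .data$test, "within", "transfer"))
  if (!is.null(x$loco_row)) {
    grid <- dplyr::bind_rows(
      grid,
      tibble::tibble(
        train = "LOCO", test = names(x$loco_row),
        auc = unname(x$loco_row), kind = "loco"
      )
    )
  }
  grid
}

#' @rdname tidy.transfer_matrix
#' @return `glance()`: one-row tibble `avg_transfer`, `avg_loco`,
#'   `avg_diagonal`, `n_cohorts`
#' @method glance transfer_matrix
#' @export
glance.transfer_matrix <- function(x, ...) {
  tibble::tibble(
    avg_transfer = x$avg_transfer,
    avg_loco = x$avg_loco,
    avg_diagonal = mean(diag(x$auc), na.rm = TRUE),
    n_cohorts = length(x$cohorts)
  )
}

#' Tidy an ordination
#'
#' @param x a `crossbiome_ordination`
#' @param ... unused
#' @return the coordinates tibble
#' @method tidy crossbiome_ordination
#' @export
tidy.crossbiome_ordination <- function(x, ...) x$coordinates

#' @rdname tidy.crossbiome_ordination
#' @method glance crossbiome_ordination
#' @export
glance.crossbiome_ordination <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_axes = ncol(x$coordinates) - 1,
    prop_axis1 = x$proportion_explained[1],
    prop_axis2 = if (length(x$proportion_explained) >= 2) {
      x$proportion_explained[2]
    } else {
      NA_real_
    }
  )
}
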