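#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maximum-entropy model
#'
#' @param x A [fit_maxent()] object.
#' @param ... Unused.
#' @return A tibble (`feature`, `predictor`, `weight`, `penalty`), active
#'   features first.
#' @export
tidy.maxent_fit <- function(x, ...) {
  tibble::tibble(feature = names(x$lambda),
                 predictor = feature_predictor(names(x$lambda)),
                 weight = unname(x$lambda),
                 penalty = unname(x$beta)) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' @rdname tidy.maxent_fit
#' @return `glance()` returns a one-row tibble of fit summaries.
#' @export
glance.maxent_fit <- function(x, ...) {
  tibble::tibble(n_presence = x$n_presence, n_background = x$n_background,
                 n_features = length(x$lambda),
                 n_active = sum(x$lambda != 0),
                 entropy = x$entropy,
                 objective = utils::tail(x$objective, 1),
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a replicate ensemble
#'
#' @param x A [fit_ensemble()] object.
#' @param ... Unused.
#' @return The per-replicate AUC tibble (`replicate`, `auc_train`,
#'   `auc_test`).
#' @export
tidy.sdm_ensemble <- function(x, ...) x$auc

#' @rdname tidy.sdm_ensemble
#' @return `glance()` returns a one-row tibble with replicate count and mean
#'   train/test AUC.
#' @export
glance.sdm_ensemble <- function(x, ...) {
  tibble::tibble(k = x$k, n_presence = nrow(x$pres_X),
                 n_background = nrow(x$bg_X),
                 mean_auc_train = mean(x$auc$auc_train),
                 mean_auc_test = mean(x$auc$auc_test))
}
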