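#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.dyn_network
#' @export
glance.dyn_network <- function(x, ...) {
  tibble::tibble(t = x$t, n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 n_red = sum(x$edges$sign == "red"),
                 n_green = sum(x$edges$sign == "green"), tau = x$tau)
}

#' Tidy dynamic networks and series
#'
#' `tidy()` returns the edge table (one row per edge, with `t`); `glance()`
#' returns one-row-per-network summaries.
#'
#' @param x A `dyn_network` or `dyn_network_series`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dyn_network <- function(x, ...) {
  e <- x$edges
  e$t <- x$t
  e[c("feature_i", "feature_j", "t", "sign", "nor")]
}

#' @rdname tidy.dyn_network
#' @export
tidy.dyn_network_series <- function(x, ...) {
  purrr::map_dfr(x, tidy)
}

#' @rdname tidy.dyn_network
#' @export
glance.dyn_network_series <- function(x, ...) {
  purrr::map_dfr(x, glance)
}

#' Tidy an RFE result
#'
#' `tidy()` returns the feature ranking (most important first, with
#' membership of the best subset); `glance()` the best subset size and its CV
#' accuracy.
#'
#' @param x An `rfe_result` from [svm_rfe_rank()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rfe_result <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$ranking), feature = x$ranking,
                 in_best_subset = x$ranking %in% x$best_subset)
}

#' @rdname tidy.rfe_result
#' @export
glance.rfe_result <- function(x, ...) {
  tibble::tibble(n_features = length(x$ranking),
                 best_size = length(x$best_subset),
                 best_cv_accuracy = max(x$trace$cv_accuracy))
}

#' Tidy a ROC result
#'
#' `tidy()` returns the ROC curve points; `glance()` the AUC, its standard
#' error and confidence interval, and the Youden-optimal operating point.
#'
#' @param x A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se, ci_lower = x$ci[1],
                 ci_upper = x$ci[2], cutoff = x$cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a PCA summary
#'
#' `tidy()` returns the per-sample scores; `glance()` the variance captured
#' by the first two components.
#'
#' @param x A `pca_summary` from [pca_summary()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pca_summary <- function(x, ...) x$scores

#' @rdname tidy.pca_summary
#' @export
glance.pca_summary <- function(x, ...) {
  tibble::tibble(pc1 = x$var_explained[1], pc2 = x$var_explained[2],
                 cum_pc12 = x$cum_pc12)
}

#' One-row summary of a pipeline run
#'
#' The headline counts of every stage: retained features, ratios, edges per
#' network, subset sizes and screened candidates.
#'
#' @param x A `pipeline_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.pipeline_run <- function(x, ...) {
  cts <- x$manifest$counts
  tibble::tibble(
    n_retained = cts$n_retained, n_ratios = cts$n_ratios,
    n_networks = cts$n_networks,
    max_edges = max(cts$edges_per_network),
    n_subset1 = cts$n_subset1, n_subset2 = cts$n_subset2,
    n_combined = cts$n_combined, n_screened = cts$n_screened
  )
}

#' @rdname glance.pipeline_run
#' @export
tidy.pipeline_run <- function(x, ...) {
  if (is.null(x$report)) {
    stop("this run has no candidate report to tidy", call. = FALSE)
  }
  tibble::as_tibble(x$report)
}
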