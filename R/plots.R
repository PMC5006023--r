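#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Edge counts along the network series
#'
#' Bar chart of edges per dynamic network, split by edge sign (red = ratio
#' up, green = ratio down) — the profile whose peak marks the key transition.
#'
#' @param object A `dyn_network_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dyn_network_series <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::count(.data$t, .data$sign)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$t), y = .data$n,
                                    fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(red = "#c0392b", green = "#27ae60"),
                               name = "edge sign") +
    ggplot2::labs(x = "network DN-t", y = "edges",
                  title = "Edges per dynamic network") +
    ggplot2::theme_minimal()
}

#' ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity, with the
#'   Youden-optimal operating point marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  crv <- dplyr::arrange(object$curve, .data$sensitivity)
  ggplot2::ggplot(crv, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "#c0392b", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object A `pca_summary` from [pca_summary()].
#' @param ... Unused.
#' @return A ggplot of the first two component scores, coloured by label when
#'   one was supplied.
#' @export
autoplot.pca_summary <- function(object, ...) {
  sc <- object$scores
  p <- if ("label" %in% names(sc)) {
    ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                     colour = .data$label))
  } else {
    ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      title = sprintf("PCA scores (PC1+PC2 = %.1f%%)", 100 * object$cum_pc12)
    ) +
    ggplot2::theme_minimal()
}

#' Metabolic trajectory of one candidate ratio
#'
#' Mean with standard-error ribbon per group along the time course.
#'
#' @param ds A [ts_dataset()].
#' @param ratio Length-2 vector: numerator, denominator feature.
#' @return A ggplot.
#' @export
plot_trajectory <- function(ds, ratio) {
  dat <- trajectory_summary(ds, ratio)
  lab <- {
    idx <- sort(resolve_features(ds, ratio))
    paste(ds$features[idx], collapse = " / ")
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$mean,
                                    colour = .data$group)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(dat$time)) +
    ggplot2::labs(x = "time point", y = lab,
                  title = paste("Trajectory (mean ± SE):", lab)) +
    ggplot2::theme_minimal()
}
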