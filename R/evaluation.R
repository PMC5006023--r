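#' Group-difference tests for one candidate ratio
#'
#' Two-sample t-test (Welch by default) of the ratio values, model vs control,
#' at each disease-stage time point.
#'
#' @param ds A [ts_dataset()].
#' @param ratio Length-2 vector of feature names (or indices): numerator,
#'   denominator; canonicalized to `i < j`.
#' @param stage_points Integer vector of time points to test (e.g. the
#'   disease-stage points).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble with columns `time`, `n_model`, `n_control`, `p_value`
#'   (`NA` with a warning where a group has < 2 samples).
#' @export
group_tests <- function(ds, ratio, stage_points, var_equal = FALSE) {
  rs <- ratio_series(ds, ratio[1], ratio[2])
  purrr::map_dfr(stage_points, function(tp) {
    m <- rs$value[rs$time == tp & rs$group == "model"]
    c_ <- rs$value[rs$time == tp & rs$group == "control"]
    p <- NA_real_
    if (length(m) >= 2 && length(c_) >= 2 &&
        (stats::sd(m) > 0 || stats::sd(c_) > 0)) {
      p <- stats::t.test(m, c_, var.equal = var_equal)$p.value
    } else {
      warning("group test at t=", tp, " skipped: insufficient samples or ",
              "zero variance in both groups", call. = FALSE)
    }
    tibble::tibble(time = tp, n_model = length(m), n_control = length(c_),
                   p_value = p)
  })
}

#' Paired within-subject tests for one candidate ratio
#'
#' Paired t-test of the ratio values between a pre-onset reference point and
#' each disease-stage point, model group only. Subjects missing at either
#' point of a comparison are excluded from that pairing.
#'
#' @inheritParams group_tests
#' @param reference_point Time index of the reference (typical pre-onset)
#'   point.
#' @return Tibble with columns `reference`, `time`, `n_pairs`, `p_value`
#'   (`NA` with a flag column `degenerate` when the paired differences have
#'   zero variance or < 2 complete pairs exist).
#' @export
paired_tests <- function(ds, ratio, reference_point, stage_points) {
  rs <- ratio_series(ds, ratio[1], ratio[2], group = "model")
  ref <- rs[rs$time == reference_point, c("subject", "value")]
  purrr::map_dfr(stage_points, function(tp) {
    cur <- rs[rs$time == tp, c("subject", "value")]
    pairs <- dplyr::inner_join(ref, cur, by = "subject",
                               suffix = c("_ref", "_t"))
    diffs <- pairs$value_t - pairs$value_ref
    degenerate <- FALSE
    p <- NA_real_
    if (length(diffs) < 2) {
      warning("paired test T", reference_point, " vs T", tp,
              ": < 2 complete pairs", call. = FALSE)
    } else if (stats::sd(diffs) == 0) {
      degenerate <- TRUE
    } else {
      p <- stats::t.test(pairs$value_t, pairs$value_ref, paired = TRUE)$p.value
    }
    tibble::tibble(reference = reference_point, time = tp,
                   n_pairs = length(diffs), p_value = p,
                   degenerate = degenerate)
  })
}

#' Screen candidate ratios on their univariate evidence
#'
#' A candidate passes when every group-test p-value at the disease-stage
#' points AND every paired-test p-value is below `alpha` simultaneously. Any
#' `NA` p-value fails the candidate (conservative).
#'
#' @param report A candidate report from [evaluate_candidates()], or any
#'   tibble with columns `feature_i`, `feature_j`, `test`
#'   (`"group"`/`"paired"`), `p_value`.
#' @param alpha Significance threshold; default 0.05.
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, matching a plain
#'   per-test screen.
#' @return Tibble with one row per ratio: `feature_i`, `feature_j`, `n_tests`,
#'   `max_p`, `pass`, `reason`.
#' @export
screen_candidates <- function(report, alpha = 0.05, adjust = "none") {
  stopifnot(all(c("feature_i", "feature_j", "p_value") %in% names(report)))
  report |>
    dplyr::group_by(.data$feature_i, .data$feature_j) |>
    dplyr::summarise(
      n_tests = dplyr::n(),
      max_p = suppressWarnings(max(stats::p.adjust(.data$p_value,
                                                   method = adjust))),
      pass = !anyNA(.data$p_value) &&
        all(stats::p.adjust(.data$p_value, method = adjust) < alpha),
      reason = if (anyNA(.data$p_value)) "missing p-value" else
        if (all(stats::p.adjust(.data$p_value, method = adjust) < alpha))
          "all tests significant" else "non-significant test",
      .groups = "drop"
    )
}

#' ROC analysis with the Mann-Whitney AUC and a Youden-index cut-off
#'
#' The AUC is the pair-counting (Mann-Whitney) estimator: the fraction of
#' (positive, negative) pairs where the positive scores higher, ties counting
#' one half. Its standard error follows Hanley & McNeil, with a 95% normal
#' confidence interval truncated to `[0, 1]`. The best cut-off maximizes the
#' Youden index `sensitivity + specificity - 1`; ties are broken toward
#' higher specificity. Scores at or above the cut-off are called positive.
#'
#' @param scores Numeric vector (e.g. per-sample ratio values).
#' @param labels Logical or two-level vector; `TRUE` / second level = positive
#'   (disease-stage) class.
#' @param positive Which label value marks the positive class (default: `TRUE`
#'   for logicals, the last level otherwise).
#' @return A `roc_result`: list with `auc`, `se`, `ci` (length 2), `cutoff`,
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`, and `curve` (tibble
#'   `cutoff`, `sensitivity`, `specificity`).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  scores <- as.numeric(scores)
  if (is.null(positive)) {
    positive <- if (is.logical(labels)) TRUE else {
      lv <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
      lv[length(lv)]
    }
  }
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be non-empty for ROC analysis", call. = FALSE)
  }

  # Mann-Whitney pair counting via midranks
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # Hanley-McNeil standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))

  # candidate cut-offs: every observed score (calls score >= cutoff
  # positive), plus +Inf for the all-negative end of the curve
  cuts <- c(sort(unique(scores)), Inf)
  sens <- vapply(cuts, function(ct) mean(pos >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(neg < ct), numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[which.max(spec[best])]

  structure(
    list(auc = auc, se = se, ci = ci, cutoff = cuts[best],
         sensitivity = sens[best], specificity = spec[best],
         n_pos = n1, n_neg = n0,
         curve = tibble::tibble(cutoff = cuts, sensitivity = sens,
                                specificity = spec)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$auc, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("  best cut-off %.4g: sensitivity %.3f, specificity %.3f (n+ %d, n- %d)\n",
              x$cutoff, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' PCA summary of a sample-by-ratio matrix
#'
#' Autoscaled principal component analysis; reports the variance captured by
#' the first two components (the quantity used to compare candidate subsets)
#' and the per-sample scores for plotting. Constant columns are dropped with
#' a warning.
#'
#' @param x Numeric sample-by-variable matrix or data frame (>= 3 rows, >= 2
#'   usable columns).
#' @param labels Optional per-sample labels carried into the score table.
#' @return A `pca_summary`: list with `var_explained` (per-PC fraction),
#'   `cum_pc12` (PC1 + PC2 fraction), `scores` (tibble `PC1`, `PC2`, `label`).
#' @export
pca_summary <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs >= 3 samples", call. = FALSE)
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant column(s) before PCA",
            call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stop("PCA needs >= 2 non-constant columns", call. = FALSE)
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::tibble(PC1 = fit$x[, 1], PC2 = fit$x[, 2])
  if (!is.null(labels)) scores$label <- labels
  structure(
    list(var_explained = ve, cum_pc12 = sum(ve[1:2]), scores = scores),
    class = "pca_summary"
  )
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("<pca_summary> PC1 %.1f%% + PC2 %.1f%% = %.1f%% of total variation\n",
              100 * x$var_explained[1], 100 * x$var_explained[2],
              100 * x$cum_pc12))
  invisible(x)
}

#' Mean and standard error of a ratio per group and time point
#'
#' The metabolic trajectory of one candidate ratio.
#'
#' @inheritParams group_tests
#' @return Tibble with columns `group`, `time`, `n`, `mean`, `se` (`NA` for a
#'   single sample).
#' @export
trajectory_summary <- function(ds, ratio) {
  ratio_series(ds, ratio[1], ratio[2]) |>
    dplyr::group_by(.data$group, .data$time) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = ifelse(dplyr::n() > 1,
                  stats::sd(.data$value) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    )
}

#' Full univariate and ROC evaluation of a candidate subset
#'
#' For every ratio of a subset: group t-tests at the disease-stage points,
#' paired t-tests against the reference point, the simultaneous screen, and
#' ROC analysis of disease-stage vs pre-stage samples (model-group samples at
#' the disease-stage points are positives; all earlier model-group samples
#' are negatives).
#'
#' @param ds A [ts_dataset()].
#' @param subset A `ratio_subset` (or tibble with `feature_i`, `feature_j`).
#' @param stage_points Disease-stage time points (positives).
#' @param reference_point Reference point for the paired tests; defaults to
#'   the last pre-stage point.
#' @param alpha Screening threshold; default 0.05.
#' @param var_equal,adjust Passed to [group_tests()] / [screen_candidates()].
#' @return A `candidate_report`: tibble with one row per ratio — screening
#'   columns (`pass`, `max_p`, `reason`), `auc`, `auc_se`, `ci_lower`,
#'   `ci_upper`, `cutoff`, `sensitivity`, `specificity` — plus attributes
#'   `tests` (the long p-value table) and `roc` (named list of `roc_result`s).
#' @export
evaluate_candidates <- function(ds, subset, stage_points,
                                reference_point = min(stage_points) - 1,
                                alpha = 0.05, var_equal = FALSE,
                                adjust = "none") {
  stopifnot(inherits(ds, "ts_dataset"))
  pairs <- subset_pairs(subset)
  if (nrow(pairs) == 0) {
    stop("empty candidate subset: nothing to evaluate", call. = FALSE)
  }
  pre_points <- setdiff(seq_len(ds$n_time), stage_points)
  pre_points <- pre_points[pre_points < min(stage_points)]

  tests <- purrr::pmap_dfr(pairs, function(feature_i, feature_j) {
    g <- group_tests(ds, c(feature_i, feature_j), stage_points,
                     var_equal = var_equal)
    p <- paired_tests(ds, c(feature_i, feature_j), reference_point,
                      stage_points)
    dplyr::bind_rows(
      tibble::tibble(feature_i, feature_j, test = "group", time = g$time,
                     p_value = g$p_value),
      tibble::tibble(feature_i, feature_j, test = "paired", time = p$time,
                     p_value = p$p_value)
    )
  })
  screen <- screen_candidates(tests, alpha = alpha, adjust = adjust)

  rocs <- purrr::pmap(pairs, function(feature_i, feature_j) {
    rs <- ratio_series(ds, feature_i, feature_j, group = "model")
    keep <- rs$time %in% c(pre_points, stage_points)
    roc_auc(rs$value[keep], rs$time[keep] %in% stage_points)
  })
  names(rocs) <- paste(pairs$feature_i, pairs$feature_j, sep = "/")

  roc_tab <- purrr::map_dfr(rocs, function(r) {
    tibble::tibble(auc = r$auc, auc_se = r$se, ci_lower = r$ci[1],
                   ci_upper = r$ci[2], cutoff = r$cutoff,
                   sensitivity = r$sensitivity, specificity = r$specificity)
  })

  out <- dplyr::bind_cols(
    dplyr::left_join(pairs, screen, by = c("feature_i", "feature_j")),
    roc_tab
  )
  attr(out, "tests") <- tests
  attr(out, "roc") <- rocs
  class(out) <- c("candidate_report", class(out))
  out
}
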