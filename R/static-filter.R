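#' Enumerate binary stage-pair sub-problems
#'
#' With `N_s` disease stages, static filtering decomposes the discrimination
#' problem into `N_s * (N_s - 1) / 2` binary sub-problems, one per stage pair,
#' each using the model-group samples at the two stages' typical time points.
#'
#' @param ds A [ts_dataset()].
#' @param design A [stage_design()] declaring a typical point per stage.
#' @return A tibble with one row per sub-problem: columns `stage_a`,
#'   `stage_b`, `time_a`, `time_b`.
#' @export
enumerate_subproblems <- function(ds, design) {
  stopifnot(inherits(ds, "ts_dataset"), inherits(design, "stage_design"))
  stages <- unique(unname(ds$stage_map))
  missing <- setdiff(stages, names(design$typical_points))
  if (length(missing) > 0) {
    stop("design error: no typical point declared for stage(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(stages) < 2) {
    stop("design error: need >= 2 stages for static filtering", call. = FALSE)
  }
  idx <- utils::combn(length(stages), 2)
  tibble::tibble(
    stage_a = stages[idx[1, ]],
    stage_b = stages[idx[2, ]],
    time_a = unname(design$typical_points[stages[idx[1, ]]]),
    time_b = unname(design$typical_points[stages[idx[2, ]]])
  )
}

#' Recursive feature elimination with a linear SVM
#'
#' Iteratively fits a linear max-margin classifier (cost 1), scores each
#' surviving feature by its squared weight in the separating hyperplane,
#' removes the `ceiling(elim_fraction * current)` lowest-scoring features (at
#' least 1), and repeats until no features remain. The ranking is the reverse
#' elimination order (last removed = most important). At every iteration the
#' stratified k-fold cross-validated accuracy of the current subset is
#' recorded; the best subset is the one with maximal CV accuracy, ties going
#' to the smaller subset.
#'
#' Features are standardized to zero mean and unit variance before fitting
#' (per training fold inside CV), so weight magnitudes are comparable. Weight
#' ties are broken by removing the feature with the larger canonical (column)
#' index first.
#'
#' @param x Numeric sample-by-feature matrix with column names.
#' @param y Binary labels (factor or coercible), >= 2 samples per class.
#' @param elim_fraction Fraction of surviving features removed per iteration,
#'   in (0, 1); default 0.10.
#' @param n_folds Folds for the CV accuracy trace; default 5.
#' @param seed Integer seed for the fold assignment.
#' @param cost SVM penalty parameter; default 1.
#' @return An `rfe_result`: list with `ranking` (feature names, most important
#'   first), `best_subset`, `trace` (tibble `n_features`, `cv_accuracy`,
#'   `features` list-column).
#' @export
svm_rfe_rank <- function(x, y, elim_fraction = 0.1, n_folds = 5, seed = 1,
                         cost = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) != 2) stop("argument error: y must be binary", call. = FALSE)
  if (min(table(y)) < 2) {
    stop("insufficient-data error: each class needs >= 2 samples",
         call. = FALSE)
  }
  if (elim_fraction <= 0 || elim_fraction >= 1) {
    stop("argument error: elim_fraction must lie in (0, 1)", call. = FALSE)
  }

  folds <- withr::with_seed(seed, stratified_folds(y, n_folds))
  canon <- colnames(x)
  surviving <- canon
  eliminated <- character(0)
  trace <- list()

  while (length(surviving) > 0) {
    xs <- x[, surviving, drop = FALSE]
    acc <- cv_accuracy(xs, y, folds, cost)
    trace[[length(trace) + 1]] <- tibble::tibble(
      n_features = length(surviving), cv_accuracy = acc,
      features = list(surviving)
    )
    w2 <- svm_weights2(xs, y, cost)
    n_drop <- max(1L, ceiling(elim_fraction * length(surviving)))
    # ties: larger canonical index goes first
    ord <- order(w2, -match(surviving, canon))
    drop <- surviving[ord[seq_len(n_drop)]]
    # within a dropped batch, record least important first
    eliminated <- c(eliminated, drop)
    surviving <- setdiff(surviving, drop)
  }

  trace <- dplyr::bind_rows(trace)
  best_i <- which(trace$cv_accuracy == max(trace$cv_accuracy))
  best_i <- best_i[which.min(trace$n_features[best_i])]
  structure(
    list(ranking = rev(eliminated), best_subset = trace$features[[best_i]],
         trace = trace),
    class = "rfe_result"
  )
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("<rfe_result> ", length(x$ranking), " features ranked; best subset: ",
      length(x$best_subset), " features (CV accuracy ",
      sprintf("%.3f", max(x$trace$cv_accuracy)), ")\n", sep = "")
  invisible(x)
}

# squared hyperplane weights of a linear SVM on standardized data
svm_weights2 <- function(x, y, cost) {
  xs <- standardize(x)
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  stats::setNames(w^2, colnames(x))
}

standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  sweep(sweep(x, 2, center), 2, scale, "/")
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

cv_accuracy <- function(x, y, folds, cost) {
  hits <- 0L
  for (k in sort(unique(folds))) {
    test <- folds == k
    if (all(test) || !all(levels(y) %in% y[!test])) next
    ctr <- colMeans(x[!test, , drop = FALSE])
    scl <- apply(x[!test, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    xtr <- standardize(x[!test, , drop = FALSE], ctr, scl)
    xte <- standardize(x[test, , drop = FALSE], ctr, scl)
    fit <- e1071::svm(xtr, y[!test], kernel = "linear", cost = cost,
                      scale = FALSE)
    hits <- hits + sum(stats::predict(fit, xte) == y[test])
  }
  hits / length(y)
}

#' Features retained by the static filter
#'
#' Runs repeated SVM-RFE on every stage-pair sub-problem and unites the
#' results. For each sub-problem, `n_repeats` independent RFE runs (each with
#' its own fold split) produce `n_repeats` best subsets; features appearing in
#' at least `selection_threshold` of them are selected for that sub-problem.
#' The union over sub-problems, in canonical order, feeds network
#' construction.
#'
#' @param ds A [ts_dataset()].
#' @param design A [stage_design()].
#' @param elim_fraction,n_folds,cost Passed to [svm_rfe_rank()].
#' @param n_repeats Repeated CV runs per sub-problem; default 50.
#' @param selection_threshold Minimum selection frequency; default 0.5.
#' @param seed Integer seed; run `r` of a sub-problem uses `seed + r`.
#' @return Character vector of retained features, canonical order, with a
#'   `selection` attribute: tibble (`stage_a`, `stage_b`, `feature`,
#'   `frequency`) of per-sub-problem selection frequencies.
#' @export
retained_features <- function(ds, design, elim_fraction = 0.1, n_folds = 5,
                              n_repeats = 50, selection_threshold = 0.5,
                              seed = 1, cost = 1) {
  subs <- enumerate_subproblems(ds, design)
  sel <- purrr::pmap_dfr(subs, function(stage_a, stage_b, time_a, time_b) {
    d <- ds$data[ds$data$group == "model" & ds$data$time %in% c(time_a, time_b), ]
    x <- as.matrix(d[ds$features])
    y <- factor(ifelse(d$time == time_a, stage_a, stage_b))
    freq <- stats::setNames(numeric(length(ds$features)), ds$features)
    for (r in seq_len(n_repeats)) {
      res <- svm_rfe_rank(x, y, elim_fraction = elim_fraction,
                          n_folds = n_folds, seed = seed + r, cost = cost)
      freq[res$best_subset] <- freq[res$best_subset] + 1
    }
    tibble::tibble(stage_a = stage_a, stage_b = stage_b,
                   feature = names(freq), frequency = unname(freq) / n_repeats)
  })
  kept <- sel$feature[sel$frequency >= selection_threshold]
  kept <- ds$features[ds$features %in% kept]
  if (length(kept) == 0) {
    stop("static filter retained no feature; relax selection_threshold ",
         "or elim_fraction", call. = FALSE)
  }
  attr(kept, "selection") <- sel
  kept
}
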