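#' Run the full dynamic-ratio-network pipeline
#'
#' Orchestrates the four stages end to end: (1) static filtering of
#' non-informative features by repeated linear SVM-RFE on every stage-pair
#' sub-problem; (2) construction of the `N - 1` signed dynamic networks over
#' the retained features; (3) extraction of candidate ratios by
#' dynamic-concentration and/or topological-structure analysis and their
#' combination; (4) univariate (group + paired t-test) screening and ROC
#' evaluation of the combined subset. Every stage's headline counts are
#' collected into a manifest, and the run is fully reproducible from
#' `(ds, design, parameters, seed)`.
#'
#' @param ds A [ts_dataset()].
#' @param design A [stage_design()].
#' @param tau Edge threshold on `|NOR|`; default [DEFAULT_TAU].
#' @param gamma Chebyshev coefficient; default [CHEBYSHEV_GAMMA].
#' @param mode Which network analyses to run: `"both"` (default),
#'   `"concentration"` or `"topology"`.
#' @param combine `"intersection"` (default) or `"union"` of the two subsets
#'   (ignored unless `mode = "both"`).
#' @param k Top-node count for the topological analysis; default 1.
#' @param skip_filter Use all features instead of the static filter.
#' @param elim_fraction,n_folds,n_repeats,selection_threshold,cost Static
#'   filter parameters (see [retained_features()]).
#' @param stage_points Disease-stage time points for the evaluation;
#'   default: every time point of the stage containing the onset point.
#' @param reference_point Reference point for the paired tests; default: the
#'   time point just before the disease stage.
#' @param alpha Screening threshold; default 0.05.
#' @param seed Integer seed driving the RFE fold splits.
#' @param out_dir Optional directory: when given, writes the dataset-level
#'   artifacts (edge lists, GraphML, subset and candidate TSVs, JSON
#'   manifest).
#' @param verbose Print stage-by-stage headline counts; default `TRUE`.
#' @return A `pipeline_run`: list with `retained`, `networks`, `subset1`,
#'   `subset2`, `combined`, `report`, `manifest`.
#' @export
run_pipeline <- function(ds, design, tau = DEFAULT_TAU,
                         gamma = CHEBYSHEV_GAMMA,
                         mode = c("both", "concentration", "topology"),
                         combine = c("intersection", "union"), k = 1,
                         skip_filter = FALSE, elim_fraction = 0.1,
                         n_folds = 5, n_repeats = 50,
                         selection_threshold = 0.5, cost = 1,
                         stage_points = NULL, reference_point = NULL,
                         alpha = 0.05, seed = 1, out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(ds, "ts_dataset"), inherits(design, "stage_design"))
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  say <- function(...) if (verbose) message(...)
  stage <- function(lab, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", lab, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  validate_design(ds, design)

  retained <- stage("static_filter", {
    if (skip_filter) ds$features else {
      retained_features(ds, design, elim_fraction = elim_fraction,
                        n_folds = n_folds, n_repeats = n_repeats,
                        selection_threshold = selection_threshold,
                        seed = seed, cost = cost)
    }
  })
  say("static filter: ", length(retained), " of ", length(ds$features),
      " features retained -> ", choose(length(retained), 2),
      " feature ratios")

  networks <- stage("dynamic_network", {
    network_series(ds, features = retained, tau = tau, gamma = gamma)
  })
  say("networks: ", paste(sprintf("DN-%d: %d", edge_counts(networks)$t,
                                  edge_counts(networks)$n_edges),
                          collapse = ", "), " edges (tau = ", tau, ")")

  subset1 <- subset2 <- combined <- NULL
  if (mode %in% c("both", "concentration")) {
    subset1 <- stage("dynamic_concentration",
                     dynamic_concentration(networks, design))
    say("concentration subset: ", nrow(subset1), " ratios persistent over DN-{",
        paste(concentration_window(design), collapse = ","), "}")
  }
  if (mode %in% c("both", "topology")) {
    subset2 <- stage("topological_structure",
                     topological_structure(networks, k = k))
    say("topology subset: ", nrow(subset2), " ratios incident to top-", k,
        " node(s) {", paste(attr(subset2, "top_nodes"), collapse = ", "),
        "} of DN-", attr(subset2, "key_network"))
  }
  combined <- if (mode == "both") {
    stage("combine", combine_subsets(subset1, subset2, mode = combine))
  } else if (mode == "concentration") subset1 else subset2
  say("combined (", if (mode == "both") combine else mode, "): ",
      nrow(combined), " candidate ratios")

  if (is.null(stage_points)) {
    onset_stage <- ds$stage_map[[as.character(design$onset_point)]]
    stage_points <- as.integer(names(ds$stage_map)[ds$stage_map == onset_stage])
  }
  if (is.null(reference_point)) reference_point <- min(stage_points) - 1

  report <- NULL
  if (nrow(combined) > 0) {
    report <- stage("evaluation", {
      evaluate_candidates(ds, combined, stage_points = stage_points,
                          reference_point = reference_point, alpha = alpha)
    })
    say("evaluation: ", sum(report$pass), " of ", nrow(report),
        " candidates pass the simultaneous screen (alpha = ", alpha, ")")
  } else {
    say("evaluation skipped: empty candidate subset")
  }

  manifest <- list(
    parameters = list(
      tau = tau, gamma = gamma, mode = mode, combine = combine, k = k,
      skip_filter = skip_filter, elim_fraction = elim_fraction,
      n_folds = n_folds, n_repeats = n_repeats,
      selection_threshold = selection_threshold, cost = cost,
      stage_points = stage_points, reference_point = reference_point,
      alpha = alpha, seed = seed
    ),
    design = list(typical_points = as.list(design$typical_points),
                  onset_point = design$onset_point,
                  lookback = design$lookback),
    counts = list(
      n_samples = nrow(ds$data), n_features = length(ds$features),
      n_time = ds$n_time, n_retained = length(retained),
      n_ratios = choose(length(retained), 2),
      n_networks = length(networks),
      edges_per_network = edge_counts(networks)$n_edges,
      n_subset1 = if (is.null(subset1)) NA_integer_ else nrow(subset1),
      n_subset2 = if (is.null(subset2)) NA_integer_ else nrow(subset2),
      n_combined = nrow(combined),
      n_screened = if (is.null(report)) 0L else sum(report$pass)
    ),
    package_version = as.character(utils::packageVersion("dynratio"))
  )

  run <- structure(
    list(retained = retained, networks = networks, subset1 = subset1,
         subset2 = subset2, combined = combined, report = report,
         manifest = manifest),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("<pipeline_run>\n")
  cat("  retained features: ", cts$n_retained, " (", cts$n_ratios,
      " ratios)\n", sep = "")
  cat("  networks: ", paste(cts$edges_per_network, collapse = "/"),
      " edges\n", sep = "")
  cat("  subsets: concentration ", cts$n_subset1, ", topology ",
      cts$n_subset2, ", combined ", cts$n_combined, "\n", sep = "")
  cat("  screened candidates: ", cts$n_screened, "\n", sep = "")
  invisible(x)
}

#' Write the artifacts of a pipeline run to a directory
#'
#' Edge lists and GraphML per network, subset TSVs with provenance, the
#' candidate report TSV, and a JSON run manifest.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "pipeline_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_networks(run$networks, file.path(dir, "networks"))
  dump_subset <- function(s, name) {
    if (is.null(s)) return()
    out <- subset_pairs(s)
    out$provenance <- if ("provenance" %in% names(s)) s$provenance else
      attr(s, "provenance")
    readr::write_tsv(out, file.path(dir, paste0(name, ".tsv")),
                     progress = FALSE)
  }
  dump_subset(run$subset1, "subset_concentration")
  dump_subset(run$subset2, "subset_topology")
  dump_subset(run$combined, "subset_combined")
  if (!is.null(run$report)) {
    readr::write_tsv(tibble::as_tibble(run$report),
                     file.path(dir, "candidates.tsv"), progress = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
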