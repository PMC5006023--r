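#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the discovery design of a stepwise hepatocarcinogenesis
#' rat study: 10 control + 7 model subjects sampled at 7 time points spanning
#' three stages (hepatitis T1, cirrhosis T2-T4, carcinoma T5-T7), with
#' planted ratio-shift biomarkers switching on at the carcinoma onset (T5).
#'
#' Abundances are log-normal: `log f = baseline_i + subject effect + planted
#' group-by-time effect + noise`. The subject effect is shared across all
#' features of a subject (a loading/dilution effect), so it cancels in every
#' ratio. For each planted pair the numerator gains `log_fold_shift` per time
#' point from `shift_onset` onward (a cumulative ramp, model subjects only),
#' and the denominator loses `denominator_shift` per time point, so the
#' planted ratio's effective range upshifts persistently across every
#' post-onset transition. The default effect size is set by the geometry of
#' the NOR: adjacent effective ranges at `p = 0.5` are `u -/+ 1.732 * sd`,
#' and the log ratio's scale is `sqrt(2) * noise_sd`, so a per-step log shift
#' of about `4.5 * noise_sd` is needed before `|NOR|` can reach 0.85; the
#' default `0.6 = 6 * noise_sd` clears that with margin.
#'
#' @param n_control,n_model Subject counts; defaults 10 and 7.
#' @param n_time Number of time points `N`; default 7.
#' @param stage_map Stage label per time point; default
#'   `H, CIR, CIR, CIR, HCC, HCC, HCC`.
#' @param m Feature count; default 40.
#' @param n_planted_pairs Number of planted biomarker pairs (mutually
#'   disjoint); default 1. With several pairs, any up-shifted numerator
#'   paired with any down-shifted denominator forms an equally valid shifted
#'   ratio, so planted pairs are only uniquely identifiable with one pair.
#' @param shift_onset Time index where planted ratios start shifting;
#'   default 5.
#' @param log_fold_shift Per-step log increase of each planted numerator in
#'   model subjects; default 0.6.
#' @param denominator_shift Per-step log decrease of each planted denominator;
#'   default `log_fold_shift` (one lipid up, its partner down, both
#'   carrying discriminative information).
#' @param subject_sd SD of the per-subject log offset (shared across
#'   features); default 1.2. This emulates the large inter-individual
#'   variation of serum lipid levels; because it is shared across features it
#'   cancels exactly in every ratio, which is the core argument for ratio
#'   markers: single abundances classify poorly while numerator/denominator
#'   contrasts classify cleanly.
#' @param noise_sd Residual log-scale SD per cell; default 0.1.
#' @param baseline_log_mean Range the per-feature log baselines are drawn
#'   from; default `c(1, 3)`.
#' @param seed Integer seed; the dataset is a pure function of the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_control = 10, n_model = 7, n_time = 7,
                             stage_map = c("H", "CIR", "CIR", "CIR",
                                           "HCC", "HCC", "HCC"),
                             m = 40, n_planted_pairs = 1, shift_onset = 5,
                             log_fold_shift = 0.6,
                             denominator_shift = log_fold_shift,
                             subject_sd = 1.2, noise_sd = 0.1,
                             baseline_log_mean = c(1, 3), seed = 1) {
  if (length(stage_map) != n_time) {
    stop("config error: stage_map must have one label per time point",
         call. = FALSE)
  }
  if (shift_onset < 2 || shift_onset > n_time) {
    stop("config error: shift_onset must lie in 2..N", call. = FALSE)
  }
  if (subject_sd < 0 || noise_sd < 0) {
    stop("config error: sds must be >= 0", call. = FALSE)
  }
  if (2 * n_planted_pairs > m) {
    stop("config error: ", n_planted_pairs, " disjoint planted pairs need ",
         2 * n_planted_pairs, " features, only ", m, " available",
         call. = FALSE)
  }
  structure(
    list(n_control = n_control, n_model = n_model, n_time = n_time,
         stage_map = stage_map, m = m, n_planted_pairs = n_planted_pairs,
         shift_onset = shift_onset, log_fold_shift = log_fold_shift,
         denominator_shift = denominator_shift, subject_sd = subject_sd,
         noise_sd = noise_sd, baseline_log_mean = baseline_log_mean,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic time-series cohort with planted ratio biomarkers
#'
#' @param config A [generator_config()].
#' @return A list: `dataset` (a [ts_dataset()]) and `truth`, a manifest list
#'   with `planted_pairs` (tibble `feature_i`, `feature_j`, oriented so the
#'   up-shifted numerator has the smaller canonical index) and the full
#'   `config`.
#' @examples
#' sim <- generate_cohort(generator_config(seed = 7))
#' nrow(sim$dataset$data) # 119 samples: (10 + 7) subjects x 7 time points
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    feats <- sprintf("f%02d", seq_len(cf$m))
    baseline <- stats::runif(cf$m, cf$baseline_log_mean[1],
                             cf$baseline_log_mean[2])

    # planted pairs: disjoint features; numerator first (smaller index)
    planted_idx <- seq_len(2 * cf$n_planted_pairs)
    num_idx <- planted_idx[seq_len(cf$n_planted_pairs) * 2 - 1]
    den_idx <- planted_idx[seq_len(cf$n_planted_pairs) * 2]

    subjects <- c(sprintf("c%02d", seq_len(cf$n_control)),
                  sprintf("m%02d", seq_len(cf$n_model)))
    groups <- rep(c("control", "model"), c(cf$n_control, cf$n_model))
    subj_eff <- stats::rnorm(length(subjects), 0, cf$subject_sd)

    # cumulative post-onset ramp: 0 before onset, then 1, 2, ... steps
    ramp <- pmax(0, seq_len(cf$n_time) - cf$shift_onset + 1)

    rows <- list()
    k <- 0
    for (s in seq_along(subjects)) {
      for (t in seq_len(cf$n_time)) {
        lg <- baseline + subj_eff[s] +
          stats::rnorm(cf$m, 0, cf$noise_sd)
        if (groups[s] == "model" && ramp[t] > 0) {
          lg[num_idx] <- lg[num_idx] + cf$log_fold_shift * ramp[t]
          lg[den_idx] <- lg[den_idx] - cf$denominator_shift * ramp[t]
        }
        k <- k + 1
        rows[[k]] <- dplyr::bind_cols(
          tibble::tibble(subject = subjects[s], group = groups[s], time = t),
          tibble::as_tibble(as.list(stats::setNames(exp(lg), feats)))
        )
      }
    }
    tab <- dplyr::bind_rows(rows)

    ds <- ts_dataset(tab, stage_map = cf$stage_map)
    truth <- list(
      planted_pairs = tibble::tibble(feature_i = feats[num_idx],
                                     feature_j = feats[den_idx]),
      config = cf
    )
    list(dataset = ds, truth = truth)
  })
}

#' Planted-biomarker recovery experiment
#'
#' Generates a cohort, runs the full pipeline (static filter, networks,
#' concentration + topology subsets, combination, univariate/ROC screen) and
#' reports where each planted pair surfaced; repeats over seeds and
#' aggregates.
#'
#' @param config A [generator_config()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param seeds Integer vector of generator seeds; default `1:10`.
#' @param pipeline_params Named list of overrides passed to [run_pipeline()]
#'   (e.g. `list(n_repeats = 15)` to lighten the RFE stage).
#' @return A `recovery_report`: tibble with one row per (seed, planted pair)
#'   and logical columns `in_subset1`, `in_subset2`, `in_combined`,
#'   `screened` (passed the univariate screen), plus attribute `rates` (the
#'   per-column recovery fractions).
#' @export
recovery_experiment <- function(config, seeds = 1:10,
                                pipeline_params = list()) {
  stopifnot(inherits(config, "generator_config"))
  rows <- purrr::map_dfr(seeds, function(sd) {
    cf <- config
    cf$seed <- as.integer(sd)
    sim <- generate_cohort(cf)
    run <- tryCatch(
      do.call(run_pipeline,
              c(list(ds = sim$dataset, design = default_design(cf),
                     seed = sd), pipeline_params)),
      error = function(e) NULL
    )
    planted <- sim$truth$planted_pairs
    in_set <- function(subset) {
      if (is.null(run) || is.null(subset) || nrow(subset) == 0) {
        return(rep(FALSE, nrow(planted)))
      }
      key <- paste(subset$feature_i, subset$feature_j)
      paste(planted$feature_i, planted$feature_j) %in% key
    }
    screened_pairs <- if (!is.null(run)) {
      rep_ <- run$report
      rep_[rep_$pass %in% TRUE, c("feature_i", "feature_j")]
    } else NULL
    tibble::tibble(
      seed = sd,
      feature_i = planted$feature_i, feature_j = planted$feature_j,
      in_subset1 = in_set(run$subset1),
      in_subset2 = in_set(run$subset2),
      in_combined = in_set(run$combined),
      screened = in_set(screened_pairs)
    )
  })
  rates <- colMeans(rows[c("in_subset1", "in_subset2", "in_combined",
                           "screened")])
  attr(rows, "rates") <- rates
  class(rows) <- c("recovery_report", class(rows))
  rows
}

# stage design implied by a generator config: typical point = last point of
# each stage, onset = typical point of the last stage, lookback = N_e such
# that the window starts at the pre-onset typical point
default_design <- function(cf) {
  sm <- stats::setNames(cf$stage_map, seq_along(cf$stage_map))
  typical <- vapply(unique(cf$stage_map), function(stg) {
    max(as.integer(names(sm)[sm == stg]))
  }, integer(1))
  onset <- typical[[length(typical)]]
  stage_design(typical, onset_point = onset,
               lookback = min(3, onset - 1))
}
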