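#' Time-series omics dataset
#'
#' Bundles a wide sample-by-feature abundance table with the study-design
#' annotations the rest of the package needs: subject identity, group
#' (`"control"` / `"model"`), a 1-based time-point index, and a map from time
#' points to disease-stage labels. Abundances must be strictly positive
#' relative quantities (e.g. internal-standard-normalized peak areas) because
#' every downstream statistic is built on feature ratios.
#'
#' @param data A data frame: one row per serum sample, with the id columns
#'   named by `subject`, `group`, `time`, and one numeric column per feature.
#' @param subject,group,time Names of the id columns in `data`.
#' @param stage_map Stage label per time point: an unnamed character vector of
#'   length `N` (position = time index) or a vector named by time index.
#' @param features Feature column names, in canonical order. Defaults to every
#'   non-id column of `data`, in their column order. The canonical order is
#'   preserved by I/O and fixes the `i < j` orientation of all ratios.
#'
#' @return A `ts_dataset` object: a list with elements `data` (tibble with
#'   columns `subject`, `group`, `time`, then the features), `features`,
#'   `stage_map`, `n_time` and `stages`.
#'
#' @details Missing values are not allowed: a cell must be a positive number,
#'   since ratios and standard deviations are undefined otherwise; impute
#'   upstream if needed. Unbalanced designs (subjects absent at some time
#'   points) are accepted with a warning; per-time-point computations use
#'   whichever samples are present.
#'
#' @examples
#' tab <- expand.grid(subject = c("r1", "r2", "r3"), time = 1:3)
#' tab$group <- "model"
#' tab$A <- runif(9, 1, 2); tab$B <- runif(9, 1, 2)
#' ds <- ts_dataset(tab, stage_map = c("H", "CIR", "CIR"))
#' ds$n_time
#' @export
ts_dataset <- function(data, subject = "subject", group = "group",
                       time = "time", stage_map, features = NULL) {
  data <- tibble::as_tibble(data)
  id_cols <- c(subject = subject, group = group, time = time)
  missing_cols <- setdiff(unname(id_cols), names(data))
  if (length(missing_cols) > 0) {
    stop("schema error: column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(features)) {
    features <- setdiff(names(data), unname(id_cols))
  }
  if (length(features) < 2) {
    stop("schema error: at least two feature columns are required", call. = FALSE)
  }
  out <- tibble::tibble(
    subject = as.character(data[[subject]]),
    group = as.character(data[[group]]),
    time = as.integer(data[[time]])
  )
  out <- dplyr::bind_cols(out, data[features])

  bad_group <- setdiff(unique(out$group), c("control", "model"))
  if (length(bad_group) > 0) {
    stop("schema error: group labels must be 'control' or 'model'; found: ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(out$time)) || any(out$time < 1)) {
    stop("validation error: time indices must be positive integers (1-based)",
         call. = FALSE)
  }

  dup <- out[duplicated(out[c("subject", "time")]), c("subject", "time")]
  if (nrow(dup) > 0) {
    stop("validation error: duplicate (subject, time) pair(s): ",
         paste(sprintf("(%s, t=%d)", dup$subject, dup$time), collapse = "; "),
         call. = FALSE)
  }

  for (f in features) {
    v <- out[[f]]
    if (!is.numeric(v)) {
      stop("validation error: feature '", f, "' is not numeric", call. = FALSE)
    }
    bad <- which(is.na(v) | v <= 0)
    if (length(bad) > 0) {
      stop("validation error: non-positive or missing abundance for feature '",
           f, "' in sample (subject ", out$subject[bad[1]], ", t=",
           out$time[bad[1]], ")", call. = FALSE)
    }
  }

  stage_map <- normalize_stage_map(stage_map, max(out$time))
  n_time <- length(stage_map)
  if (max(out$time) > n_time) {
    stop("validation error: data contain time index ", max(out$time),
         " beyond the stage map (N = ", n_time, ")", call. = FALSE)
  }

  counts <- table(out$subject)
  if (length(unique(counts)) > 1 || any(counts < n_time)) {
    warning("unbalanced design: some subjects are not observed at all ",
            n_time, " time points", call. = FALSE)
  }

  structure(
    list(
      data = out,
      features = features,
      stage_map = stage_map,
      n_time = n_time,
      stages = unique(unname(stage_map))
    ),
    class = "ts_dataset"
  )
}

# stage_map -> character vector named "1".."N"
normalize_stage_map <- function(stage_map, n_min) {
  stage_map <- unlist(stage_map)
  if (is.null(names(stage_map)) || all(names(stage_map) == "")) {
    names(stage_map) <- seq_along(stage_map)
  }
  idx <- as.integer(names(stage_map))
  if (any(is.na(idx))) {
    stop("schema error: stage_map names must be time indices", call. = FALSE)
  }
  n <- max(idx, n_min)
  if (!setequal(idx, seq_len(n))) {
    stop("validation error: stage_map must cover every time index 1..", n,
         call. = FALSE)
  }
  out <- as.character(stage_map[order(idx)])
  names(out) <- seq_len(n)
  out
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat("<ts_dataset> ", nrow(x$data), " samples, ", length(x$features),
      " features, N = ", x$n_time, " time points\n", sep = "")
  cat("  groups: ",
      paste(sprintf("%s (n=%d subjects)",
                    names(table(unique(x$data[c("subject", "group")])$group)),
                    table(unique(x$data[c("subject", "group")])$group)),
            collapse = ", "), "\n", sep = "")
  cat("  stages: ", paste(sprintf("%s -> T%s", x$stage_map, names(x$stage_map)),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.ts_dataset <- function(x, ...) x$data

#' Abundance matrix for a slice of the dataset
#'
#' @param ds A [ts_dataset()].
#' @param time Optional time index (or vector) to restrict to.
#' @param group Optional group label to restrict to.
#' @return Numeric matrix, samples in rows (named `subject.time`), features in
#'   canonical column order.
#' @export
abundance_matrix <- function(ds, time = NULL, group = NULL) {
  stopifnot(inherits(ds, "ts_dataset"))
  d <- ds$data
  if (!is.null(time)) d <- d[d$time %in% time, , drop = FALSE]
  if (!is.null(group)) d <- d[d$group %in% group, , drop = FALSE]
  m <- as.matrix(d[ds$features])
  rownames(m) <- paste(d$subject, d$time, sep = ".")
  m
}

#' Stage design: typical points, onset and look-back window
#'
#' Encodes the time anatomy of the study: the typical (last) time point of each
#' disease stage, the onset point `T_s` whose early-warning signal is sought,
#' and the number of pre-onset time points `N_e` to examine.
#'
#' @param typical_points Named integer vector, stage label -> typical time
#'   index.
#' @param onset_point Integer `s` with `1 < s <= N`: the typical time point of
#'   the disease whose onset is analyzed.
#' @param lookback Integer `N_e` with `0 < N_e < N`: how many time points
#'   before the onset point are examined by the concentration analysis.
#' @return A `stage_design` object (list).
#' @examples
#' stage_design(c(H = 1, CIR = 4, HCC = 7), onset_point = 7, lookback = 3)
#' @export
stage_design <- function(typical_points, onset_point, lookback) {
  typical_points <- vapply(typical_points, as.integer, integer(1))
  if (is.null(names(typical_points)) || any(names(typical_points) == "")) {
    stop("design error: typical_points must be named by stage", call. = FALSE)
  }
  onset_point <- as.integer(onset_point)
  lookback <- as.integer(lookback)
  if (onset_point <= 1) {
    stop("design error: onset_point must exceed 1", call. = FALSE)
  }
  if (lookback < 1 || onset_point - lookback < 1) {
    stop("design error: lookback must satisfy 0 < N_e and s - N_e >= 1",
         call. = FALSE)
  }
  structure(
    list(typical_points = typical_points, onset_point = onset_point,
         lookback = lookback),
    class = "stage_design"
  )
}

#' @export
print.stage_design <- function(x, ...) {
  cat("<stage_design> typical points: ",
      paste(sprintf("%s=T%d", names(x$typical_points), x$typical_points),
            collapse = ", "),
      "; onset T_s=", x$onset_point, ", lookback N_e=", x$lookback, "\n",
      sep = "")
  invisible(x)
}

#' Validate a dataset against a stage design
#'
#' Checks that the design is compatible with the dataset (typical points and
#' onset within `1..N`, stages contiguous in time) and tabulates per-time-point
#' sample counts per group.
#'
#' @param ds A [ts_dataset()].
#' @param design A [stage_design()].
#' @return A tibble with one row per (time, group): columns `time`, `stage`,
#'   `group`, `n_samples`, plus logical attribute columns are avoided — the
#'   function throws on a violated design instead.
#' @export
validate_design <- function(ds, design) {
  stopifnot(inherits(ds, "ts_dataset"), inherits(design, "stage_design"))
  n <- ds$n_time

  # every stage must span a consecutive run of time points
  for (stg in unique(ds$stage_map)) {
    idx <- as.integer(names(ds$stage_map)[ds$stage_map == stg])
    if (!identical(sort(idx), seq(min(idx), max(idx)))) {
      stop("design error: stage '", stg, "' is assigned to non-consecutive ",
           "time points {", paste(sort(idx), collapse = ", "), "}",
           call. = FALSE)
    }
  }
  bad_stage <- setdiff(names(design$typical_points), unique(ds$stage_map))
  if (length(bad_stage) > 0) {
    stop("design error: typical point declared for unknown stage(s): ",
         paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  if (any(design$typical_points > n) || design$onset_point > n) {
    stop("design error: typical/onset points exceed N = ", n, call. = FALSE)
  }

  ds$data |>
    dplyr::count(.data$time, .data$group, name = "n_samples") |>
    dplyr::mutate(stage = unname(ds$stage_map[as.character(.data$time)]),
                  .after = "time") |>
    dplyr::arrange(.data$time, .data$group)
}

#' Look-back window of a stage design
#'
#' The dynamic-network indices `i` examined by the concentration analysis:
#' `s - N_e <= i < s - 1` (upper bound exclusive), so the window ends with the
#' network spanning the onset transition. For `s = 7`, `N_e = 3` this is
#' `{4, 5}`.
#'
#' @param design A [stage_design()].
#' @return Integer vector of network indices.
#' @export
concentration_window <- function(design) {
  stopifnot(inherits(design, "stage_design"))
  lo <- design$onset_point - design$lookback
  hi <- design$onset_point - 2
  if (hi < lo || lo < 1) {
    stop("design error: empty or out-of-range concentration window",
         call. = FALSE)
  }
  seq(lo, hi)
}
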