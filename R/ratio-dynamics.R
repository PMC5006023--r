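#' Chebyshev coefficient for a two-thirds effective range
#'
#' With half-width `gamma * sd` at equal sample probability, Chebyshev's
#' inequality guarantees that at least two-thirds of the population lies
#' inside the range: `1 - 1/gamma^2 = 2/3` gives `gamma = sqrt(3) = 1.732`.
#' @export
CHEBYSHEV_GAMMA <- 1.732

#' Default edge threshold on |NOR|
#' @export
DEFAULT_TAU <- 0.85

#' Sample probability of a time point in a two-point network
#'
#' When a dynamic network is built from adjacent time points with `n_t` and
#' `n_t1` samples, the first point's sample probability is
#' `p_t = n_t / (n_t + n_t1)`; it scales that point's effective-range
#' half-width. Equal sample sets give `p_t = 0.5`.
#'
#' @param n_t,n_t1 Sample counts at the two time points (each >= 1).
#' @return A number in (0, 1).
#' @examples
#' sample_probability(7, 7) # 0.5
#' @export
sample_probability <- function(n_t, n_t1) {
  if (n_t < 1 || n_t1 < 1) {
    stop("insufficient-data error: both time points need >= 1 sample",
         call. = FALSE)
  }
  n_t / (n_t + n_t1)
}

#' Effective range of a feature ratio at one time point
#'
#' The effective range is the interval `u -/+ 2 * p * gamma * sigma`, where
#' `u` and `sigma` are the sample mean and standard deviation (divisor `n`,
#' population form) of the per-sample ratio values, `p` is the time point's
#' sample probability in the network under construction, and `gamma` is the
#' Chebyshev coefficient. At `p = 0.5` the range reduces to `u -/+ gamma *
#' sigma` and contains at least two-thirds of the population in the limit.
#'
#' @param values Numeric vector of per-sample ratio values at one time point
#'   (>= 2 values).
#' @param p Sample probability in (0, 1); see [sample_probability()].
#' @param gamma Chebyshev coefficient (> 0); default [CHEBYSHEV_GAMMA].
#' @param sd_divisor `"n"` (default, population form) or `"n-1"`.
#' @return An `effective_range` object: list with `mean`, `sd`, `floor`,
#'   `ceiling`, `p`, `n`, and `degenerate` (`TRUE` when `sd == 0`).
#' @examples
#' effective_range(c(1.8, 2.2, 2.0), p = 0.5)
#' @export
effective_range <- function(values, p, gamma = CHEBYSHEV_GAMMA,
                            sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) {
    stop("insufficient-data error: an effective range needs >= 2 samples",
         call. = FALSE)
  }
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  u <- mean(values)
  s <- sqrt(sum((values - u)^2) / if (sd_divisor == "n") n else n - 1)
  h <- 2 * p * gamma * s
  structure(
    list(mean = u, sd = s, floor = u - h, ceiling = u + h, p = p, n = n,
         degenerate = s == 0),
    class = "effective_range"
  )
}

#' @export
print.effective_range <- function(x, ...) {
  cat(sprintf("<effective_range> [%.4g, %.4g]  (u=%.4g, sd=%.4g, p=%.3g, n=%d)%s\n",
              x$floor, x$ceiling, x$mean, x$sd, x$p, x$n,
              if (x$degenerate) "  [degenerate: sd = 0]" else ""))
  invisible(x)
}

#' Classify the change between two effective ranges
#'
#' Between time `t` (`a`) and `t + 1` (`b`) an effective range can move up
#' (both floor and ceiling strictly increase), move down (both strictly
#' decrease), or one range can lie within the other (inclusive), which carries
#' no direction and is excluded from the NOR. Exactly equal ranges are
#' `"identical"`.
#'
#' @param a,b [effective_range()] objects at times `t` and `t + 1`.
#' @return One of `"upshift"`, `"downshift"`, `"nested"`, `"identical"`.
#' @export
classify_change <- function(a, b) {
  stopifnot(inherits(a, "effective_range"), inherits(b, "effective_range"))
  classify_change_num(a$floor, a$ceiling, b$floor, b$ceiling)
}

# vectorized core shared with the network builder
classify_change_num <- function(fa, ca, fb, cb) {
  out <- rep("nested", length(fa))
  out[fb > fa & cb > ca] <- "upshift"
  out[fb < fa & cb < ca] <- "downshift"
  out[fb == fa & cb == ca] <- "identical"
  out
}

#' Signed non-overlapping ratio (NOR) between adjacent effective ranges
#'
#' Quantifies how far the effective range of a feature ratio shifts between
#' two adjacent time points. With range lengths `L1 = a$ceiling - a$floor`,
#' `L2 = b$ceiling - b$floor` and overlap
#' `O = max(0, min(ceilings) - max(floors))`:
#' `|NOR| = (L1 + L2 - 2 * O) / (L1 + L2)`, signed `+` for an upshift and `-`
#' for a downshift. `|NOR| = 1` exactly when the ranges are disjoint; nested
#' or identical ranges carry no direction and have no NOR value.
#'
#' Degenerate ranges (`sd = 0`, a point): two separated points are disjoint
#' with `|NOR| = 1`; a point falling inside (or equal to) the other range is
#' nested/identical and undefined.
#'
#' @param a,b [effective_range()] objects at times `t` and `t + 1`.
#' @return A `nor_value` object: list with `value` (signed number in
#'   `[-1, 1]`, or `NA` when undefined), `case`, `L1`, `L2`.
#' @examples
#' a <- effective_range(c(1, 2, 3), p = 0.5)
#' b <- effective_range(c(7, 8, 9), p = 0.5)
#' nor_value(a, b)$value # +1: disjoint upshift
#' @export
nor_value <- function(a, b) {
  case <- classify_change(a, b)
  l1 <- a$ceiling - a$floor
  l2 <- b$ceiling - b$floor
  val <- NA_real_
  if (case %in% c("upshift", "downshift")) {
    val <- nor_magnitude_num(a$floor, a$ceiling, b$floor, b$ceiling)
    if (case == "downshift") val <- -val
  }
  structure(list(value = val, case = case, L1 = l1, L2 = l2),
            class = "nor_value")
}

# |NOR| for interval pairs; vectorized. Defined (and only called) for
# non-nested pairs; L1 + L2 = 0 then implies disjoint points -> 1.
nor_magnitude_num <- function(fa, ca, fb, cb) {
  l1 <- ca - fa
  l2 <- cb - fb
  o <- pmax(0, pmin(ca, cb) - pmax(fa, fb))
  tot <- l1 + l2
  ifelse(tot > 0, (tot - 2 * o) / tot, 1)
}

#' @export
print.nor_value <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf("<nor_value> undefined (%s ranges)\n", x$case))
  } else {
    cat(sprintf("<nor_value> %+.4f (%s)\n", x$value, x$case))
  }
  invisible(x)
}

#' Per-sample values of one feature ratio, by time point
#'
#' Computes `r_ij = f_i / f_j` for every sample, with the pair canonicalized
#' to `i < j` in the dataset's feature order (a request in the opposite
#' orientation is flipped and flagged).
#'
#' @param ds A [ts_dataset()].
#' @param i,j Feature names or canonical indices; `i != j`.
#' @param group Optional group restriction (`"control"` or `"model"`).
#' @return A tibble with columns `subject`, `group`, `time`, `value` and
#'   attributes `feature_i`, `feature_j`, `flipped`.
#' @export
ratio_series <- function(ds, i, j, group = NULL) {
  stopifnot(inherits(ds, "ts_dataset"))
  idx <- resolve_features(ds, c(i, j))
  if (idx[1] == idx[2]) {
    stop("argument error: a ratio needs two distinct features", call. = FALSE)
  }
  flipped <- idx[1] > idx[2]
  idx <- sort(idx)
  d <- ds$data
  if (!is.null(group)) d <- d[d$group %in% group, , drop = FALSE]
  fi <- ds$features[idx[1]]
  fj <- ds$features[idx[2]]
  out <- tibble::tibble(
    subject = d$subject, group = d$group, time = d$time,
    value = d[[fi]] / d[[fj]]
  )
  attr(out, "feature_i") <- fi
  attr(out, "feature_j") <- fj
  attr(out, "flipped") <- flipped
  out
}

# feature names or integer indices -> integer indices in canonical order
resolve_features <- function(ds, x) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (any(idx < 1 | idx > length(ds$features))) {
      stop("argument error: feature index out of range", call. = FALSE)
    }
    return(idx)
  }
  idx <- match(x, ds$features)
  if (any(is.na(idx))) {
    stop("argument error: unknown feature(s): ",
         paste(x[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' All canonical feature pairs
#'
#' @param features Character vector of feature names in canonical order.
#' @return Tibble with columns `feature_i`, `feature_j` (`i < j`), one row per
#'   unordered pair; `choose(m, 2)` rows for `m` features.
#' @export
feature_pairs <- function(features) {
  m <- length(features)
  if (m < 2) stop("argument error: need >= 2 features", call. = FALSE)
  idx <- utils::combn(m, 2)
  tibble::tibble(feature_i = features[idx[1, ]], feature_j = features[idx[2, ]])
}

#' Audit table of ranges and NOR values for every pair and transition
#'
#' Computes, for every canonical feature pair and every adjacent pair of time
#' points, the effective ranges at both points and the NOR of the transition.
#' This is the full evidence table behind [network_series()]; write it to TSV
#' for audit with [readr::write_tsv()].
#'
#' @param ds A [ts_dataset()].
#' @param features Features to use (default: all), in canonical order.
#' @param gamma Chebyshev coefficient.
#' @param group Group whose samples drive the ranges (default `"model"`).
#' @param sd_divisor Passed to the range computation (see
#'   [effective_range()]).
#' @return Tibble with one row per (pair, transition `t`): columns
#'   `feature_i`, `feature_j`, `t`, `u_t`, `sd_t`, `floor_t`, `ceiling_t`,
#'   `u_t1`, `sd_t1`, `floor_t1`, `ceiling_t1`, `p_t`, `case`, `nor`.
#' @export
ratio_audit <- function(ds, features = NULL, gamma = CHEBYSHEV_GAMMA,
                        group = "model", sd_divisor = "n") {
  stopifnot(inherits(ds, "ts_dataset"))
  if (is.null(features)) features <- ds$features
  features <- ds$features[sort(resolve_features(ds, features))]
  purrr::map_dfr(seq_len(ds$n_time - 1), function(t) {
    transition_table(ds, features, t, gamma, group, sd_divisor)
  })
}

# ranges + NOR for all pairs at one transition t -> t+1; the vectorized hot
# path shared by ratio_audit() and build_network()
transition_table <- function(ds, features, t, gamma, group, sd_divisor) {
  a_t <- abundance_matrix(ds, time = t, group = group)[, features, drop = FALSE]
  a_t1 <- abundance_matrix(ds, time = t + 1, group = group)[, features, drop = FALSE]
  n_t <- nrow(a_t)
  n_t1 <- nrow(a_t1)
  if (n_t < 2 || n_t1 < 2) {
    stop("insufficient-data error: < 2 samples in group '", group,
         "' at time ", if (n_t < 2) t else t + 1, call. = FALSE)
  }
  p_t <- sample_probability(n_t, n_t1)
  pairs <- feature_pairs(features)
  ii <- match(pairs$feature_i, features)
  jj <- match(pairs$feature_j, features)

  r_t <- a_t[, ii, drop = FALSE] / a_t[, jj, drop = FALSE]
  r_t1 <- a_t1[, ii, drop = FALSE] / a_t1[, jj, drop = FALSE]

  rng <- function(r, p) {
    n <- nrow(r)
    u <- colMeans(r)
    s <- sqrt(colMeans(sweep(r, 2, u)^2))
    if (sd_divisor == "n-1") s <- s * sqrt(n / (n - 1))
    h <- 2 * p * gamma * s
    list(u = u, s = s, fl = u - h, ce = u + h)
  }
  ra <- rng(r_t, p_t)
  rb <- rng(r_t1, 1 - p_t)

  case <- classify_change_num(ra$fl, ra$ce, rb$fl, rb$ce)
  nor <- rep(NA_real_, nrow(pairs))
  dir <- case %in% c("upshift", "downshift")
  if (any(dir)) {
    mag <- nor_magnitude_num(ra$fl[dir], ra$ce[dir], rb$fl[dir], rb$ce[dir])
    nor[dir] <- ifelse(case[dir] == "downshift", -mag, mag)
  }

  tibble::tibble(
    feature_i = pairs$feature_i, feature_j = pairs$feature_j, t = t,
    u_t = ra$u, sd_t = ra$s, floor_t = ra$fl, ceiling_t = ra$ce,
    u_t1 = rb$u, sd_t1 = rb$s, floor_t1 = rb$fl, ceiling_t1 = rb$ce,
    p_t = p_t, case = case, nor = nor
  )
}
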