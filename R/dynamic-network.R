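#' Build one signed dynamic network between adjacent time points
#'
#' For every canonical feature pair, the NOR of the ratio between time `t` and
#' `t + 1` is computed from the model-group samples; pairs with `NOR >= tau`
#' are linked by a red (`+`) edge, pairs with `NOR <= -tau` by a green (`-`)
#' edge. Nested or identical ranges never create an edge. All retained
#' features are nodes, including isolates, so degree tables are comparable
#' across networks.
#'
#' @param ds A [ts_dataset()].
#' @param features Features to include (default all), canonical order.
#' @param t Time index of the network's first point, `1 <= t < N`.
#' @param tau Edge threshold on `|NOR|`, in `(0, 1]`; default [DEFAULT_TAU].
#' @param gamma Chebyshev coefficient; default [CHEBYSHEV_GAMMA].
#' @param group Group whose samples drive the ranges (default `"model"`).
#' @param sd_divisor See [effective_range()].
#' @return A `dyn_network` object: list with `t`, `nodes`, `edges` (tibble
#'   `feature_i`, `feature_j`, `sign` (`"red"`/`"green"`), `nor`), `tau`,
#'   `gamma`, `p_t`.
#' @export
build_network <- function(ds, features = NULL, t, tau = DEFAULT_TAU,
                          gamma = CHEBYSHEV_GAMMA, group = "model",
                          sd_divisor = "n") {
  stopifnot(inherits(ds, "ts_dataset"))
  if (t < 1 || t >= ds$n_time) {
    stop("index error: t must satisfy 1 <= t < N = ", ds$n_time, call. = FALSE)
  }
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]", call. = FALSE)
  if (is.null(features)) features <- ds$features
  features <- ds$features[sort(resolve_features(ds, features))]

  tab <- transition_table(ds, features, t, gamma, group, sd_divisor)
  hit <- !is.na(tab$nor) & abs(tab$nor) >= tau
  edges <- tab[hit, c("feature_i", "feature_j", "nor")]
  edges <- dplyr::mutate(
    edges, sign = dplyr::if_else(.data$nor > 0, "red", "green"),
    .before = "nor"
  )
  structure(
    list(t = t, nodes = features, edges = edges, tau = tau, gamma = gamma,
         p_t = tab$p_t[1]),
    class = "dyn_network"
  )
}

#' @export
print.dyn_network <- function(x, ...) {
  cat(sprintf("<dyn_network> DN-%d (T%d -> T%d): %d nodes, %d edges (%d red, %d green), tau = %g\n",
              x$t, x$t, x$t + 1, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "red"), sum(x$edges$sign == "green"), x$tau))
  invisible(x)
}

#' Build the full series of dynamic networks
#'
#' One network per adjacent pair of time points: `DN-1 ... DN-(N-1)`.
#'
#' @inheritParams build_network
#' @return A `dyn_network_series`: list of `N - 1` [build_network()] results.
#' @export
network_series <- function(ds, features = NULL, tau = DEFAULT_TAU,
                           gamma = CHEBYSHEV_GAMMA, group = "model",
                           sd_divisor = "n") {
  stopifnot(inherits(ds, "ts_dataset"))
  if (ds$n_time < 2) stop("need N >= 2 time points", call. = FALSE)
  out <- lapply(seq_len(ds$n_time - 1), function(t) {
    build_network(ds, features, t, tau, gamma, group, sd_divisor)
  })
  structure(out, class = "dyn_network_series")
}

#' @export
print.dyn_network_series <- function(x, ...) {
  cat("<dyn_network_series> ", length(x), " networks over ",
      length(x) + 1, " time points\n", sep = "")
  for (nw in x) {
    cat(sprintf("  DN-%d: %d edges (%d red, %d green)\n", nw$t,
                nrow(nw$edges), sum(nw$edges$sign == "red"),
                sum(nw$edges$sign == "green")))
  }
  invisible(x)
}

#' Per-network and accumulated node degrees
#'
#' @param networks A `dyn_network_series` or list of `dyn_network`s.
#' @return A tibble with one row per (feature, network): columns `feature`,
#'   `t`, `degree`, plus `accumulated` (the feature's total degree over all
#'   networks, repeated per row) and `rank` (dense rank by descending degree
#'   within each network; ties share a rank).
#' @export
degree_stats <- function(networks) {
  networks <- as_network_list(networks)
  per <- purrr::map_dfr(networks, function(nw) {
    deg <- degrees_of(nw)
    tibble::tibble(feature = names(deg), t = nw$t, degree = unname(deg))
  })
  per |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(accumulated = sum(.data$degree)) |>
    dplyr::group_by(.data$t) |>
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$degree))) |>
    dplyr::ungroup()
}

degrees_of <- function(nw) {
  deg <- stats::setNames(integer(length(nw$nodes)), nw$nodes)
  if (nrow(nw$edges) > 0) {
    tab <- table(c(nw$edges$feature_i, nw$edges$feature_j))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

as_network_list <- function(networks) {
  if (inherits(networks, "dyn_network")) return(list(networks))
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, logical(1), "dyn_network")))
  networks
}

#' Edge counts per network
#'
#' @param networks A `dyn_network_series`.
#' @return Tibble with columns `t`, `n_edges`, `n_red`, `n_green`.
#' @export
edge_counts <- function(networks) {
  networks <- as_network_list(networks)
  purrr::map_dfr(networks, function(nw) {
    tibble::tibble(t = nw$t, n_edges = nrow(nw$edges),
                   n_red = sum(nw$edges$sign == "red"),
                   n_green = sum(nw$edges$sign == "green"))
  })
}
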