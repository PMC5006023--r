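#' Dynamic-concentration analysis: persistent same-sign edges
#'
#' Scans the pre-onset window of networks `DN-i`,
#' `s - N_e <= i < s - 1` (see [concentration_window()]), and keeps the
#' feature ratios whose edge is present with the same sign in every network of
#' the window — a persistent monotone metabolic disturbance leading into the
#' onset point. For `s = 7`, `N_e = 3` the window is `DN-4` and `DN-5`.
#'
#' @param networks A `dyn_network_series` from [network_series()].
#' @param design A [stage_design()] supplying the onset point and look-back.
#' @return A `ratio_subset` tibble: columns `feature_i`, `feature_j`, `sign`,
#'   and one `nor_dn<t>` column per window network; attribute
#'   `provenance = "concentration"` and `window`.
#' @export
dynamic_concentration <- function(networks, design) {
  networks <- as_network_list(networks)
  window <- concentration_window(design)
  have <- vapply(networks, function(nw) nw$t, integer(1))
  if (!all(window %in% have)) {
    stop("design error: concentration window {",
         paste(window, collapse = ", "), "} outside the built networks",
         call. = FALSE)
  }
  win_edges <- purrr::map(window, function(t) {
    nw <- networks[[match(t, have)]]
    e <- nw$edges
    names(e)[names(e) == "nor"] <- sprintf("nor_dn%d", t)
    e
  })
  # inner-join on (pair, sign): keeps edges present with one sign everywhere
  out <- purrr::reduce(win_edges, function(x, y) {
    dplyr::inner_join(x, y, by = c("feature_i", "feature_j", "sign"))
  })
  out <- dplyr::arrange(out, .data$feature_i, .data$feature_j)
  new_ratio_subset(out, provenance = "concentration", window = window)
}

#' Topological-structure analysis: edges of the top-degree nodes
#'
#' Picks the network with the most edges (the key transition), ranks its nodes
#' by degree, and returns every ratio incident to the top `k` nodes in that
#' network. Degree ties are broken first by larger accumulated degree over all
#' networks, then by canonical feature order. If several networks tie for the
#' most edges, the earliest is used, with a warning.
#'
#' @param networks A `dyn_network_series`.
#' @param k Number of top nodes (>= 1).
#' @return A `ratio_subset` tibble: columns `feature_i`, `feature_j`, `sign`,
#'   `nor`, `top_node` (which selected node the edge is incident to);
#'   attributes `provenance = "topology"`, `key_network` (its `t`),
#'   `top_nodes`.
#' @export
topological_structure <- function(networks, k = 1) {
  networks <- as_network_list(networks)
  if (k < 1) stop("argument error: k must be >= 1", call. = FALSE)
  sizes <- vapply(networks, function(nw) nrow(nw$edges), integer(1))
  if (all(sizes == 0)) {
    stop("all networks are empty: no topological structure to analyze",
         call. = FALSE)
  }
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    warning("multiple networks tie for the most edges (t = ",
            paste(vapply(networks[best], function(nw) nw$t, integer(1)),
                  collapse = ", "),
            "); using the earliest", call. = FALSE)
  }
  key <- networks[[best[1]]]

  deg <- degrees_of(key)
  acc <- degree_stats(networks) |>
    dplyr::distinct(.data$feature, .data$accumulated)
  acc <- stats::setNames(acc$accumulated, acc$feature)[names(deg)]
  ord <- order(-deg, -acc, match(names(deg), key$nodes))
  top_nodes <- names(deg)[ord][seq_len(min(k, length(deg)))]

  out <- purrr::map_dfr(top_nodes, function(node) {
    hit <- key$edges$feature_i == node | key$edges$feature_j == node
    dplyr::mutate(key$edges[hit, ], top_node = node)
  })
  out <- dplyr::distinct(out, .data$feature_i, .data$feature_j,
                         .keep_all = TRUE)
  out <- dplyr::arrange(out, .data$feature_i, .data$feature_j)
  new_ratio_subset(out, provenance = "topology", key_network = key$t,
                   top_nodes = top_nodes)
}

#' Combine two candidate-ratio subsets
#'
#' Intersects or unites the ratio pairs of the concentration and topology
#' subsets. An empty intersection is reported with a warning, not an error.
#'
#' @param s1,s2 `ratio_subset` tibbles over the same feature universe.
#' @param mode `"intersection"` (default) or `"union"`.
#' @return A `ratio_subset` tibble with columns `feature_i`, `feature_j` and a
#'   `provenance` column recording, for each ratio, which parent(s) it came
#'   from (`"both"`, or the parent's provenance label); the tibble's own
#'   `provenance` attribute is `mode`.
#' @export
combine_subsets <- function(s1, s2, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  p1 <- attr(s1, "provenance") %||% "subset1"
  p2 <- attr(s2, "provenance") %||% "subset2"
  k1 <- s1[c("feature_i", "feature_j")]
  k2 <- s2[c("feature_i", "feature_j")]
  both <- dplyr::inner_join(k1, k2, by = c("feature_i", "feature_j"))
  out <- if (mode == "intersection") {
    dplyr::mutate(both, provenance = "both")
  } else {
    dplyr::bind_rows(
      dplyr::mutate(both, provenance = "both"),
      dplyr::mutate(dplyr::anti_join(k1, k2, by = c("feature_i", "feature_j")),
                    provenance = p1),
      dplyr::mutate(dplyr::anti_join(k2, k1, by = c("feature_i", "feature_j")),
                    provenance = p2)
    )
  }
  if (mode == "intersection" && nrow(out) == 0) {
    warning("the two subsets share no ratio: intersection is empty",
            call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$feature_i, .data$feature_j)
  new_ratio_subset(out, provenance = mode)
}

new_ratio_subset <- function(tbl, provenance, ...) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "provenance") <- provenance
  extra <- list(...)
  for (nm in names(extra)) attr(tbl, nm) <- extra[[nm]]
  class(tbl) <- c("ratio_subset", class(tbl))
  tbl
}

#' Ratio pairs of a subset as a plain tibble
#' @param subset A `ratio_subset`.
#' @return Tibble with columns `feature_i`, `feature_j`.
#' @export
subset_pairs <- function(subset) {
  tibble::as_tibble(subset[c("feature_i", "feature_j")])
}
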