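#' Read a wide time-series feature table
#'
#' Loads a CSV or TSV table (delimiter chosen by file extension, override with
#' `delim`) and validates it into a [ts_dataset()]. Feature column order in the
#' file becomes the canonical feature order.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param subject_col,group_col,time_col Names of the id columns.
#' @param stage_map Stage label per time point (see [ts_dataset()]).
#' @param delim Optional field delimiter; default `","` for `.csv`, `"\t"`
#'   otherwise.
#' @return A [ts_dataset()].
#' @export
read_ts_dataset <- function(path, subject_col = "subject",
                            group_col = "group", time_col = "time",
                            stage_map, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  ts_dataset(tab, subject = subject_col, group = group_col, time = time_col,
             stage_map = stage_map)
}

#' Write a time-series dataset back to disk
#'
#' Writes the sample table (id columns then features in canonical order) as
#' CSV or TSV, UTF-8, `.` decimal separator. Numbers round-trip bit-exactly
#' through [read_ts_dataset()] for finite decimal inputs.
#'
#' @param ds A [ts_dataset()].
#' @param path Output path; `.csv` selects comma, anything else tab.
#' @return `path`, invisibly.
#' @export
write_ts_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "ts_dataset"))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(ds$data, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Export a dynamic-network series as edge lists and GraphML
#'
#' Writes `dn_<t>.edges.tsv` (columns `feature_i`, `feature_j`, `t`, `sign`,
#' `nor`) and `dn_<t>.graphml` for every network in the series. Isolated nodes
#' are kept in the GraphML so degree tables are comparable across networks.
#'
#' @param networks A `dyn_network_series` from [network_series()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_networks <- function(networks, dir) {
  stopifnot(inherits(networks, "dyn_network_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nw in networks) {
    base <- file.path(dir, sprintf("dn_%d", nw$t))
    edges <- nw$edges
    edges$t <- nw$t
    readr::write_tsv(edges[c("feature_i", "feature_j", "t", "sign", "nor")],
                     paste0(base, ".edges.tsv"), progress = FALSE)
    g <- as_igraph(nw)
    igraph::write_graph(g, paste0(base, ".graphml"), format = "graphml")
    files <- c(files, paste0(base, c(".edges.tsv", ".graphml")))
  }
  invisible(files)
}

#' Convert a dynamic network to an igraph object
#'
#' @param nw A `dyn_network` from [build_network()].
#' @return An undirected `igraph` graph whose edges carry `sign` and `nor`
#'   attributes; all retained features are vertices, including isolates.
#' @export
as_igraph <- function(nw) {
  stopifnot(inherits(nw, "dyn_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nw$nodes), name = nw$nodes)
  if (nrow(nw$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(nw$edges$feature_i, nw$edges$feature_j),
      sign = nw$edges$sign, nor = nw$edges$nor
    )
  }
  g
}
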