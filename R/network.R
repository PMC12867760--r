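#' Social-network edge table from pairwise CCR
#'
#' One edge per unordered animal pair, weighted by the pair's CCR scaled
#' down by 10 (`weight = ccr_pct / 10`, so weights lie in `[0, 10]`) —
#' the scaling used to modulate edge thickness in Cytoscape
#' visualizations. Pairs with missing CCR (no coverage) are omitted;
#' zero-weight edges are kept by default.
#'
#' @param ccr_values A table with columns `tag_i`, `tag_j`, `ccr_pct` for
#'   one analysis window (e.g. a window subset of [pair_window_stats()]).
#' @param keep_zero Keep edges with weight 0? Default `TRUE`.
#' @return A `data.table` with columns `source`, `target`, `weight`.
#' @export
build_edge_table <- function(ccr_values, keep_zero = TRUE) {
  cv <- data.table::as.data.table(ccr_values)
  stopifnot(all(c("tag_i", "tag_j", "ccr_pct") %in% names(cv)))
  if ("window_id" %in% names(cv) &&
      data.table::uniqueN(cv$window_id) > 1L) {
    stop("edge table must be built from a single analysis window; ",
         "subset pair_window_stats() first")
  }
  edges <- cv[!is.na(ccr_pct),
              .(source = tag_i, target = tag_j, weight = ccr_pct / 10)]
  if (!keep_zero) edges <- edges[weight > 0]
  edges[]
}

#' Write a Cytoscape-importable edge TSV
#'
#' Tab-delimited, with the exact header `Source`, `Target`,
#' `Edge betweenness` expected by the Cytoscape import used for
#' spring-embedded social-network layouts. (The third column is the
#' scaled CCR edge weight; the header name is kept verbatim for
#' compatibility even though the quantity is not graph-theoretic
#' betweenness.)
#'
#' @param edges An edge table from [build_edge_table()].
#' @param path Output file path.
#' @param digits Fixed number of decimal places for weights. Default 3.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(edges, path, digits = 3) {
  ed <- data.table::as.data.table(edges)
  lines <- c("Source\tTarget\tEdge betweenness",
             if (nrow(ed)) sprintf(paste0("%s\t%s\t%.", digits, "f"),
                                   ed$source, ed$target, ed$weight))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Node strength and density of a social network
#'
#' Simple weighted-graph summaries for light/dark comparisons: per-node
#' strength (sum of incident edge weights) and graph density (mean edge
#' weight).
#'
#' @param edges An edge table from [build_edge_table()].
#' @return A list with `nodes` (a `data.table` of `node`, `strength`) and
#'   `density` (mean weight; `NA` for an empty edge set).
#' @export
network_summary <- function(edges) {
  ed <- data.table::as.data.table(edges)
  long <- data.table::rbindlist(list(
    ed[, .(node = source, weight)], ed[, .(node = target, weight)]))
  nodes <- long[, .(strength = sum(weight)), by = node]
  data.table::setorder(nodes, node)
  list(nodes = nodes[],
       density = if (nrow(ed)) mean(ed$weight) else NA_real_)
}
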