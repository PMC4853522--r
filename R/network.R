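#' Convert RAP-DB gene ids to MSU (TIGR) ids
#'
#' Order-preserving conversion through a mapping table; ids absent from
#' the mapping are reported, never silently dropped, and duplicates in the
#' input yield duplicates in the output.
#'
#' @param genes Character vector of RAP-DB ids.
#' @param mapping An `id_mapping` from [read_id_mapping()] (or any named
#'   character vector RAP -> MSU).
#' @return List with `mapped` (MSU ids, input order, mapped genes only)
#'   and `unmapped` (RAP ids without a mapping, input order).
#' @export
map_ids <- function(genes, mapping) {
  hit <- genes %in% names(mapping)
  list(mapped = unname(unclass(mapping)[genes[hit]]),
       unmapped = genes[!hit])
}

#' Tally genes per rice chromosome
#'
#' Reads the chromosome straight from the RAP locus identifier prefix
#' (`Os01`-`Os12`). Unparseable ids are collected and reported, so the
#' tally plus the unparseable count always equals the input length.
#'
#' @param genes Character vector of ids.
#' @return Named integer vector `chr1`..`chr12` with attribute
#'   `unparseable` (the offending ids).
#' @export
chromosome_distribution <- function(genes) {
  ok <- grepl("^Os(0[1-9]|1[0-2])g[0-9]{7}$", genes)
  chr <- as.integer(substr(genes[ok], 3L, 4L))
  counts <- tabulate(chr, nbins = 12L)
  names(counts) <- paste0("chr", 1:12)
  attr(counts, "unparseable") <- genes[!ok]
  counts
}

#' Induce the interaction subnetwork of a gene list
#'
#' Restricts the edge list to edges with both endpoints in the gene set
#' and reports connected components (size-descending), per-node degree,
#' and each component's hub (maximum degree, lexicographic tie-break).
#' Input genes that end up with no induced edge are reported separately as
#' isolated rather than as single-node components; edge-list nodes outside
#' the gene set are excluded entirely.
#'
#' @param genes Character vector of node ids (same namespace as the edge
#'   list; convert with [map_ids()] first if needed).
#' @param edges An `interaction_edges` data frame.
#' @return A `subnetwork_report`: list with `edges` (induced), `components`
#'   (list of node-id vectors, size descending), `hubs` (one per
#'   component), `degree` (named, connected nodes), `isolated` (sorted
#'   input genes without induced edges).
#' @export
induce_subnetwork <- function(genes, edges) {
  genes <- unique(genes)
  keep <- edges$node_a %in% genes & edges$node_b %in% genes
  sub <- edges[keep, , drop = FALSE]
  if (nrow(sub)) {
    # canonical order makes the report invariant to input ordering
    sub <- sub[order(sub$node_a, sub$node_b), , drop = FALSE]
    rownames(sub) <- NULL
    g <- igraph::graph_from_data_frame(sub[, c("node_a", "node_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    deg <- igraph::degree(g)
    members <- split(names(comp$membership), comp$membership)
    members <- lapply(members, sort)
    members <- members[order(-vapply(members, length, integer(1L)),
                             vapply(members, `[[`, character(1L), 1L))]
    names(members) <- NULL
    hubs <- vapply(members, function(nodes) {
      dd <- deg[nodes]
      sort(names(dd)[dd == max(dd)])[[1L]]
    }, character(1L))
    connected <- unique(c(sub$node_a, sub$node_b))
  } else {
    members <- list()
    hubs <- character(0)
    deg <- stats::setNames(integer(0), character(0))
    connected <- character(0)
  }
  structure(list(edges = sub, components = members, hubs = hubs,
                 degree = deg[order(names(deg))],
                 isolated = sort(setdiff(genes, connected))),
            class = "subnetwork_report")
}

#' @export
print.subnetwork_report <- function(x, ...) {
  cat("subnetwork_report: ", length(x$components), " component(s), ",
      nrow(x$edges), " edge(s), ", length(x$isolated),
      " isolated gene(s)\n", sep = "")
  for (i in seq_along(x$components))
    cat("  component ", i, ": ", length(x$components[[i]]),
        " nodes, hub ", x$hubs[[i]], " (degree ",
        x$degree[[x$hubs[[i]]]], ")\n", sep = "")
  invisible(x)
}

#' Write a subnetwork report as an edge table
#' @param report A `subnetwork_report`.
#' @param path Output TSV path (columns node_a, node_b, confidence,
#'   component).
#' @return Invisibly, the data frame written.
#' @export
write_subnetwork <- function(report, path) {
  comp_of <- stats::setNames(
    rep(seq_along(report$components),
        vapply(report$components, length, integer(1L))),
    unlist(report$components))
  df <- report$edges
  df$component <- if (nrow(df)) unname(comp_of[df$node_a]) else integer(0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
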