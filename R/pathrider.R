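#' Remove excluded biomolecules from a graph
#'
#' Given a list of excluded gene symbols (typically genes whose expression
#' is undetectable), removes for each symbol X the nodes `X_gen`, `X_prot`,
#' every complex having `X_prot` as member, and all incident edges.
#' Symbols absent from the graph are ignored (and counted in the returned
#' attribute).
#'
#' @param graph a [signed_graph()].
#' @param excluded_genes character vector of gene symbols.
#' @return the filtered [signed_graph()], with attributes `removed_nodes`
#'   and `absent_symbols`.
#' @export
filter_excluded <- function(graph, excluded_genes) {
  excluded_genes <- trimws(as.character(excluded_genes))
  excluded_genes <- excluded_genes[nzchar(excluded_genes)]
  if (!length(excluded_genes)) {
    attr(graph, "removed_nodes") <- character(0)
    attr(graph, "absent_symbols") <- character(0)
    return(graph)
  }
  hit_prot <- paste0(excluded_genes, "_prot")
  hit <- c(paste0(excluded_genes, "_gen"), hit_prot)
  cx <- graph$nodes$id[graph$nodes$kind == "complex"]
  cx_hit <- cx[vapply(cx, function(id) {
    any(complex_members(id) %in% hit_prot)
  }, logical(1))]
  drop <- intersect(c(hit, cx_hit), graph$nodes$id)
  keep <- setdiff(graph$nodes$id, drop)
  e <- graph$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  out <- signed_graph(e, nodes = keep)
  attr(out, "removed_nodes") <- drop
  attr(out, "absent_symbols") <-
    excluded_genes[!(paste0(excluded_genes, "_gen") %in% graph$nodes$id |
                     paste0(excluded_genes, "_prot") %in% graph$nodes$id)]
  out
}

#' Extract the upstream regulatory subgraph of a gene list
#'
#' Keeps the nodes that can reach (by a directed path) a gene node of the
#' target list, i.e. the upstream signaling and regulatory events of those
#' genes. Seeds are gene nodes only: target symbol T seeds `T_gen` when
#' present. The result is the subgraph induced by the seeds plus all their
#' ancestors; every edge between two kept nodes lies on a path to a seed,
#' so induced and path-only semantics coincide here.
#'
#' @param graph a [signed_graph()].
#' @param targets non-empty character vector of gene symbols.
#' @param downstream also include the forward closure (descendants of the
#'   seeds); off by default.
#' @return a [signed_graph()] with attribute `matched_targets`, the target
#'   symbols whose gene node was found.
#' @export
upstream_subgraph <- function(graph, targets, downstream = FALSE) {
  targets <- trimws(as.character(targets))
  targets <- unique(targets[nzchar(targets)])
  if (!length(targets)) stop("targets must be non-empty", call. = FALSE)
  seeds <- paste0(targets, "_gen")
  matched <- targets[seeds %in% graph$nodes$id]
  seeds <- intersect(seeds, graph$nodes$id)
  if (!length(seeds)) {
    stop("no target symbol matches a gene node in the graph",
         call. = FALSE)
  }
  ig <- as_igraph(graph)
  keep <- unique(unlist(lapply(seeds, function(s) {
    names(igraph::subcomponent(ig, s, mode = "in"))
  })))
  if (downstream) {
    keep <- unique(c(keep, unlist(lapply(seeds, function(s) {
      names(igraph::subcomponent(ig, s, mode = "out"))
    }))))
  }
  e <- graph$edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  out <- signed_graph(e, nodes = keep)
  attr(out, "matched_targets") <- matched
  out
}
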