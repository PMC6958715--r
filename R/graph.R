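#' Signed interaction graph
#'
#' A `signed_graph` is a directed graph whose nodes are genes, proteins or
#' protein complexes and whose edges carry a sign (`"+"` activation or
#' `"-"` inhibition) and a relation type (`PPrel` protein-protein, `GErel`
#' transcription-factor to gene, `GPrel` gene to its protein product, or
#' `other`). Parallel edges with identical (source, target, sign) are
#' deduplicated; a duplicate with a different sign is kept, so a pair of
#' nodes can be linked by at most one `"+"` and one `"-"` edge.
#'
#' @param edges data.frame with columns `from`, `to`, `sign` and optionally
#'   `relation`. Signs are parsed with [as_sign()] and must not be `"0"`.
#' @param nodes optional character vector of node ids; endpoints of `edges`
#'   are always included. Use this to add isolated nodes.
#' @return an object of class `signed_graph`: a list with data.frames
#'   `nodes` (`id`, `kind`) and `edges` (`from`, `to`, `sign`, `relation`).
#' @examples
#' g <- signed_graph(data.frame(from = "A_prot", to = "B_gen", sign = "+",
#'                              relation = "GErel"))
#' g
#' @export
signed_graph <- function(edges = NULL, nodes = character(0)) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        sign = character(0), relation = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to", "sign") %in% names(edges))) {
      stop("edges need columns from, to, sign", call. = FALSE)
    }
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$sign <- as_sign(edges$sign)
    if (any(edges$sign == "0")) {
      stop("edge signs must be \"+\" or \"-\"", call. = FALSE)
    }
    if (is.null(edges$relation)) {
      edges$relation <- infer_relation(edges$from, edges$to)
    }
    edges <- edges[, c("from", "to", "sign", "relation")]
    edges <- edges[!duplicated(edges[, c("from", "to", "sign")]), ,
                   drop = FALSE]
  }
  ids <- sort(unique(c(nodes, edges$from, edges$to)))
  if (any(grepl("[[:space:]]", ids))) {
    stop("node ids must not contain whitespace", call. = FALSE)
  }
  nodes_df <- data.frame(id = ids,
                         kind = if (length(ids)) node_kind_of(ids)
                                else character(0),
                         stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes_df, edges = edges), class = "signed_graph")
}

# relation type implied by endpoint kinds (used when SIF input carries only
# the sign): gene -> protein is GPrel, anything -> gene is GErel, the rest
# among proteins/complexes is PPrel
infer_relation <- function(from, to) {
  fk <- if (length(from)) node_kind_of(from) else character(0)
  tk <- if (length(to)) node_kind_of(to) else character(0)
  rel <- rep("other", length(from))
  rel[fk == "gene" & tk == "protein"] <- "GPrel"
  rel[tk == "gene"] <- "GErel"
  rel[fk %in% c("protein", "complex") & tk %in% c("protein", "complex")] <-
    "PPrel"
  rel
}

#' @export
print.signed_graph <- function(x, ...) {
  cat("signed_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  kinds <- table(x$nodes$kind)
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n")
  if (nrow(x$edges)) {
    signs <- table(x$edges$sign)
    cat("  signs:", paste(names(signs), signs, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
format.signed_graph <- function(x, ...) {
  paste0("signed_graph<", nrow(x$nodes), "n,", nrow(x$edges), "e>")
}

#' Number of nodes and edges
#' @param graph a [signed_graph()].
#' @return integer count.
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Incoming edges of a node
#'
#' @param graph a [signed_graph()].
#' @param id a node id present in the graph.
#' @return the rows of `graph$edges` whose target is `id`.
#' @export
in_edges <- function(graph, id) {
  stopifnot(id %in% graph$nodes$id)
  graph$edges[graph$edges$to == id, , drop = FALSE]
}

# convert to igraph (for reachability / component queries)
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

#' Read and write signed graphs in SIF
#'
#' One edge per line, three whitespace-separated columns
#' `source relation target`. Accepted relation tokens: `1`, `activation`,
#' `+` for activation; `-1`, `inhibition`, `-` (or the Unicode minus) for
#' inhibition. Lines starting with `#` are comments. The writer emits `1`
#' and `-1`. Relation types (PPrel/GErel/GPrel) are not part of SIF; on
#' read they are inferred from the endpoint kinds, which round-trips all
#' graphs produced by this package.
#'
#' @param path file path.
#' @return `read_sif()` returns a [signed_graph()].
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  iso <- sub("^#node[[:space:]]+", "",
             lines[grepl("^#node[[:space:]]+\\S+$", lines)])
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(signed_graph(nodes = iso))
  parts <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf != 3)) {
    stop("malformed SIF line (expected 3 columns): ",
         lines[which(nf != 3)[1]], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  rel <- m[, 2]
  sign <- rep(NA_character_, length(rel))
  sign[rel %in% c("1", "activation", "+")] <- "+"
  sign[rel %in% c("-1", "inhibition", "-", "−")] <- "-"
  if (anyNA(sign)) {
    stop("unknown SIF relation token: ", rel[which(is.na(sign))[1]],
         call. = FALSE)
  }
  signed_graph(data.frame(from = m[, 1], to = m[, 3], sign = sign,
                          stringsAsFactors = FALSE), nodes = iso)
}

#' @rdname read_sif
#' @param graph a [signed_graph()] to write.
#' @export
write_sif <- function(graph, path) {
  e <- graph$edges
  lines <- character(0)
  if (nrow(e)) {
    lines <- paste(e$from, ifelse(e$sign == "+", "1", "-1"), e$to)
  }
  iso <- setdiff(graph$nodes$id, c(e$from, e$to))
  if (length(iso)) {
    lines <- c(lines, paste("#node", iso))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Node annotation table
#'
#' @param graph a [signed_graph()].
#' @return data.frame with columns `id`, `kind` and `display` (complex
#'   display names strip the `_prot` member suffixes).
#' @export
node_table <- function(graph) {
  data.frame(id = graph$nodes$id, kind = graph$nodes$kind,
             display = ifelse(graph$nodes$kind == "complex",
                              complex_display_name(graph$nodes$id),
                              graph$nodes$id),
             stringsAsFactors = FALSE)
}
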