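# shared helpers: graph shorthand, the brute-force prediction oracle, and
# an in-code KGML fixture builder

# edges given as triples: from, sign, to
make_graph <- function(..., nodes = character(0)) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  signed_graph(data.frame(from = m[, 1], to = m[, 3], sign = m[, 2],
                          stringsAsFactors = FALSE), nodes = nodes)
}

# independent oracle: exhaustive enumeration + the pred definition.
# Returns NULL when inconsistent; otherwise a named vector with the
# consensual sign per node (NA = undecided).
oracle_predict <- function(graph, obs = character(0),
                           repaired = character(0)) {
  M <- enumerate_consistent(graph, obs, repaired)
  if (nrow(M) == 0) return(NULL)
  apply(M, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1) u else NA_character_
  })
}

# random test instance: graph plus random gene-node observations
random_instance <- function(trial, n_genes = sample(2:5, 1),
                            density = runif(1, 0.1, 0.5),
                            inhibition = 0.3, n_obs = NULL) {
  g <- random_signed_graph(n_genes, edge_density = density,
                           inhibition_fraction = inhibition, seed = trial)
  genes <- g$nodes$id[g$nodes$kind == "gene"]
  if (is.null(n_obs)) n_obs <- sample(0:min(3, length(genes)), 1)
  n_obs <- min(n_obs, length(genes))
  obs <- if (n_obs > 0) {
    stats::setNames(sample(c("+", "-"), n_obs, replace = TRUE),
                    genes[sample.int(length(genes), n_obs)])
  } else {
    character(0)
  }
  list(graph = g, obs = obs)
}

# minimal KGML document; entries is a list of lists with id, type, name
# (graphics label), components; relations a list with entry1, entry2,
# type, subtypes
kgml_doc <- function(entries, relations = list()) {
  ent <- vapply(entries, function(e) {
    comp <- if (!is.null(e$components)) {
      paste0(sprintf('<component id="%s"/>', e$components), collapse = "")
    } else ""
    gfx <- if (!is.null(e$name)) {
      sprintf('<graphics name="%s" type="rectangle"/>', e$name)
    } else ""
    sprintf('<entry id="%s" name="%s" type="%s">%s%s</entry>',
            e$id, if (is.null(e$kegg)) paste0("hsa:", e$id) else e$kegg,
            e$type, gfx, comp)
  }, character(1))
  rel <- vapply(relations, function(r) {
    st <- if (length(r$subtypes)) {
      paste0(sprintf('<subtype name="%s" value="--&gt;"/>', r$subtypes),
             collapse = "")
    } else ""
    sprintf('<relation entry1="%s" entry2="%s" type="%s">%s</relation>',
            r$entry1, r$entry2, r$type, st)
  }, character(1))
  paste0('<?xml version="1.0"?><pathway name="path:test" org="hsa" number="1">',
         paste0(ent, collapse = ""), paste0(rel, collapse = ""),
         "</pathway>")
}

write_kgml <- function(doc, path = tempfile(fileext = ".xml")) {
  writeLines(doc, path)
  path
}
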