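# Synthetic inputs with the structural properties the pipeline assumes:
# gene/protein node pairs joined by GPrel edges, signed PPrel/GErel wiring,
# complexes wired from their members, planted consistent labelings, and
# partial gene-level revelation of observations.

#' Random signed interaction graph
#'
#' Generates `n_genes` gene/protein pairs (each protein receiving its
#' plus-signed GPrel formation edge), random plus/minus PPrel edges among
#' proteins and GErel edges from proteins to genes, and `complex_count`
#' complexes wired from two random member proteins. The default inhibition
#' fraction of 0.153 emulates the activation-dominated composition of
#' curated signaling knowledge (roughly 2,110 inhibitions among 13,771
#' interactions).
#'
#' @param n_genes number of gene/protein pairs (>= 2).
#' @param edge_density probability in (0, 1] of each candidate regulatory
#'   edge (protein -> other protein, and protein -> other gene).
#' @param inhibition_fraction probability in [0, 1) that a regulatory edge
#'   is minus-signed.
#' @param complex_count number of two-member complexes to add.
#' @param gerel_density probability of each candidate GErel edge; defaults
#'   to `edge_density / 2`.
#' @param seed integer seed; equal seeds give identical graphs.
#' @return a [signed_graph()].
#' @export
random_signed_graph <- function(n_genes, edge_density = 0.15,
                                inhibition_fraction = 0.153,
                                complex_count = 0,
                                gerel_density = edge_density / 2,
                                seed = 1) {
  stopifnot(n_genes >= 2, edge_density > 0, edge_density <= 1,
            inhibition_fraction >= 0, inhibition_fraction < 1)
  set.seed(as.integer(seed))
  syms <- sprintf("G%02d", seq_len(n_genes))
  prot <- paste0(syms, "_prot")
  gen <- paste0(syms, "_gen")
  pairs <- expand.grid(i = seq_len(n_genes), j = seq_len(n_genes))
  pairs <- pairs[pairs$i != pairs$j, ]
  pp <- pairs[stats::runif(nrow(pairs)) < edge_density, ]
  ge <- pairs[stats::runif(nrow(pairs)) < gerel_density, ]
  ef <- c(prot[pp$i], prot[ge$i])
  et <- c(prot[pp$j], gen[ge$j])
  er <- c(rep("PPrel", nrow(pp)), rep("GErel", nrow(ge)))
  es <- ifelse(stats::runif(length(ef)) < inhibition_fraction, "-", "+")
  edges <- data.frame(from = ef, to = et, sign = es, relation = er,
                      stringsAsFactors = FALSE)
  if (complex_count > 0) {
    for (k in seq_len(complex_count)) {
      mem <- sample(syms, 2)
      cx <- complex_id(mem)
      edges <- rbind(edges,
                     data.frame(from = paste0(sort(mem), "_prot"),
                                to = cx, sign = "+", relation = "PPrel",
                                stringsAsFactors = FALSE))
    }
  }
  add_gprel(signed_graph(edges, nodes = c(prot, gen)))
}

#' Plant a consistent total labeling on a graph
#'
#' Assigns free signs to in-degree-0 nodes and propagates justifiable
#' signs along a topological-ish order, with bounded rejection-resampling;
#' when cycles defeat the greedy pass, a randomized run of the constraint
#' solver (sources still fixed to random free signs) samples a labeling
#' directly. The result always satisfies [is_consistent_labeling()] with
#' no observations and no repairs.
#'
#' @param graph a [signed_graph()].
#' @param seed integer seed.
#' @param max_tries greedy/resampling budget (default 100).
#' @return named sign vector over all nodes.
#' @export
plant_consistent_labeling <- function(graph, seed = 1, max_tries = 100) {
  inst <- sc_compile(graph)
  ids <- inst$ids
  n <- inst$n
  ig <- as_igraph(graph)
  ord <- tryCatch(match(igraph::topo_sort(ig, mode = "out")$name, ids),
                  warning = function(w) seq_len(n),
                  error = function(e) seq_len(n))
  if (anyNA(ord) || length(ord) < n) ord <- seq_len(n)
  set.seed(as.integer(seed))
  greedy_tries <- max(1L, min(max_tries, 10L))
  for (try in seq_len(greedy_tries)) {
    a <- rep(NA_integer_, n)
    for (i in ord) {
      pr <- inst$preds[[i]]
      if (!length(pr$p)) {
        a[i] <- sample(c(-1L, 0L, 1L), 1)
        next
      }
      infl <- a[pr$p] * pr$e  # NA for not-yet-assigned (back) edges
      known <- infl[!is.na(infl)]
      choices <- integer(0)
      if (any(known == 1L)) choices <- c(choices, 1L)
      if (any(known == -1L)) choices <- c(choices, -1L)
      if (!length(known) || all(known == 0L) ||
          (any(known == 1L) && any(known == -1L))) {
        choices <- c(choices, 0L)
      }
      if (!length(choices)) choices <- 0L
      a[i] <- if (length(choices) == 1) choices else sample(choices, 1)
    }
    lab <- stats::setNames(int_to_sign(a), ids)
    if (is_consistent_labeling(graph, lab)) return(lab)
  }
  # cycles defeated the greedy pass: sample via the solver, re-rolling the
  # free source signs each attempt
  constrained <- sc_constrained(inst)
  sources <- which(inst$indeg == 0L)
  for (try in seq_len(max_tries)) {
    dom <- sc_root_domains(inst)
    for (i in sources) dom[i] <- sample(c(SC_NEG, SC_ZERO, SC_POS), 1)
    a <- sc_search(inst, dom, constrained, shuffle = TRUE)
    if (!is.null(a)) return(stats::setNames(int_to_sign(a), ids))
  }
  stop("failed to plant a consistent labeling after ", max_tries,
       " tries on a graph with ", n, " nodes", call. = FALSE)
}

#' Reveal part of a planted labeling as observations
#'
#' Samples observations from the non-zero-labeled nodes of a (typically
#' planted) total labeling, at a given percentage; by default only gene
#' nodes are eligible, mimicking expression data where only gene-level
#' shifts are measured.
#'
#' @param labeling named sign vector over all nodes.
#' @param graph the companion [signed_graph()].
#' @param fraction percentage in (0, 100].
#' @param genes_only restrict to gene nodes (default `TRUE`).
#' @param seed integer seed.
#' @return named sign vector usable as observations.
#' @export
reveal_observations <- function(labeling, graph, fraction = 50,
                                genes_only = TRUE, seed = 1) {
  stopifnot(fraction > 0, fraction <= 100)
  eligible <- names(labeling)[labeling != "0"]
  if (genes_only) {
    eligible <- intersect(eligible,
                          graph$nodes$id[graph$nodes$kind == "gene"])
  }
  if (!length(eligible)) {
    stop("no eligible (non-zero", if (genes_only) ", gene" else "",
         ") nodes to reveal", call. = FALSE)
  }
  set.seed(as.integer(seed))
  k <- max(1L, round_half_up(fraction / 100 * length(eligible)))
  labeling[sort(sample(eligible, k))]
}

#' Bundled toy fixtures
#'
#' A named library of small graphs with observations, covering the motifs
#' the consistency semantics is usually explained with: a two-source /
#' two-sink motif in a consistent and an inconsistent variant (with two
#' free nodes, hence a 3^2 candidate labeling space), a chain, an
#' inhibitor chain, a fork with contradictory influences, an upstream
#' cycle, a complex-membership toy, and a hub-contradiction motif where
#' one "+" observation conflicts with three "-" observations through a
#' shared unobserved regulator (minimal repair of size 1).
#'
#' @return named list; each element has `graph`, `observations` and a
#'   `comment`.
#' @export
fixture_library <- function() {
  ed <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(from = m[, 1], to = m[, 3], sign = m[, 2],
               stringsAsFactors = FALSE)
  }
  list(
    motif_consistent = list(
      graph = signed_graph(ed("A_prot", "+", "C_prot",
                              "B_prot", "-", "C_prot",
                              "B_prot", "+", "D_prot")),
      observations = c(A_prot = "+", B_prot = "-"),
      comment = "two sources, two sinks; free nodes C and D"),
    motif_inconsistent = list(
      graph = signed_graph(ed("A_prot", "+", "C_prot",
                              "B_prot", "-", "C_prot",
                              "B_prot", "+", "D_prot")),
      observations = c(A_prot = "+", B_prot = "-", C_prot = "-"),
      comment = "same motif; C's observation cannot be justified"),
    chain = list(
      graph = signed_graph(ed("A_prot", "+", "B_prot",
                              "B_prot", "+", "C_prot")),
      observations = c(A_prot = "+"),
      comment = "activation chain"),
    inhibitor_chain = list(
      graph = signed_graph(ed("A_prot", "-", "B_prot")),
      observations = c(A_prot = "+"),
      comment = "single inhibition"),
    fork = list(
      graph = signed_graph(ed("A_prot", "+", "C_prot",
                              "B_prot", "-", "C_prot")),
      observations = c(A_prot = "+", B_prot = "+"),
      comment = "contradictory influences leave C undecided"),
    cycle = list(
      graph = signed_graph(ed("A_prot", "+", "B_prot",
                              "B_prot", "+", "A_prot",
                              "B_prot", "+", "T_gen")),
      observations = c(T_gen = "+"),
      comment = "upstream cycle feeding an observed gene"),
    complex_toy = list(
      graph = signed_graph(ed("A_gen", "+", "A_prot",
                              "B_gen", "+", "B_prot",
                              "A_prot", "+", "A_prot::B_prot",
                              "B_prot", "+", "A_prot::B_prot",
                              "A_prot::B_prot", "+", "T_gen")),
      observations = c(A_gen = "+", B_gen = "+", T_gen = "+"),
      comment = "complex formed from two members, regulating a gene"),
    hub_contradiction = list(
      graph = signed_graph(ed("HUB_prot", "+", "P_gen",
                              "HUB_prot", "+", "Q1_gen",
                              "HUB_prot", "+", "Q2_gen",
                              "HUB_prot", "+", "Q3_gen",
                              "P_gen", "+", "P_prot")),
      observations = c(P_gen = "+", Q1_gen = "-", Q2_gen = "-",
                       Q3_gen = "-"),
      comment = paste("one + observation against three - observations",
                      "through a shared regulator; repair size 1"))
  )
}
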