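# Sign-consistency inference core.
#
# A total labeling mu: V -> {+,-,0} is consistent with a signed graph and
# observations when
#   (1) observed nodes keep their observed sign,
#   (2) every node labeled + or - receives at least one influence of that
#       sign from a predecessor (influence = predecessor label x edge sign),
#   (3) every node labeled 0 receives only zero influences, or at least one
#       + and one - influence from two distinct predecessors.
# Nodes with no predecessors, and nodes in the repair set (modeled as
# having one artificial predecessor of unconstrained sign), are exempt from
# rules (2)-(3); rule (1) always binds.
#
# The production solver is a three-valued constraint search: domains over
# {-1,0,+1} per node, arc-style propagation of the justification rules to a
# fixpoint, then backtracking with minimum-remaining-values ordering.
# Predictions are entailment queries against this solver; the brute-force
# enumerator below doubles as the independent oracle in the test suite.

# ---- compiled instance ----------------------------------------------------

# Precompute predecessor lists in integer form. `observations` is a named
# sign vector on node ids; `repaired` a character vector of exempt nodes.
sc_compile <- function(graph, observations = NULL) {
  ids <- graph$nodes$id
  n <- length(ids)
  e <- graph$edges
  pto <- match(e$to, ids)
  pfrom <- match(e$from, ids)
  esign <- ifelse(e$sign == "+", 1L, -1L)
  preds <- vector("list", n)
  for (i in seq_len(n)) preds[[i]] <- list(p = integer(0), e = integer(0))
  if (length(pto)) {
    ord <- order(pto)
    split_idx <- split(ord, pto[ord])
    for (k in names(split_idx)) {
      i <- as.integer(k)
      preds[[i]] <- list(p = pfrom[split_idx[[k]]],
                         e = esign[split_idx[[k]]])
    }
  }
  fixed <- rep(NA_integer_, n)
  if (length(observations)) {
    miss <- setdiff(names(observations), ids)
    if (length(miss)) {
      stop("observed node(s) not in graph: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    fixed[match(names(observations), ids)] <- sign_to_int(observations)
  }
  list(ids = ids, n = n, preds = preds,
       indeg = lengths(lapply(preds, `[[`, "p")), fixed = fixed)
}

sc_constrained <- function(inst, repaired = character(0)) {
  inst$indeg > 0 & !(inst$ids %in% repaired)
}

# Domains are bitmasks over {-1, 0, +1}: bit 1 = "-", bit 2 = "0",
# bit 4 = "+". SC_SWAP negates a producible-value mask (an inhibiting edge
# swaps the +/- bits); SC_POP is the population count.
SC_NEG <- 1L; SC_ZERO <- 2L; SC_POS <- 4L; SC_FULL <- 7L
SC_SWAP <- c(0L, 4L, 2L, 6L, 1L, 5L, 3L, 7L)  # index by mask + 1
SC_POP <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L)
SC_MASK_OF_INT <- function(v) c(1L, 2L, 4L)[v + 2L]    # -1/0/1 -> mask
SC_INT_OF_MASK <- c(-1L, 0L, NA, 1L, NA, NA, NA)       # index by mask

sc_root_domains <- function(inst) {
  dom <- rep(SC_FULL, inst$n)
  obs <- which(!is.na(inst$fixed))
  dom[obs] <- SC_MASK_OF_INT(inst$fixed[obs])
  dom
}

# exact rule check for one node under a full integer assignment
sc_node_ok <- function(inst, i, a) {
  pr <- inst$preds[[i]]
  infl <- a[pr$p] * pr$e
  s <- a[i]
  if (s == 1L) return(any(infl == 1L))
  if (s == -1L) return(any(infl == -1L))
  all(infl == 0L) || (any(infl == 1L) && any(infl == -1L))
}

sc_check_total <- function(inst, a, constrained) {
  for (i in which(constrained)) {
    if (!sc_node_ok(inst, i, a)) return(FALSE)
  }
  obs <- which(!is.na(inst$fixed))
  all(a[obs] == inst$fixed[obs])
}

# ---- propagation + search -------------------------------------------------

# Prune bitmask domains to a fixpoint; returns the pruned domain vector or
# NULL on wipe-out. Sound: only removes values that occur in no consistent
# total labeling extending the current domains.
sc_propagate <- function(inst, dom, constrained) {
  cns <- which(constrained)
  preds <- inst$preds
  repeat {
    changed <- FALSE
    for (i in cns) {
      pr <- preds[[i]]
      d <- dom[pr$p]
      neg_edge <- pr$e == -1L
      prod <- d
      if (any(neg_edge)) prod[neg_edge] <- SC_SWAP[d[neg_edge] + 1L]
      can_pos <- bitwAnd(prod, SC_POS) > 0L
      can_neg <- bitwAnd(prod, SC_NEG) > 0L
      npos <- sum(can_pos)
      nneg <- sum(can_neg)
      couple_ok <- npos > 0L && nneg > 0L &&
        !(npos == 1L && nneg == 1L && which(can_pos) == which(can_neg))
      all_zero <- all(bitwAnd(prod, SC_ZERO) > 0L)
      allowed <- (if (nneg > 0L) SC_NEG else 0L) +
        (if (all_zero || couple_ok) SC_ZERO else 0L) +
        (if (npos > 0L) SC_POS else 0L)
      nd <- bitwAnd(dom[i], allowed)
      if (nd == 0L) return(NULL)
      if (nd != dom[i]) {
        dom[i] <- nd
        changed <- TRUE
      }
      if (nd == SC_POS && npos == 1L) {
        j <- which(can_pos)
        need <- if (neg_edge[j]) SC_NEG else SC_POS
        nv <- bitwAnd(dom[pr$p[j]], need)
        if (nv == 0L) return(NULL)
        if (nv != dom[pr$p[j]]) {
          dom[pr$p[j]] <- nv
          changed <- TRUE
        }
      } else if (nd == SC_NEG && nneg == 1L) {
        j <- which(can_neg)
        need <- if (neg_edge[j]) SC_POS else SC_NEG
        nv <- bitwAnd(dom[pr$p[j]], need)
        if (nv == 0L) return(NULL)
        if (nv != dom[pr$p[j]]) {
          dom[pr$p[j]] <- nv
          changed <- TRUE
        }
      } else if (nd == SC_ZERO) {
        if (!all_zero && couple_ok) {
          if (npos == 1L) {
            j <- which(can_pos)
            need <- if (neg_edge[j]) SC_NEG else SC_POS
            nv <- bitwAnd(dom[pr$p[j]], need)
            if (nv == 0L) return(NULL)
            if (nv != dom[pr$p[j]]) {
              dom[pr$p[j]] <- nv
              changed <- TRUE
            }
          }
          if (nneg == 1L) {
            j <- which(can_neg)
            need <- if (neg_edge[j]) SC_POS else SC_NEG
            nv <- bitwAnd(dom[pr$p[j]], need)
            if (nv == 0L) return(NULL)
            if (nv != dom[pr$p[j]]) {
              dom[pr$p[j]] <- nv
              changed <- TRUE
            }
          }
        } else if (!couple_ok && all_zero) {
          nv <- bitwAnd(dom[pr$p], SC_ZERO)
          if (any(nv == 0L)) return(NULL)
          if (any(nv != dom[pr$p])) {
            dom[pr$p] <- nv
            changed <- TRUE
          }
        } else if (!couple_ok && !all_zero) {
          return(NULL)
        }
      }
    }
    if (!changed) break
  }
  dom
}

# Backtracking search for one consistent total labeling (integer vector
# over -1/0/1); NULL if none. With shuffle = TRUE the variable and value
# orders are randomized (used by the synthetic planting to sample varied
# labelings); callers control the RNG state.
sc_search <- function(inst, dom, constrained, shuffle = FALSE) {
  dom <- sc_propagate(inst, dom, constrained)
  if (is.null(dom)) return(NULL)
  sizes <- SC_POP[dom + 1L]
  if (all(sizes == 1L)) {
    a <- SC_INT_OF_MASK[dom]
    if (sc_check_total(inst, a, constrained)) return(a)
    return(NULL)
  }
  open <- which(sizes > 1L)
  if (shuffle) open <- open[sample.int(length(open))]
  i <- open[which.min(sizes[open])]
  vals <- c(SC_NEG, SC_ZERO, SC_POS)
  vals <- vals[bitwAnd(dom[i], vals) > 0L]
  if (shuffle) vals <- vals[sample.int(length(vals))]
  for (v in vals) {
    d2 <- dom
    d2[i] <- v
    r <- sc_search(inst, d2, constrained, shuffle)
    if (!is.null(r)) return(r)
  }
  NULL
}

sc_satisfiable <- function(inst, repaired = character(0)) {
  sc_search(inst, sc_root_domains(inst), sc_constrained(inst, repaired))
}

# ---- public surface -------------------------------------------------------

#' Check a total labeling against the sign-consistency rules
#'
#' @param graph a [signed_graph()].
#' @param labeling named sign vector covering every node of the graph.
#' @param observations named sign vector (node id -> sign), possibly empty.
#' @param repaired character vector of node ids exempted from the
#'   justification rules (each stands for one added artificial influence
#'   toward that node).
#' @return `TRUE` iff the labeling satisfies all three constraints.
#' @export
is_consistent_labeling <- function(graph, labeling,
                                   observations = character(0),
                                   repaired = character(0)) {
  ids <- graph$nodes$id
  if (!setequal(names(labeling), ids)) {
    stop("labeling must be total over the graph's nodes", call. = FALSE)
  }
  inst <- sc_compile(graph, observations)
  a <- sign_to_int(labeling[ids])
  sc_check_total(inst, a, sc_constrained(inst, repaired))
}

#' Enumerate all consistent total labelings (exhaustive)
#'
#' Brute-force enumeration over the 3^k candidate labelings of the k
#' unobserved nodes, filtered by the consistency rules. Intended as an
#' exact reference on small graphs; the bound guards against accidental
#' blow-up.
#'
#' @inheritParams is_consistent_labeling
#' @param bound maximum node count accepted (default 12).
#' @return a character matrix, one row per consistent labeling, columns
#'   named by node id; zero rows signal inconsistency.
#' @export
enumerate_consistent <- function(graph, observations = character(0),
                                 repaired = character(0), bound = 12) {
  ids <- graph$nodes$id
  n <- length(ids)
  if (n > bound) {
    stop("graph has ", n, " nodes; exhaustive bound is ", bound,
         call. = FALSE)
  }
  inst <- sc_compile(graph, observations)
  free <- which(is.na(inst$fixed))
  grids <- rep(list(c(-1L, 0L, 1L)), length(free))
  A <- matrix(0L, nrow = max(1L, 3L^length(free)), ncol = n)
  if (length(free)) {
    A[, free] <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  }
  fixed_cols <- which(!is.na(inst$fixed))
  for (i in fixed_cols) A[, i] <- inst$fixed[i]
  ok <- rep(TRUE, nrow(A))
  for (i in which(sc_constrained(inst, repaired))) {
    pr <- inst$preds[[i]]
    infl <- sweep(A[, pr$p, drop = FALSE], 2, pr$e, `*`)
    pos <- rowSums(infl == 1L) > 0
    neg <- rowSums(infl == -1L) > 0
    s <- A[, i]
    ok <- ok & ((s == 1L & pos) | (s == -1L & neg) |
                  (s == 0L & ((!pos & !neg & rowSums(infl != 0L) == 0) |
                                (pos & neg))))
  }
  out <- matrix(int_to_sign(A[ok, , drop = FALSE]), ncol = n,
                dimnames = list(NULL, ids))
  out
}

#' Minimal correction sets
#'
#' When the observations contradict the graph, consistency can be restored
#' by adding artificial influences toward some nodes (exempting them from
#' the justification rules). `mcos()` searches by increasing cardinality
#' k = 0, 1, ... and collects every node set of the first satisfiable size.
#'
#' @inheritParams is_consistent_labeling
#' @param max_k cardinality cap for the repair search (default 3).
#' @return list with `k` (minimal repair size) and `repair_sets` (list of
#'   character vectors; a single empty set when already consistent).
#' @export
mcos <- function(graph, observations = character(0), max_k = 3) {
  inst <- sc_compile(graph, observations)
  if (!is.null(sc_satisfiable(inst))) {
    return(list(k = 0L, repair_sets = list(character(0))))
  }
  # only nodes with predecessors can change status under exemption
  cand <- inst$ids[inst$indeg > 0]
  for (k in seq_len(max_k)) {
    if (length(cand) < k) break
    sets <- utils::combn(cand, k, simplify = FALSE)
    hits <- Filter(function(s) !is.null(sc_satisfiable(inst, repaired = s)),
                   sets)
    if (length(hits)) return(list(k = k, repair_sets = hits))
  }
  stop("no repair of size <= ", max_k, " restores consistency", call. = FALSE)
}

# achievable signs per node for one repair scenario, by entailment queries
# with witness reuse: every found labeling certifies one sign per node.
sc_possible_signs <- function(inst, repaired) {
  constrained <- sc_constrained(inst, repaired)
  dom0 <- sc_propagate(inst, sc_root_domains(inst), constrained)
  if (is.null(dom0)) return(NULL)
  sol <- sc_search(inst, dom0, constrained)
  if (is.null(sol)) return(NULL)
  # possible[i]: bitmask of witnessed signs; every found labeling certifies
  # one sign per node, so successful queries resolve many nodes at once
  possible <- SC_MASK_OF_INT(sol)
  for (i in seq_len(inst$n)) {
    open <- bitwAnd(dom0[i], bitwNot(possible[i]))
    for (v in c(SC_NEG, SC_ZERO, SC_POS)) {
      if (bitwAnd(open, v) == 0L) next
      d2 <- dom0
      d2[i] <- v
      w <- sc_search(inst, d2, constrained)
      if (!is.null(w)) {
        possible <- bitwOr(possible, SC_MASK_OF_INT(w))
      }
    }
  }
  possible
}

#' Sign predictions for unmeasured biomolecules
#'
#' Computes the minimal correction sets, then for each repair scenario the
#' prediction function pred(x): a node is predicted sign s iff every
#' consistent total labeling of that scenario assigns it s; nodes the
#' labelings disagree on are undecided. Scenarios are combined by union: a
#' node keeps sign s iff at least one scenario predicts s and no scenario
#' predicts a different sign. Observed nodes are excluded from the report.
#'
#' @inheritParams mcos
#' @return a `prediction_map`: list with `predictions` (data.frame `node`,
#'   `kind`, `sign`), `undecided` (node ids with no consensual sign),
#'   `breakdown` (sign x kind counts) and `mcos` (the repair report).
#' @export
predict_signs <- function(graph, observations = character(0), max_k = 3) {
  rep_report <- mcos(graph, observations, max_k = max_k)
  inst <- sc_compile(graph, observations)
  per_scenario <- lapply(rep_report$repair_sets, function(r) {
    poss <- sc_possible_signs(inst, r)
    if (is.null(poss)) {
      stop("internal error: repair set does not restore satisfiability",
           call. = FALSE)
    }
    SC_INT_OF_MASK[poss]  # NA where several signs are achievable
  })
  pred_mat <- do.call(cbind, per_scenario)
  combined <- apply(pred_mat, 1, function(row) {
    s <- unique(row[!is.na(row)])
    if (length(s) == 1L) s else NA_integer_
  })
  unobserved <- is.na(inst$fixed)
  ids <- inst$ids
  decided <- unobserved & !is.na(combined)
  predictions <- data.frame(node = ids[decided],
                            kind = node_kind_of(ids[decided]),
                            sign = int_to_sign(combined[decided]),
                            stringsAsFactors = FALSE)
  predictions <- predictions[order(predictions$node), , drop = FALSE]
  rownames(predictions) <- NULL
  breakdown <- table(sign = factor(predictions$sign, levels = SIGNS),
                     kind = factor(predictions$kind,
                                   levels = c("gene", "protein", "complex")))
  structure(list(predictions = predictions,
                 undecided = ids[unobserved & is.na(combined)],
                 breakdown = breakdown,
                 mcos = rep_report),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat("prediction_map:", nrow(x$predictions), "predictions,",
      length(x$undecided), "undecided; MCoS k =", x$mcos$k, "\n")
  print(x$breakdown)
  invisible(x)
}

#' Extract predictions as a named sign vector
#' @param x a `prediction_map`.
#' @return named character vector node id -> predicted sign.
#' @export
prediction_vector <- function(x) {
  stats::setNames(x$predictions$sign, x$predictions$node)
}

#' Write a predictions table and MCoS report
#'
#' @param x a `prediction_map` from [predict_signs()].
#' @param tsv_path path for the tab-separated predictions table
#'   (node, kind, sign).
#' @param mcos_path optional path for the JSON repair report.
#' @return `tsv_path`, invisibly.
#' @export
write_predictions <- function(x, tsv_path, mcos_path = NULL) {
  utils::write.table(x$predictions, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(mcos_path)) {
    jsonlite::write_json(list(k = x$mcos$k,
                              repair_sets = x$mcos$repair_sets),
                         mcos_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tsv_path)
}
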