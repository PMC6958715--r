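#' Default keyword-to-sign configuration
#'
#' KGML relations are annotated with subtype keywords; edge signs are
#' inferred from them. The mapping is configuration, not code: each keyword
#' maps to `"+"`, `"-"` or `"drop"`. Relations whose subtypes carry no
#' sign-bearing keyword (binding/association, state changes, ...) are
#' dropped rather than guessed, trading recall for causal precision.
#'
#' @param path optional path to a two-column file (`keyword<TAB>value`,
#'   `#` comments) overriding or extending the defaults.
#' @return named character vector keyword -> `"+"`/`"-"`/`"drop"`.
#' @export
default_sign_config <- function(path = NULL) {
  cfg <- c("activation" = "+",
           "expression" = "+",
           "indirect effect" = "+",
           "inhibition" = "-",
           "repression" = "-")
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "\t|=")[[1]]
      if (length(kv) != 2) stop("bad sign-config line: ", ln, call. = FALSE)
      cfg[trimws(kv[1])] <- trimws(kv[2])
    }
  }
  if (!all(cfg %in% c("+", "-", "drop"))) {
    stop("sign-config values must be +, - or drop", call. = FALSE)
  }
  cfg
}

#' Parse a KGML pathway file
#'
#' Extracts the entries (genes, groups, ...) and relations (with their
#' subtype keywords) of one KEGG KGML XML document. Gene symbols are taken
#' from the entry's `graphics/@name` label (first comma-separated tokens),
#' falling back to the `entry/@name` KEGG identifiers with the organism
#' prefix stripped.
#'
#' @param path path to a KGML XML file.
#' @return a list with two data-frame-free components: `entries`, a named
#'   list keyed by entry id with fields `entry_id`, `entry_type`, `names`
#'   (gene symbols) and `component_ids` (non-empty only for groups); and
#'   `relations`, a list of records with `entry1`, `entry2`, `rel_type` and
#'   `subtypes`.
#' @export
parse_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("malformed KGML XML in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (xml2::xml_name(doc) != "pathway") {
    stop("not a KGML document (no <pathway> root): ", path, call. = FALSE)
  }
  entries <- list()
  for (node in xml2::xml_find_all(doc, "./entry")) {
    eid <- xml2::xml_attr(node, "id")
    etype <- xml2::xml_attr(node, "type")
    gname <- xml2::xml_attr(xml2::xml_find_first(node, "./graphics"), "name")
    syms <- character(0)
    if (!is.na(gname) && nzchar(gname)) {
      syms <- trimws(strsplit(gname, ",")[[1]])
      syms <- sub("\\.\\.\\.$", "", syms)
    } else {
      nm <- xml2::xml_attr(node, "name")
      if (!is.na(nm) && nzchar(nm)) {
        syms <- sub("^[a-z]+:", "", strsplit(nm, "[[:space:]]+")[[1]])
      }
    }
    comp <- xml2::xml_attr(xml2::xml_find_all(node, "./component"), "id")
    entries[[eid]] <- list(entry_id = eid, entry_type = etype,
                           names = syms[nzchar(syms)],
                           component_ids = comp)
  }
  relations <- list()
  for (node in xml2::xml_find_all(doc, "./relation")) {
    relations[[length(relations) + 1L]] <- list(
      entry1 = xml2::xml_attr(node, "entry1"),
      entry2 = xml2::xml_attr(node, "entry2"),
      rel_type = xml2::xml_attr(node, "type"),
      subtypes = xml2::xml_attr(xml2::xml_find_all(node, "./subtype"),
                                "name"))
  }
  list(entries = entries, relations = relations)
}

#' Infer an edge sign from KGML subtype keywords
#'
#' @param subtypes character vector of subtype keywords (may be empty).
#' @param config keyword map from [default_sign_config()].
#' @return character vector of signs to emit for this relation: `"+"`,
#'   `"-"`, both (when the keywords are contradictory; this is logged), or
#'   length zero when no sign-bearing keyword is present (the relation is
#'   dropped).
#' @export
sign_from_subtypes <- function(subtypes, config = default_sign_config()) {
  vals <- config[intersect(subtypes, names(config))]
  vals <- unique(vals[vals != "drop"])
  if (length(vals) == 2) {
    message("ambiguous relation subtypes (", paste(subtypes, collapse = ","),
            "): emitting both + and - edges")
  }
  unname(vals)
}

# leaf gene symbols of an entry, flattening nested groups
entry_symbols <- function(eid, entries, depth = 0) {
  if (depth > 10) stop("group nesting too deep", call. = FALSE)
  e <- entries[[eid]]
  if (is.null(e)) return(character(0))
  if (e$entry_type == "group") {
    unique(unlist(lapply(e$component_ids, entry_symbols, entries = entries,
                         depth = depth + 1)))
  } else if (e$entry_type == "gene") {
    e$names
  } else {
    character(0)  # compound / map / ortholog entries are excluded
  }
}

# graph node id(s) for an entry on the protein level: a group becomes a
# single complex node, a gene entry one protein node per symbol
entry_protein_ids <- function(eid, entries) {
  e <- entries[[eid]]
  if (is.null(e)) return(character(0))
  if (e$entry_type == "group") {
    mem <- entry_symbols(eid, entries)
    if (length(mem) < 2) return(character(0))
    complex_id(mem)
  } else {
    paste0(entry_symbols(eid, entries), "_prot")
  }
}

#' Build a signed interaction graph from parsed KGML
#'
#' Applies the node-splitting rules that turn KEGG relations into an
#' explicit gene/protein/complex causal graph:
#' \itemize{
#'   \item PPrel A -> B becomes `A_prot -> B_prot`;
#'   \item GErel TF -> G becomes `TF_prot -> G_gen` (transcription);
#'   \item every KGML group entry \{A, B, ...\} becomes a complex node
#'     `A_prot::B_prot::...` receiving one plus-signed PPrel edge from each
#'     member protein;
#'   \item for every protein node `C_prot` a plus-signed GPrel edge
#'     `C_gen -> C_prot` is added, modeling protein formation from gene
#'     expression.
#' }
#' Multi-symbol gene entries are expanded (a relation touching an entry
#' with k symbols yields k edges). Compound/map entries and relations with
#' no sign-bearing subtype are excluded. Graphs from several pathways merge
#' by node id with edge deduplication.
#'
#' @param parsed one result of [parse_kgml()], or a list of them.
#' @param sign_config keyword map from [default_sign_config()].
#' @return a [signed_graph()].
#' @export
build_graph <- function(parsed, sign_config = default_sign_config()) {
  if (!is.null(parsed$entries)) parsed <- list(parsed)
  ef <- et <- es <- er <- character(0)
  extra_nodes <- character(0)
  for (pw in parsed) {
    entries <- pw$entries
    for (rel in pw$relations) {
      if (is.null(entries[[rel$entry1]]) || is.null(entries[[rel$entry2]])) {
        warning("relation references missing entry (", rel$entry1, " -> ",
                rel$entry2, "); skipped", call. = FALSE)
        next
      }
      if (!rel$rel_type %in% c("PPrel", "GErel")) next
      signs <- sign_from_subtypes(rel$subtypes, sign_config)
      if (!length(signs)) next
      src <- entry_protein_ids(rel$entry1, entries)
      if (rel$rel_type == "PPrel") {
        tgt <- entry_protein_ids(rel$entry2, entries)
      } else {
        tgt <- paste0(entry_symbols(rel$entry2, entries), "_gen")
        tgt <- tgt[tgt != "_gen"]
      }
      if (!length(src) || !length(tgt)) next
      combo <- expand.grid(s = src, t = tgt, g = signs,
                           stringsAsFactors = FALSE)
      ef <- c(ef, combo$s)
      et <- c(et, combo$t)
      es <- c(es, combo$g)
      er <- c(er, rep(rel$rel_type, nrow(combo)))
    }
    # complex membership edges for every group entry, relation or not
    for (e in entries) {
      if (e$entry_type != "group") next
      mem <- entry_symbols(e$entry_id, entries)
      if (length(mem) < 2) next
      cx <- complex_id(mem)
      mp <- paste0(sort(unique(mem)), "_prot")
      ef <- c(ef, mp)
      et <- c(et, rep(cx, length(mp)))
      es <- c(es, rep("+", length(mp)))
      er <- c(er, rep("PPrel", length(mp)))
    }
    # isolated gene entries still contribute their protein nodes
    for (e in entries) {
      if (e$entry_type == "gene") {
        extra_nodes <- c(extra_nodes, paste0(e$names, "_prot"))
      }
    }
  }
  edges <- data.frame(from = ef, to = et, sign = es, relation = er,
                      stringsAsFactors = FALSE)
  add_gprel(signed_graph(edges, nodes = unique(extra_nodes)))
}

# add the gene -> protein formation edge for every protein node, plus the
# gene nodes it requires
add_gprel <- function(graph) {
  prot <- graph$nodes$id[graph$nodes$kind == "protein"]
  if (!length(prot)) return(graph)
  gp <- data.frame(from = sub("_prot$", "_gen", prot), to = prot,
                   sign = "+", relation = "GPrel",
                   stringsAsFactors = FALSE)
  signed_graph(rbind(graph$edges, gp), nodes = graph$nodes$id)
}

#' Convert a directory of KGML files to one merged graph
#'
#' @param paths character vector of KGML file paths (or one directory,
#'   whose `*.xml` files are taken).
#' @param sign_config keyword map from [default_sign_config()].
#' @return a merged [signed_graph()].
#' @export
ingest_kgml <- function(paths, sign_config = default_sign_config()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.xml$", full.names = TRUE)
  }
  if (!length(paths)) stop("no KGML files found", call. = FALSE)
  build_graph(lapply(paths, parse_kgml), sign_config)
}
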