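#' Sign values
#'
#' Qualitative shifts are encoded as the three characters `"+"`, `"-"` and
#' `"0"` (up-regulation / activation, down-regulation / inhibition, and
#' no change). Readers accept both the ASCII hyphen and the Unicode minus
#' glyph; writers always emit the ASCII `"-"`.
#'
#' @param x character vector of sign tokens.
#' @return `as_sign()` returns a character vector over `c("+", "-", "0")`.
#' @examples
#' as_sign(c("+", "−", "0"))
#' @export
as_sign <- function(x) {
  x <- as.character(x)
  x[x == "−"] <- "-"
  bad <- !(x %in% c("+", "-", "0"))
  if (any(bad)) {
    stop("invalid sign token(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

SIGNS <- c("+", "-", "0")

# internal integer encoding used by the solver: "+" -> 1L, "-" -> -1L, "0" -> 0L
sign_to_int <- function(s) {
  unname(c("+" = 1L, "-" = -1L, "0" = 0L)[as_sign(s)])
}

int_to_sign <- function(i) {
  c("-", "0", "+")[i + 2L]
}

#' Influence received along a signed edge
#'
#' The influence a node receives from a predecessor is the sign product of
#' the predecessor's label and the edge sign: zero is absorbing, two minuses
#' make a plus. Edge signs are restricted to `"+"` and `"-"`; a zero-signed
#' edge is an error.
#'
#' @param label sign of the predecessor node (`"+"`, `"-"` or `"0"`).
#' @param edge_sign sign of the edge (`"+"` or `"-"`).
#' @return a sign character: the product.
#' @examples
#' influence("+", "-")  # "-"
#' influence("0", "-")  # "0"
#' @export
influence <- function(label, edge_sign) {
  label <- as_sign(label)
  edge_sign <- as_sign(edge_sign)
  if (any(edge_sign == "0")) {
    stop("edge signs must be \"+\" or \"-\", never \"0\"", call. = FALSE)
  }
  int_to_sign(sign_to_int(label) * sign_to_int(edge_sign))
}

#' Classify a node identifier as gene, protein or complex
#'
#' Node kinds are derivable from the identifier itself: ids containing
#' `"::"` are protein complexes, the suffix `"_gen"` marks genes and
#' `"_prot"` marks proteins. Identifiers with none of these markers (as may
#' occur in third-party SIF files) are treated as proteins; a warning
#' summarises how many such ids were seen.
#'
#' @param id character vector of node identifiers.
#' @return character vector with values in `c("gene", "protein", "complex")`.
#' @examples
#' node_kind_of(c("TP53_gen", "MAPK3_prot", "NFKB1_prot::BCL3_prot"))
#' @export
node_kind_of <- function(id) {
  id <- as.character(id)
  if (any(!nzchar(id))) stop("empty node identifier", call. = FALSE)
  kind <- rep("protein", length(id))
  kind[grepl("::", id, fixed = TRUE)] <- "complex"
  is_gene <- !grepl("::", id, fixed = TRUE) & grepl("_gen$", id)
  kind[is_gene] <- "gene"
  recognised <- grepl("::", id, fixed = TRUE) | grepl("_gen$|_prot$", id)
  if (any(!recognised)) {
    warning(sum(!recognised), " node id(s) without _gen/_prot suffix ",
            "treated as proteins (e.g. ", id[!recognised][1], ")",
            call. = FALSE)
  }
  kind
}

#' Canonical complex identifier from member proteins
#'
#' Complex ids are the `"::"`-joined member protein ids in lexicographic
#' order, so that `A::B` and `B::A` denote the same node. The display name
#' of a complex strips the `_prot` member suffixes.
#'
#' @param members character vector of member protein ids (with or without
#'   the `_prot` suffix; it is added when missing).
#' @return a single canonical complex id.
#' @examples
#' complex_id(c("BCL3", "NFKB1"))  # "BCL3_prot::NFKB1_prot"
#' @export
complex_id <- function(members) {
  members <- as.character(members)
  members <- ifelse(grepl("_prot$", members), members,
                    paste0(members, "_prot"))
  paste(sort(unique(members)), collapse = "::")
}

#' @rdname complex_id
#' @param id complex id to render for display.
#' @export
complex_display_name <- function(id) {
  gsub("_prot", "", id, fixed = TRUE)
}

# member protein ids of a complex id
complex_members <- function(id) {
  strsplit(id, "::", fixed = TRUE)[[1]]
}

# strip _gen/_prot to recover the gene symbol; complexes are returned NA
node_symbol <- function(id) {
  out <- sub("_(gen|prot)$", "", id)
  out[grepl("::", id, fixed = TRUE)] <- NA_character_
  out
}
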