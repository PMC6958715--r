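#' Read a differential-expression table
#'
#' Comma-separated, three columns: gene symbol, log2 fold-change, adjusted
#' p-value. A header line is optional and detected by the second field not
#' parsing as a number. Records with missing numeric fields or an adjusted
#' p-value outside [0, 1] are rejected.
#'
#' @param path CSV file path.
#' @return data.frame with columns `gene`, `log2fc`, `padj`.
#' @export
read_diffexp <- function(path) {
  first <- strsplit(readLines(path, n = 1, warn = FALSE), ",")[[1]]
  header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.csv(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expected 3 columns: gene,log2fc,padj",
                         call. = FALSE)
  df <- df[, 1:3]
  names(df) <- c("gene", "log2fc", "padj")
  df$gene <- trimws(as.character(df$gene))
  df$log2fc <- suppressWarnings(as.numeric(df$log2fc))
  df$padj <- suppressWarnings(as.numeric(df$padj))
  bad <- !nzchar(df$gene) | is.na(df$log2fc) | is.na(df$padj) |
    df$padj < 0 | df$padj > 1
  if (any(bad)) {
    stop(sum(bad), " invalid record(s) in ", path,
         " (missing fields or padj outside [0,1])", call. = FALSE)
  }
  df
}

#' Discretize differential expression into qualitative signs
#'
#' A gene becomes a `"+"` observation when its log2 fold-change exceeds
#' `up_threshold` and its adjusted p-value is below `alpha`; `"-"` when the
#' log2 fold-change is below `down_threshold` with the same p-value cut.
#' Everything else is dropped. All inequalities are strict. The default
#' under-expression cut is -0.5 on the log2 scale (the negative reading is
#' the only one that keeps the up/down classes disjoint).
#'
#' @param records data.frame from [read_diffexp()] (columns `gene`,
#'   `log2fc`, `padj`).
#' @param up_threshold log2 fold-change above which a gene is `"+"`.
#' @param down_threshold log2 fold-change below which a gene is `"-"`.
#' @param alpha adjusted p-value cut.
#' @return named character vector: gene symbol -> sign.
#' @export
discretize <- function(records, up_threshold = 2, down_threshold = -0.5,
                       alpha = 1e-5) {
  stopifnot(down_threshold < up_threshold)
  sig <- records$padj < alpha
  up <- sig & records$log2fc > up_threshold
  dn <- sig & records$log2fc < down_threshold
  out <- c(stats::setNames(rep("+", sum(up)), records$gene[up]),
           stats::setNames(rep("-", sum(dn)), records$gene[dn]))
  dup <- unique(names(out)[duplicated(names(out))])
  if (length(dup)) {
    conflict <- dup[vapply(dup, function(g) {
      length(unique(out[names(out) == g])) > 1
    }, logical(1))]
    if (length(conflict)) {
      stop("conflicting signs for duplicated gene(s): ",
           paste(conflict, collapse = ", "), call. = FALSE)
    }
    out <- out[!duplicated(names(out))]
  }
  out
}

#' Attach discretized signs to a graph as observations
#'
#' Each symbol whose gene node `SYMBOL_gen` exists in the graph yields one
#' observation on that node; other symbols are reported as unmatched.
#'
#' @param signs named sign vector from [discretize()].
#' @param graph a [signed_graph()].
#' @return an `observation_set`: named sign vector keyed by node id, with
#'   attributes `matched` and `unmatched` (symbol vectors).
#' @export
attach_to_graph <- function(signs, graph) {
  if (!length(signs)) stop("no discretized genes to attach", call. = FALSE)
  node <- paste0(names(signs), "_gen")
  hit <- node %in% graph$nodes$id
  if (!any(hit)) {
    stop("no discretized gene matches a gene node in the graph",
         call. = FALSE)
  }
  obs <- stats::setNames(as_sign(unname(signs[hit])), node[hit])
  structure(obs, class = "observation_set",
            matched = names(signs)[hit], unmatched = names(signs)[!hit])
}

#' @export
print.observation_set <- function(x, ...) {
  cat("observation_set:", length(x), "observations (",
      sum(x == "+"), "+ /", sum(x == "-"), "- /", sum(x == "0"), "0 )\n")
  invisible(x)
}

#' Read and write observation files
#'
#' One `node = sign` line per observation, e.g. `A_gen = +`. `#` starts a
#' comment.
#'
#' @param path file path.
#' @return `read_observations()` returns a named sign vector.
#' @export
read_observations <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  m <- regmatches(lines, regexec("^(\\S+)\\s*=\\s*(\\S+)$", lines))
  if (any(lengths(m) != 3)) {
    stop("malformed observation line: ", lines[which(lengths(m) != 3)[1]],
         call. = FALSE)
  }
  m <- do.call(rbind, m)
  stats::setNames(as_sign(m[, 3]), m[, 2])
}

#' @rdname read_observations
#' @param observations named sign vector (node id -> sign).
#' @export
write_observations <- function(observations, path) {
  writeLines(paste(names(observations), "=", as_sign(observations)), path)
  invisible(path)
}
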