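# End-to-end orchestration of the five pipeline steps:
#   1 observations: discretize the differential-expression CSV
#   2 pathrider:    filter excluded genes, extract the upstream subgraph
#   3 signcons:     consistency check, MCoS repair, predictions
#   4 validation:   subsampling precision and stability experiments
#   5 plots:        figures and summary tables
# (KGML -> SIF conversion is step 0, exposed separately via ingest_kgml(),
# since the signed graph is input data to the pipeline proper.)

step_outputs <- function(outdir) {
  list("1" = file.path(outdir, c("observations.txt", "gene_list.txt",
                                 "observations.json")),
       "2" = file.path(outdir, "subgraph.sif"),
       "3" = file.path(outdir, c("predictions.tsv", "mcos.json")),
       "4" = file.path(outdir, "experiments.csv"),
       "5" = file.path(outdir, c("precision_boxplot.png",
                                 "stability_curves.png",
                                 "stability_summary.csv")))
}

manifest_record <- function(outdir, config, files) {
  files <- files[file.exists(files)]
  man_path <- file.path(outdir, "manifest.json")
  man <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else {
    list(config = config, files = list())
  }
  man$config <- config
  sums <- as.list(tools::md5sum(files))
  names(sums) <- basename(files)
  man$files <- utils::modifyList(as.list(man$files), sums)
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man_path)
}

# a step is up to date when all its outputs exist and match the manifest
step_done <- function(outdir, files) {
  man_path <- file.path(outdir, "manifest.json")
  if (!all(file.exists(files)) || !file.exists(man_path)) return(FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  sums <- unlist(man$files)
  all(vapply(files, function(f) {
    identical(unname(tools::md5sum(f)), unname(sums[basename(f)]))
  }, logical(1)))
}

#' Run the prediction pipeline end to end
#'
#' Executes the requested steps in order; each step writes files consumed
#' by the next, and a `manifest.json` in `outdir` records the
#' configuration and output checksums. Re-running a later step with
#' unchanged upstream artifacts reuses them instead of recomputing
#' (`force = TRUE` recomputes everything).
#'
#' @param graph path to the signed-graph SIF file.
#' @param diffexp path to the differential-expression CSV
#'   (gene, log2fc, padj).
#' @param outdir output directory.
#' @param excluded optional path to an excluded-gene list (one symbol per
#'   line).
#' @param steps integer vector of steps to run, within 1:5 (default all).
#' @param up_threshold,down_threshold,alpha discretization parameters, see
#'   [discretize()].
#' @param fractions,replicates sampling plan for step 4, see
#'   [sampling_plan()].
#' @param seed master seed for all randomness.
#' @param max_k repair-size cap, see [mcos()].
#' @param force recompute steps even when their artifacts are current.
#' @return invisibly, a list with `outdir`, the executed `steps`, and
#'   `consistent` (`TRUE` when step 3 needed no repair, `NA` if step 3 was
#'   not run).
#' @export
run_pipeline <- function(graph, diffexp, outdir, excluded = NULL,
                         steps = 1:5, up_threshold = 2,
                         down_threshold = -0.5, alpha = 1e-5,
                         fractions = seq(10, 95, by = 5), replicates = 100,
                         seed = 1, max_k = 3, force = FALSE) {
  stopifnot(all(steps %in% 1:5))
  steps <- sort(unique(as.integer(steps)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- list(graph = graph, diffexp = diffexp, excluded = excluded,
                 up_threshold = up_threshold,
                 down_threshold = down_threshold, alpha = alpha,
                 fractions = fractions, replicates = replicates,
                 seed = seed, max_k = max_k)
  out <- step_outputs(outdir)
  need <- function(step, for_step) {
    if (!all(file.exists(out[[as.character(step)]]))) {
      stop("step ", for_step, " needs the outputs of step ", step,
           "; run it first (missing ",
           basename(out[[as.character(step)]][1]), ")", call. = FALSE)
    }
  }
  executed <- integer(0)
  consistent <- NA

  if (1 %in% steps && (force || !step_done(outdir, out[["1"]]))) {
    if (!file.exists(diffexp)) stop("diffexp file not found: ", diffexp,
                                    call. = FALSE)
    records <- read_diffexp(diffexp)
    signs <- discretize(records, up_threshold, down_threshold, alpha)
    g <- read_sif(graph)
    obs <- attach_to_graph(signs, g)
    write_observations(obs, out[["1"]][1])
    writeLines(names(signs), out[["1"]][2])
    jsonlite::write_json(list(discretized = length(signs),
                              matched = length(attr(obs, "matched")),
                              unmatched = length(attr(obs, "unmatched")),
                              unmatched_symbols = attr(obs, "unmatched")),
                         out[["1"]][3], auto_unbox = TRUE, pretty = TRUE)
    manifest_record(outdir, config, out[["1"]])
    executed <- c(executed, 1L)
  }

  if (2 %in% steps && (force || !step_done(outdir, out[["2"]]))) {
    need(1, 2)
    g <- read_sif(graph)
    if (!is.null(excluded)) {
      excl <- readLines(excluded, warn = FALSE)
      g <- filter_excluded(g, excl)
    }
    targets <- readLines(out[["1"]][2], warn = FALSE)
    sub <- upstream_subgraph(g, targets)
    write_sif(sub, out[["2"]])
    message("pathrider: ", n_nodes(sub), " nodes, ", n_edges(sub),
            " edges, ", length(attr(sub, "matched_targets")),
            " matched targets")
    manifest_record(outdir, config, out[["2"]])
    executed <- c(executed, 2L)
  }

  if (3 %in% steps && (force || !step_done(outdir, out[["3"]]))) {
    need(1, 3); need(2, 3)
    g <- read_sif(out[["2"]])
    obs <- read_observations(out[["1"]][1])
    obs <- obs[names(obs) %in% g$nodes$id]
    pm <- predict_signs(g, obs, max_k = max_k)
    write_predictions(pm, out[["3"]][1], out[["3"]][2])
    manifest_record(outdir, config, out[["3"]])
    executed <- c(executed, 3L)
  }
  if (3 %in% steps && file.exists(out[["3"]][2])) {
    consistent <- jsonlite::read_json(out[["3"]][2])$k == 0
  }

  if (4 %in% steps && (force || !step_done(outdir, out[["4"]]))) {
    need(1, 4); need(2, 4)
    g <- read_sif(out[["2"]])
    obs <- read_observations(out[["1"]][1])
    obs <- obs[names(obs) %in% g$nodes$id]
    records <- read_diffexp(diffexp)
    fc <- stats::setNames(records$log2fc, records$gene)
    plan <- sampling_plan(fractions, replicates, seed)
    report <- run_validation(g, obs, fc, plan, max_k = max_k)
    utils::write.csv(report$experiments, out[["4"]], row.names = FALSE)
    saveRDS(report, file.path(outdir, "validation_report.rds"))
    manifest_record(outdir, config, out[["4"]])
    executed <- c(executed, 4L)
  }

  if (5 %in% steps && (force || !step_done(outdir, out[["5"]]))) {
    rds <- file.path(outdir, "validation_report.rds")
    if (!file.exists(rds)) {
      stop("step 5 needs the outputs of step 4; run it first",
           call. = FALSE)
    }
    report <- readRDS(rds)
    summarize_and_plot(report, outdir)
    manifest_record(outdir, config, out[["5"]])
    executed <- c(executed, 5L)
  }

  invisible(list(outdir = outdir, steps = executed,
                 consistent = consistent))
}
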