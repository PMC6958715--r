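# Subsampling validation: precision of predictions against fold-changes,
# and stability of sub-predictions against the full-observation reference.

# round-half-up (base round() is half-even, which would make stratum sizes
# depend on parity)
round_half_up <- function(x) floor(x + 0.5)

#' Sampling plan for the subsampling experiments
#'
#' @param fractions percentages of the observation set to draw, strictly
#'   increasing within (0, 100). Default 10, 15, ..., 95.
#' @param replicates experiments per fraction (default 100; the default
#'   plan is 18 x 100 = 1800 experiments).
#' @param seed integer master seed; each experiment derives its own seed
#'   from it, so results do not depend on execution order.
#' @return a `sampling_plan` list.
#' @export
sampling_plan <- function(fractions = seq(10, 95, by = 5), replicates = 100,
                          seed = 1) {
  stopifnot(all(fractions > 0), all(fractions < 100),
            all(diff(fractions) > 0), replicates >= 1)
  structure(list(fractions = fractions, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

# deterministic per-experiment seed below 2^31
experiment_seed <- function(seed, fraction, replicate) {
  (as.integer(seed) + 7919L * as.integer(fraction) +
     104729L * as.integer(replicate)) %% 2147483647L
}

#' Stratified subsample of an observation set
#'
#' Draws `fraction`% of the "+" observations and `fraction`% of the "-"
#' observations (and of the "0" ones, if present) uniformly without
#' replacement; stratum sizes are rounded half-up. A stratum rounding to
#' zero at low fractions is allowed and simply contributes nothing.
#'
#' @param observations named sign vector (node id -> sign).
#' @param fraction percentage in (0, 100).
#' @param seed integer seed; equal seeds give identical subsets.
#' @return named sign vector, a subset of `observations`.
#' @export
sample_observations <- function(observations, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction < 100)
  set.seed(as.integer(seed))
  keep <- character(0)
  for (s in intersect(SIGNS, unique(as_sign(observations)))) {
    stratum <- names(observations)[observations == s]
    k <- round_half_up(fraction / 100 * length(stratum))
    if (k > 0) keep <- c(keep, sample(stratum, k))
  }
  observations[sort(intersect(names(observations), keep))]
}

#' Precision of sign predictions against fold-changes
#'
#' The score s = m / t compares predictions with expression data with all
#' thresholds removed: a "+" prediction matches any positive log2
#' fold-change and a "-" prediction any negative one. Predictions are
#' matched to symbols by stripping the `_gen`/`_prot` suffix; complex
#' nodes (and symbols absent from `foldchanges`) are not comparable and do
#' not count toward t. Zero-sign predictions would match only a
#' fold-change of exactly zero and are reported separately via the
#' attributes.
#'
#' @param predictions a `prediction_map` from [predict_signs()], or a named
#'   sign vector of predictions.
#' @param foldchanges named numeric vector: gene symbol -> log2 fold-change.
#' @return the precision in [0, 1], with attributes `m` (matching) and `t`
#'   (comparable predictions).
#' @export
precision_score <- function(predictions, foldchanges) {
  if (inherits(predictions, "prediction_map")) {
    predictions <- prediction_vector(predictions)
  }
  sym <- node_symbol(names(predictions))
  comparable <- !is.na(sym) & sym %in% names(foldchanges) &
    predictions %in% c("+", "-")
  t <- sum(comparable)
  if (t == 0) {
    stop("no prediction is comparable to the fold-change table",
         call. = FALSE)
  }
  fc <- foldchanges[sym[comparable]]
  p <- predictions[comparable]
  m <- sum((p == "+" & fc > 0) | (p == "-" & fc < 0))
  structure(m / t, m = m, t = t)
}

#' Classify sub-run predictions against the full-observation reference
#'
#' For every node predicted in the reference run: `good` if the sub-run
#' predicts the same sign, `bad` if it predicts a different sign, `missing`
#' if it does not predict the node. The three counts always sum to the
#' reference prediction count.
#'
#' @param reference,sub `prediction_map` objects (or named sign vectors);
#'   `reference` must be non-empty.
#' @return list with `good`, `bad`, `missing` counts and `bad_nodes`, the
#'   ids predicted differently.
#' @export
stability_classify <- function(reference, sub) {
  if (inherits(reference, "prediction_map")) {
    reference <- prediction_vector(reference)
  }
  if (inherits(sub, "prediction_map")) sub <- prediction_vector(sub)
  if (!length(reference)) stop("reference predictions are empty",
                               call. = FALSE)
  present <- names(reference) %in% names(sub)
  same <- present & sub[names(reference)] == reference
  list(good = sum(same), bad = sum(present & !same), missing = sum(!present),
       bad_nodes = names(reference)[present & !same])
}

#' Run the full subsampling validation
#'
#' For each (fraction, replicate) of the plan, draws a stratified subset of
#' the observations, recomputes predictions from scratch (including the
#' repair search), and records the precision score plus the good/bad/
#' missing stability counts against the reference run on the complete
#' observation set.
#'
#' @param graph a [signed_graph()].
#' @param observations named sign vector of the complete observation set.
#' @param foldchanges named numeric vector symbol -> log2 fold-change used
#'   for the precision score.
#' @param plan a [sampling_plan()].
#' @param max_k repair-size cap passed to [predict_signs()].
#' @return a `validation_report`: list with `experiments` (one data.frame
#'   row per experiment: fraction, replicate, seed, n_obs, t, m, s, good,
#'   bad, missing, mcos_k), `reference` (the 100% `prediction_map`) and
#'   `reference_precision`.
#' @export
run_validation <- function(graph, observations, foldchanges,
                           plan = sampling_plan(), max_k = 3) {
  reference <- predict_signs(graph, observations, max_k = max_k)
  ref_prec <- precision_score(reference, foldchanges)
  grid <- expand.grid(replicate = seq_len(plan$replicates),
                      fraction = plan$fractions)
  rows <- vector("list", nrow(grid))
  unstable <- character(0)
  for (r in seq_len(nrow(grid))) {
    fr <- grid$fraction[r]
    rep_i <- grid$replicate[r]
    sd <- experiment_seed(plan$seed, fr, rep_i)
    sub_obs <- sample_observations(observations, fr, seed = sd)
    sub_pred <- predict_signs(graph, sub_obs, max_k = max_k)
    st <- stability_classify(reference, sub_pred)
    unstable <- union(unstable, st$bad_nodes)
    prec <- tryCatch(precision_score(sub_pred, foldchanges),
                     error = function(e) structure(NA_real_, m = NA, t = 0))
    rows[[r]] <- data.frame(fraction = fr, replicate = rep_i, seed = sd,
                            n_obs = length(sub_obs),
                            n_pred = nrow(sub_pred$predictions),
                            t = attr(prec, "t"), m = attr(prec, "m"),
                            s = as.numeric(prec),
                            good = st$good, bad = st$bad,
                            missing = st$missing,
                            mcos_k = sub_pred$mcos$k)
  }
  structure(list(experiments = do.call(rbind, rows),
                 reference = reference,
                 reference_precision = ref_prec,
                 unstable_nodes = sort(unstable),
                 plan = plan),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", nrow(x$experiments), "experiments over",
      length(unique(x$experiments$fraction)), "fractions\n")
  cat("  reference precision:",
      format(as.numeric(x$reference_precision), digits = 3),
      sprintf("(%d/%d)\n", attr(x$reference_precision, "m"),
              attr(x$reference_precision, "t")))
  cat("  unstable nodes:", length(x$unstable_nodes), "\n")
  invisible(x)
}

#' Summaries and plots of a validation run
#'
#' Produces per-fraction boxplot statistics for the precision score and
#' per-fraction min/median/mean/max of the good/bad/missing counts, under
#' two normalizations: by the per-sub-run prediction count (the default
#' shown in plots) and by the reference prediction count. Writes a tidy
#' CSV of all experiment rows, a summary CSV, and the two figures.
#'
#' @param report a `validation_report` from [run_validation()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `stability_summary` (data.frame) and the
#'   written file paths.
#' @export
summarize_and_plot <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ex <- report$experiments
  utils::write.csv(ex, file.path(outdir, "experiments.csv"),
                   row.names = FALSE)
  n_ref <- nrow(report$reference$predictions)
  long <- do.call(rbind, lapply(c("good", "bad", "missing"), function(cat) {
    data.frame(fraction = ex$fraction, category = cat, count = ex[[cat]],
               frac_of_sub = ex[[cat]] / pmax(1L, ex$n_pred),
               frac_of_ref = ex[[cat]] / n_ref)
  }))
  stats_of <- function(v) {
    c(min = min(v), median = stats::median(v), mean = mean(v), max = max(v))
  }
  agg <- stats::aggregate(cbind(frac_of_sub, frac_of_ref) ~
                            fraction + category, data = long,
                          FUN = stats_of)
  summary_df <- do.call(data.frame, agg)
  utils::write.csv(summary_df, file.path(outdir, "stability_summary.csv"),
                   row.names = FALSE)

  p1 <- ggplot2::ggplot(ex, ggplot2::aes(x = factor(fraction), y = s)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.6) +
    ggplot2::labs(x = "sampling fraction (%)", y = "precision score s = m/t",
                  title = "Precision of sub-predictions") +
    ggplot2::theme_minimal()
  f1 <- file.path(outdir, "precision_boxplot.png")
  ggplot2::ggsave(f1, p1, width = 8, height = 4.5, dpi = 120)

  curve_df <- do.call(rbind, lapply(split(long, long[c("fraction",
                                                       "category")]),
                                    function(d) {
    data.frame(fraction = d$fraction[1], category = d$category[1],
               min = min(d$frac_of_ref), median = stats::median(d$frac_of_ref),
               mean = mean(d$frac_of_ref), max = max(d$frac_of_ref))
  }))
  curve_long <- stats::reshape(curve_df, direction = "long",
                               varying = c("min", "median", "mean", "max"),
                               v.names = "value", timevar = "stat",
                               times = c("min", "median", "mean", "max"))
  p2 <- ggplot2::ggplot(curve_long,
                        ggplot2::aes(x = fraction, y = value,
                                     colour = category, linetype = stat)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(good = "forestgreen",
                                            bad = "firebrick",
                                            missing = "steelblue")) +
    ggplot2::labs(x = "sampling fraction (%)",
                  y = "share of reference predictions",
                  title = "Stability of sub-predictions") +
    ggplot2::theme_minimal()
  f2 <- file.path(outdir, "stability_curves.png")
  ggplot2::ggsave(f2, p2, width = 8, height = 4.5, dpi = 120)

  invisible(list(stability_summary = summary_df,
                 files = c(file.path(outdir, "experiments.csv"),
                           file.path(outdir, "stability_summary.csv"),
                           f1, f2)))
}
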