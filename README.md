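# pathcons

Sign-consistency analysis of signed causal networks against discretized
differential-expression data.

Given a regulatory network whose edges carry activation (`+`) or
inhibition (`-`) signs, and a set of observed gene shifts (up `+`, down
`-`), **pathcons** answers three questions:

1. **Consistency** — can every node be labeled `+`, `-` or `0` so that
   each label is explained by at least one incoming influence and all
   observations are kept?
2. **Repair** — if not, which *minimal correction sets* (MCoS) of nodes,
   once exempted from the explanation rules, restore consistency?
3. **Prediction** — which unobserved nodes receive the *same* sign in
   every consistent labeling (of every minimal repair)? Those signs are
   reported as predictions; nodes whose sign varies stay *undecided*.

The package also ingests KEGG KGML pathway files into a signed graph with
explicit gene/protein/complex nodes, extracts the upstream subnetwork of a
gene list, discretizes differential-expression tables, and validates
predictions by stratified subsampling (precision and stability curves).

## Model

A *signed graph* has nodes $V$ (kinds: `gene`, `protein`, `complex`,
encoded by the `_gen`/`_prot`/`::` id conventions) and edges
$E \subseteq V \times V \times \{+,-\}$. A total labeling
$\mu : V \to \{+,-,0\}$ is **consistent** with observations
$\omega$ iff for every node $x$:

- if $x$ is observed, $\mu(x) = \omega(x)$ (this always binds);
- if $\mu(x) \in \{+,-\}$ and $x$ has predecessors, some predecessor
  $p$ with edge sign $s$ satisfies $\mu(p) \cdot s = \mu(x)$
  (influences multiply signs; `0` is absorbing);
- if $\mu(x) = 0$ and $x$ has predecessors, either all received
  influences are `0`, or two distinct predecessors deliver a `+` and a
  `-` influence.

Nodes without predecessors — and nodes in a repair set — are exempt from
the last two rules. An MCoS is a minimum-cardinality node set whose
exemption makes the instance satisfiable; `predict_signs()` unions the
consistent labelings across all MCoS of that minimal size.

The solver uses bitmask domains with arc-style constraint propagation and
conflict-driven backtracking; a brute-force enumerator
(`enumerate_consistent()`) serves as an independent oracle on small
instances and is cross-checked in the test suite.

## Worked example

A transcription factor `TF_prot` activates four genes. One target is
observed up, three down — a contradiction no labeling can satisfy:

```r
library(pathcons)

g <- signed_graph(data.frame(
  from = c("TF_prot", "TF_prot", "TF_prot", "TF_prot", "X_gen"),
  to   = c("X_gen",   "Y1_gen",  "Y2_gen",  "Y3_gen",  "X_prot"),
  sign = c("+",       "+",       "+",       "+",       "+")))
g
#> signed_graph: 6 nodes, 5 edges
#>   kinds: gene=4, protein=2
#>   signs: +=5

obs <- c(X_gen = "+", Y1_gen = "-", Y2_gen = "-", Y3_gen = "-")
pm <- predict_signs(g, obs)
pm
#> prediction_map: 2 predictions, 0 undecided; MCoS k = 1

str(pm$mcos)
#> List of 2
#>  $ k          : int 1
#>  $ repair_sets:List of 1
#>   ..$ : chr "X_gen"

pm$predictions
#>      node    kind sign
#> 1 TF_prot protein    -
#> 2  X_prot protein    +
```

One repair (exempting the outvoted observation `X_gen`) restores
consistency; the majority of targets then pins the shared regulator to
`-`, while `X_prot` still follows its own observed gene.

Discretization of a differential-expression table uses strict defaults
(`log2fc > 2` for `+`, `log2fc < -0.5` for `-`, both at `padj < 1e-5`):

```r
de <- data.frame(gene   = c("X", "Y1", "Y2", "Y3", "Z"),
                 log2fc = c(3.1, -1.8, -0.9, -2.2, 1.4),
                 padj   = c(2e-9, 1e-7, 4e-8, 3e-6, 0.2))
discretize(de)
#>   X  Y1  Y2  Y3
#> "+" "-" "-" "-"
```

Validation subsamples the observations at fixed fractions, re-runs the
inference, and scores precision (sign agreement with fold-changes) and
stability (good / bad / missing versus the full-data reference):

```r
gv  <- random_signed_graph(9, edge_density = 0.15,
                           inhibition_fraction = 0.2,
                           complex_count = 1, seed = 32)
lab <- plant_consistent_labeling(gv, seed = 32)
ov  <- reveal_observations(lab, gv, fraction = 100, seed = 32)
syms <- unique(sub("_(gen|prot)$", "",
                   gv$nodes$id[gv$nodes$kind != "complex"]))
set.seed(32)
fc <- setNames(runif(length(syms), 0.5, 3), syms)
fc <- fc * ifelse(lab[paste0(syms, "_gen")] == "-", -1, 1)

rep <- run_validation(gv, ov, fc,
                      sampling_plan(fractions = c(25, 50, 75),
                                    replicates = 20, seed = 3))
rep
#> validation_report: 60 experiments over 3 fractions
#>   reference precision: 0.8 (4/5)
#>   unstable nodes: 0
```

The default `sampling_plan()` spans fractions 10–95 % in steps of 5 with
100 replicates each (1800 experiments).

## KGML ingestion and the pipeline

`ingest_kgml("kegg_dir/")` parses KGML files and builds the signed graph:
protein–protein relations connect `_prot` nodes, gene-expression
relations point from a TF protein to a `_gen` node, groups become
complex nodes fed by their members, and every protein receives a
`gene → protein` edge. `upstream_subgraph(g, symbols)` restricts to
everything that can reach the genes of interest.

`run_pipeline(graph, diffexp, outdir)` chains the five steps
(observations → subgraph → inference → validation → plots) with
checksum-based resumability; `inst/cli/pathcons` wraps it as a command
line tool.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat")'
```

The suite includes property-based tests and an exhaustive-enumeration
oracle cross-check of the production solver on 1000+ random instances.

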