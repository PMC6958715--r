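---
title: "pathcons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathcons: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcons)
```

# The model

## Signed graphs and node kinds

A signed causal graph has nodes of three kinds, encoded in the node id:

* `SYMBOL_gen` — the gene (transcript) of a symbol,
* `SYMBOL_prot` — its protein product,
* `A_prot::B_prot` — a complex, written as its member ids joined by
  `::` in lexicographic order so that every member set has exactly one
  canonical id.

Edges carry a sign in $\{+,-\}$; a sign of `0` is rejected at
construction. Relation types are implied by the endpoint kinds:
protein→protein is a PPrel, protein→gene a GErel (transcriptional
regulation), gene→protein the constitutive GPrel, and member→complex
the complex-assembly edge (always `+`).

## Consistency rules

A total labeling $\mu : V \to \{+,-,0\}$ is consistent with
observations $\omega$ when, for every node $x$:

1. **Observation rule.** If $x \in \mathrm{dom}(\omega)$ then
   $\mu(x) = \omega(x)$. This rule always binds, even for repaired
   nodes.
2. **Justification rule.** If $\mu(x) \in \{+,-\}$ and $x$ has at least
   one predecessor, then some incoming edge $(p, x, s)$ delivers the
   influence $\mu(p) \cdot s = \mu(x)$, where signs multiply and `0` is
   absorbing.
3. **Zero rule.** If $\mu(x) = 0$ and $x$ has predecessors, then either
   every received influence is `0`, or two *distinct* predecessors
   deliver a `+` and a `-` influence (a cancelling couple).

Nodes with in-degree zero are inputs: rules 2–3 do not apply to them.
A *repair* of a node set $R$ exempts the members of $R$ from rules 2–3
as well (but not from rule 1).

## Minimal correction sets and predictions

When no consistent labeling exists, `mcos()` searches node subsets of
increasing cardinality $k = 0, 1, \dots$ (default cap `max_k = 3`)
until some subset restores satisfiability, and returns *all* subsets of
that minimal size. Candidates are restricted to nodes with in-degree
$> 0$: exempting an input node from rules it is not subject to cannot
change satisfiability, so the restriction loses no repair set.

`predict_signs()` assigns an unobserved node a sign iff *every*
consistent labeling of *every* minimal repair agrees on that sign;
otherwise the node is *undecided*. Taking the union across repairs is
the conservative choice: a sign is only asserted when it is invariant to
which minimal explanation of the contradiction is the true one.

# The solver

Domains are bitmasks over $\{-,0,+\}$ (bits 1, 2, 4). Propagation runs
to a fixpoint:

* the producible-influence mask of a node is the union over incoming
  edges of the predecessor domain, swapped for `-` edges;
* labels in a node's domain that no producible influence (or cancelling
  couple, for `0`) can justify are pruned;
* once a node's domain is a singleton, the supporting predecessor
  domains are pruned in turn.

If propagation wipes out a domain the branch is abandoned. Search picks
the unassigned variable with the smallest domain (MRV) and backtracks.
Satisfiability queries, planting, and the entailment queries behind
`predict_signs()` all reuse this engine; entailment additionally reuses
every found witness labeling to answer later queries without search.

The independent oracle `enumerate_consistent()` materializes all
$3^{\text{free}}$ candidate labelings (bounded at 12 free nodes) and
filters them with a direct transcription of rules 1–3. The test suite
cross-checks the production engine against this oracle on over a
thousand random instances, including unsatisfiable ones.

# Upstream extraction

`upstream_subgraph()` seeds on the `_gen` nodes of the target symbols
and keeps every node that can reach a seed (reverse reachability),
inducing the subgraph on that node set. Induced and path-only semantics
coincide here: if $u$ and $v$ are both kept, any edge $u \to v$ lies on
a path to a seed because $v$ itself reaches a seed. Hence no
`paths-only` switch is needed. `filter_excluded()` (removing a symbol's
gene, protein, and any complex containing the protein) applies *before*
extraction, so exclusions can disconnect upstream material.

# Discretization

`discretize()` maps a differential-expression table to signs with
strict inequalities:

* `+` iff `log2fc > 2` and `padj < 1e-5`,
* `-` iff `log2fc < -0.5` and `padj < 1e-5`.

The asymmetric dead zone reflects that induction calls are held to a
stronger fold-change standard than repression calls, where modest
decreases are already informative. Boundary values are deliberately
excluded (a record at exactly the threshold is not called). Thresholds
and `alpha` are arguments; duplicated genes with conflicting calls are
an error rather than a silent pick.

# Validation

`run_validation()` takes the reference predictions from the full
observation set, then for each fraction $f$ and replicate $r$:

1. draws a stratified subsample — per sign stratum, $\lfloor f \cdot
   n_s / 100 + 0.5 \rfloor$ observations (round half up, so 25 % of 10
   is 3);
2. re-runs the full inference on the subsample;
3. scores **precision** $s = m / t$, where $t$ counts predictions whose
   symbol has a fold-change (complexes excluded) and $m$ those whose
   sign matches the fold-change direction — no thresholds here, any
   $> 0$ fold-change matches `+`;
4. classifies each reference prediction as **good** (reproduced),
   **bad** (contradicted), or **missing** (not predicted), a partition
   checked row-wise in the tests.

The default plan spans fractions 10–95 % in steps of 5 with 100
replicates: 1800 experiments. Per-experiment seeds are derived as
$(\text{seed} + 7919 f + 104729 r) \bmod (2^{31}-1)$ so every
experiment is independently reproducible. Nodes that appear among the
`bad` set in any experiment are reported as *unstable*.

# Synthetic generator

`random_signed_graph()` draws a scale-free-ish random regulatory layer
(PPrel and GErel edges at `edge_density`, inhibition probability
`inhibition_fraction = 0.153`), wires the constitutive GPrel edges, and
optionally adds complexes fed by random protein pairs. The defaults are
the study conditions and are not tuned per test.

`plant_consistent_labeling()` first tries a greedy pass in topological
order (up to 10 attempts); on cyclic graphs where the greedy pass can
fail, it falls back to the solver with randomized input-node domains and
randomized search order, re-rolling up to `max_tries` times. A planted
labeling is always verified with `is_consistent_labeling()` before
return. `reveal_observations()` exposes a stratified fraction of the
non-zero *gene* labels, mirroring that real observations come from
transcript measurements.

# Numerical and design choices

* **Round half up** (`floor(x + 0.5)`) everywhere a count is derived
  from a fraction, for platform-independent determinism
  (`base::round()` rounds half to even).
* **Lexicographic complex ids** make complex identity canonical across
  input orderings.
* **`sample.int`-based subsetting** avoids the base-R pitfall where
  `sample(x)` on a length-one vector permutes `1:x`.
* **Exhaustive bound of 12 free nodes** keeps the oracle's
  $3^{12} \approx 5 \cdot 10^5$ candidate matrix comfortably in memory.
* **`max_k = 3`** caps the repair search; past the cap the functions
  error rather than return a misleading "no repair".
* Problem sizes in examples and tests (tens of nodes) are package
  choices for fast, deterministic runs; the solver itself has no
  hard-coded size limits.

# Limitations

* The MCoS search is combinatorial ($\binom{n}{k}$ satisfiability
  calls); the default cap keeps it tractable but deeply contradictory
  instances will hit the cap.
* Predictions quantify *sign invariance*, not probability; an undecided
  node may still be heavily skewed toward one sign across labelings.
* KGML ingestion keeps only keyword-signed relations (activation,
  expression, inhibition, repression, indirect effect by default);
  unsigned relation subtypes are dropped rather than guessed, and
  compound/map entries are excluded.
* The synthetic generator produces structurally plausible but not
  biologically calibrated graphs; it exists to validate the machinery,
  not to model a specific organism.
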