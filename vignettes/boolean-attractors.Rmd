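---
title: "Data-driven Boolean attractors from single-cell transcriptomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven Boolean attractors from single-cell transcriptomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attractome)
```

# The model

`attractome` treats a tumor's regulatory program as a synchronous Boolean
network. Each gene $x_i \in \{0, 1\}$ is a vertex; the network state at
time $t$ is the vector $\vec{x}(t) = (x_1(t), \dots, x_n(t))$, and every
gene updates simultaneously through its rule,

$$x_i(t+1) = f_i(\vec{x}(t)), \qquad f_i : \{0,1\}^n \to \{0,1\}.$$

Synchronous updating makes the dynamics a deterministic map on a finite
state space, so every trajectory eventually repeats a state; the set of
states it then cycles through forever is its *attractor* (a fixed point
when the period is 1). The package's central hypothesis-serving machinery
is: binarize each cell's expression of the network genes, start a
trajectory there, and read the cell's phenotype off the attractor it
reaches. This avoids enumerating all $2^n$ configurations — on a
103-gene network only the biologically occupied corner of state space is
ever visited — at the price that attractors unreachable from observed
cells are never seen.

## Nested canalyzing rules

Every node uses the same construction scheme. Given a gene's signed
regulators, `buildNCF()` returns, under the default inhibitor-dominant
scheme,

$$f = (\neg i_1 \wedge \dots \wedge \neg i_m) \wedge (a_1 \vee \dots \vee a_k):$$

any active inhibitor silences the target regardless of everything else;
otherwise any active activator switches it on. This is a nested
canalyzing function in the listed variable order (each variable, at its
canalyzing value, fixes the output), a family repeatedly found to match
real regulatory logic. The alternative `activator_dominant` scheme,
$(a_1 \vee \dots \vee a_k) \vee \neg(i_1 \vee \dots \vee i_m)$, is kept
as a configuration switch because per-node logic is genuinely
underdetermined by the input tables: the choice of clause grouping per
node is a modeling decision, and making it a single documented switch
keeps it explicit and reproducible. Dominant repression is the default
because it is the common convention for signed gene-regulatory logic.

Genes that end up with no regulators are *frozen inputs* with the
identity rule $x^* = x$: they hold their binarized value, which keeps the
transition map total without inventing regulation the input tables do
not contain.

Rules are serialized in a plain-text dialect (`GENE* = expr` with
`and/or/not`; `∧ ∨ ¬` and `& | !` accepted on parse). Parsing and
writing are mutually inverse on canonical text, and the gene order of a
parsed file is its rule-line order (frozen inputs appended in first
appearance order), so state vectors are reproducible across runs and
machines.

# Network construction

`constructNetwork()` assembles the vertex set in monotone stages, each a
pure filter or augmenter, so the construction report fully reconstructs
the decision path:

1. **Pathway filtering** — candidate genes come from named pathway
   lists; a gene is retained iff it is measured in at least one of the
   two cell-line expression tables.
2. **DE retention** — only genes with differential-expression status
   `up` or `down` survive; missing genes default to `ns` with a warning.
3. **Hub selection** — a gene is a hub iff it has at least
   `minHubDegree` (default 50, boundary inclusive) *distinct*
   interaction partners in the interactome. Degree counts distinct
   partners — redundant evidence lines are collapsed and a
   self-interaction contributes one — because raw edge counts in curated
   interaction files are inflated by duplicate evidence records.
4. **Manual seeds** — a configured list of curated genes joins the hubs.
5. **Intermediary insertion** — for each seed pair without a direct
   edge, the shortest interactome path with at most `maxIntermediaries`
   (default 3) internal vertices is admitted, provided every internal
   vertex is expressed above `lowExpressionThreshold` in the reference
   sample. The threshold defaults to the 10th percentile of the
   reference sample's nonzero values: the rule "exclude absent or lowly
   expressed intermediaries" needs a number, and a within-sample
   quantile adapts to the data's scale without a unit convention. Among
   equal-length paths the lexicographically smallest internal tuple
   wins — an arbitrary but deterministic tie-break. Whether
   admissibility should be checked in the tumor line only or in both
   lines is not settled by the procedure's description; the reference
   sample is therefore a configuration value, defaulting to the first
   (tumor) column.
6. **TF enrichment** — every transcription factor with at least one
   target among the current vertices is added with a directed edge; its
   regulation mode rides along as a provisional sign.
7. **Sign resolution and assembly** — undirected interactome edges act
   in both directions; each directed edge's sign comes from the sign
   table first, then (configurably) from the TF mode, and an edge no
   source covers is an error by default (`unsignedPolicy =
   "activation"` downgrades this to a logged fallback). Each gene's
   regulators are ordered by descending interactome degree (ties
   alphabetical) — a deterministic stand-in for the regulator importance
   ordering a curated model would provide — and fed to `buildNCF()`.

# Binarization

Each gene is thresholded independently by a step-function algorithm on
its sorted expression vector $u_1 \le \dots \le u_N$:

1. For every discontinuity count $j \in \{1, \dots, N-2\}$, dynamic
   programming finds the monotone step function with exactly $j$
   discontinuities minimizing the total squared deviation from $u$, with
   levels equal to interval means (`optimalStepFunctions()`; the DP is
   compiled code, and exhaustive breakpoint enumeration is kept as a
   test oracle).
2. Each family member's *strongest discontinuity* is the breakpoint
   maximizing jump height divided by the function's approximation error
   (plus $\varepsilon = 10^{-12}$, which only guards exact fits against
   division by zero); ties go to the smallest location.
3. The threshold location is the **lower median** of the strongest
   discontinuity locations across the family, and
   $t$ is the midpoint of the corresponding gap between consecutive
   sorted values. A cell is called expressed iff its value is $\ge t$.
   Writing the rule with $\ge$ resolves the boundary ambiguity of a
   threshold rule whose two branches would otherwise both claim
   equality; since $t$ sits strictly inside a gap, no observed value
   ever equals it on non-degenerate data.

The quality score is the median absolute deviation of the
strongest-discontinuity locations divided by $N$: 0 when the whole
family agrees on one gap. Constant genes have no threshold; they default
to all-0 ("not expressed"), switchable to dropping the gene. No
bootstrap robustness test is attached to the threshold — the procedure
here is the deterministic step-function construction alone. By default
the pipeline binarizes each sample's cells separately
(`binarizationScope = "per_sample"`), matching the per-patient reading
of the upstream protocol; `"global"` thresholds all cells jointly.

# Attractor search and consensus calls

`simulateToAttractor()` iterates the update map, hashing every visited
state with its first-seen step index; the first revisit closes the cycle
in $O(1)$ and the attractor is stored rotated so its lexicographically
smallest state comes first, making attractors comparable across cells by
string equality. A trajectory that exhausts `maxSteps` (default 10,000)
is a *no-result* — a reported value, not an error, and the budget is
logged so no-result rates are reproducible. For small networks,
`enumerateAttractors()` builds the complete $2^n$ transition map and
returns every cycle with its basin size; it is the exact oracle the
trajectory search is validated against.

Per cell and gene, `labelGeneConstancy()` reports `True`/`False` when
the gene holds one value in at least `cycleFraction` of the cycle's
states and `X` otherwise. The default `cycleFraction = 1` demands strict
constancy over the whole cycle; 0.8 gives a "most states of the cycle"
reading. Both readings are defensible paraphrases of the underlying
protocol, which is why the fraction is an explicit, reported parameter
rather than a silent choice. Cells are grouped by `(sample_id,
cell_type)` after dropping pooled profiles; `consensusGenes()` then
calls a gene `True`/`False` for a group when at least `minCellFraction`
(default 0.95, boundary inclusive: 19 of 20 cells is a call) of the
group's *attractor-bearing* cells agree. No-result cells leave the
denominator — they have no attractor to label — and their count is
reported per group. The cross-group summary defaults to malignant groups
only, since the per-patient gene panels are read off tumor-cell
attractors; the switch `malignantOnly = FALSE` aggregates all groups.

# What the synthetic data emulate — and what they do not

`simulateExpressionMatrix()` draws each gene × cell value from a
two-component log-normal mixture (components moment-matched to stated
means and standard deviation; defaults 2 and 8 with sd 0.5, i.e.
well-separated modes), with a per-gene, per-group high-state probability
and zero-inflation dropout (default 5%) applied after the true component
label is recorded. The default profile is 103 genes and 549 cells over
14 sample groups from 11 patients across four tumor subtypes and five
cell types, so simulated artifacts have the shapes of a real
single-cell breast-cancer cohort. Log-normal components mimic the
positivity and skew of expression data; they do **not** reproduce
UMI-level count noise, gene–gene correlation, batch effects, or
library-size variation. Passing recovery tests on this generator
therefore shows the binarizer separates well-separated bimodal genes and
the pipeline's bookkeeping is correct — not that any real gene is
bimodal or that a real cohort would binarize as cleanly.

`plantFixedPoint()` provides dynamics ground truth: frozen input genes
hold a target state's values and every other gene is regulated by inputs
only, so the target is provably a fixed point and its basin is exactly
the states agreeing with it on the inputs (one update reaches the fixed
point from anywhere in the basin). This two-layer design trades
dynamical depth for a verifiable basin; recovery there validates the
trajectory search and consensus counting, not the hardness of attractor
search on deep networks. `randomNCFNetwork()` supplies such deeper
dynamics (Poisson in-degrees, random activator/inhibitor splits) with
exhaustive enumeration as the oracle at $n \le 10$.

# Numerical choices and problem sizes

- The step-function DP breaks cost ties by the lexicographically
  smallest breakpoint tuple (suffix DP plus greedy forward
  reconstruction guarantees this); the test oracle applies the same rule
  with a $10^{-9}$ cost tolerance.
- States are hashed as packed bit strings; attractor identity is the
  canonical rotation's concatenated key.
- The pipeline memoizes the transition map across the cells of a run in
  an environment keyed by packed state, which leaves results identical
  and only skips re-evaluation.
- Degenerate inputs: constant expression rows are all-0 by default with
  a warning; empty regulator sets are frozen inputs; an empty group
  after no-result exclusion is skipped with a warning.
- Test and validation sizes were chosen to exercise each guarantee at
  the scale the defaults target while staying exhaustive where an
  oracle demands it: DP equivalence on 500 vectors of $N \le 10$ (all
  breakpoint sets enumerable), dynamics equivalence on 50 networks of
  $n \le 10$ (all $2^n$ initial states), recovery on 50 genes × 200
  cells, planted recovery on 20 networks of $n = 103$ with 100 cells,
  and the full default study (103 × 549, 14 groups) run twice for
  byte-identical outputs.

# Known limitations

- Only synchronous updating is implemented; asynchronous and stochastic
  schemes, SAT/BDD attractor solvers, and network-partition composition
  are out of scope.
- Binarization is strictly two-state; no trinarization or joint
  multi-sample thresholding.
- The DE test, TF-target inference, and interaction-sign inference are
  consumed as flat tables, never recomputed; identifier mapping is a
  static alias file, not a service.
- Consensus calls carry no statistical test; they are deterministic
  threshold counts, and the two thresholds (`cycleFraction`,
  `minCellFraction`) are reported with every output so either reading
  of "constant" can be reproduced exactly.
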