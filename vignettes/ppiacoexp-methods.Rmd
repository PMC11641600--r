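---
title: "Selecting edge and node biomarkers by ellipsoid separation: model, choices, limits"
author: "ppiacoexp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting edge and node biomarkers by ellipsoid separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiacoexp)
```

## The problem

Most feature selectors for expression data score genes one at a time and
therefore miss *edge* signal: a pair of interacting proteins whose joint
behaviour separates two sample classes even though neither gene's marginal
distribution moves. ppiacoexp selects a minimal panel mixing both kinds of
feature — single genes (*nodes*) and protein–protein interactions (*edges*) —
by solving one linear program over the whole candidate set.

Three ingredients go in:

* an expression matrix $X_{m \times n}$ ($m$ samples, $n$ genes,
  non-negative units such as TPM),
* a PPI edge list (e.g. a BioGRID export) restricted to measured genes, and
* sample class labels ($C \ge 2$ classes).

## Interaction affinity

For an interaction between proteins $u$ and $v$, the law of mass action gives
the complex concentration $\rho_{uv} = \alpha\,[u]^a [v]^b$ with the protein
concentrations taken proportional to the partners' mRNA levels. With the
default constants $\alpha = a = b = 1$ the per-sample affinity of edge $i =
(u,v)$ is simply $a_{ji} = x_{ju} x_{jv}$ (`mass_action_affinity()`). The
constants are exposed (`mass_action_params()`) but there is no data from
which to estimate them, so they stay at 1 unless the user knows better.

Affinities inherit the expression scale *squared*; every downstream step is
built to tolerate that (see *Numerical choices*).

## Co-expression weights

Each edge also carries a rank (Spearman) co-expression coefficient
$B_{uv} = 1 - 6\sum_l (rg(x_{lu}) - rg(x_{lv}))^2 / D$, thresholded at a
cutoff $k$ (default $0.5$): coefficients that fail the cutoff are set to 0
and the edge drops out of the model. Choices made here:

* **Denominator.** `formula_mode = "standard"` uses $D = m(m^2-1)$, the
  Spearman denominator, which keeps $B \in [-1, 1]$. A `"literal"` mode with
  $D = m(m-1)$ is provided because that variant circulates in the applied
  literature; it can leave $[-1,1]$ and is off by default.
* **Ties** get average ranks, the standard convention.
* **Scope.** By default $B$ is computed *within each class*
  (`scope = "per_class"`), and an edge survives if it passes the cutoff in
  any class. The alternative, a single pooled coefficient over all $m$
  samples (`scope = "pooled"`), silently erases exactly the edges this
  method exists to find: a pair correlated $+\rho$ in one condition and
  $-\rho$ in the other pools to $B \approx 0$ and is zeroed for any useful
  $k$. Context-specific coupling has to be measured in context.
* **Sign.** By default the cutoff is applied to $|B|$
  (`sign = "absolute"`): strong anti-correlation is as context-specific as
  strong correlation, and for an interacting pair it is biologically
  meaningful (e.g. a regulator suppressing its partner). `sign =
  "positive"` restores the stricter convention that only positive
  co-expression counts.
* The constraint multiplier is the magnitude $|B_{ik}|$ (per class $k$),
  keeping all deviation terms non-negative.

A constant gene has no defined rank correlation; its edges get $B = 0$ with
a warning rather than an error, because a few flat genes should not abort a
genome-scale run.

## The selection program

Let $d_{jik}$ be the squared deviation of sample $j$ from the class-$k$
centroid in feature $i$: $|B_{ik}|(a_{ji} - \bar a_{iK})^2$ for an edge,
$(x_{ji} - \bar x_{iK})^2$ for a node, where centroids are per-class
arithmetic means. Each class $K$ is pictured as an ellipsoid with inner
radius $Z1_K$ and outer radius $Z2_K$ in the $w$-weighted feature space,
and the program (`build_lp()`, `solve_lp()`) is

$$\min \sum_{\mathrm{edges}} w_i + \lambda \sum_{\mathrm{nodes}} w_i
  + \alpha \sum_K (Z1_K - Z2_K) + C \sum_{j,K} \eta_{jK}$$

subject to $\sum_i w_i d_{jiK} \le Z1_K + \eta_{jK}$ for $j$ in class $K$,
$\sum_i w_i d_{jiK} \ge Z2_K - \eta_{jK}$ for $j$ outside class $K$,
$0 \le Z1_K \le Z2_K$, $0 \le w_i \le 1$, $\eta \ge 0$.

Reading it: weights are sparsity-priced (features cost, so the panel stays
small), the radius gap $Z2 - Z1$ is rewarded at rate $\alpha$, and every
sample on the wrong side of a radius pays slack at rate $C$. For more than
two classes the out-of-class constraint is applied against *every* other
class's ellipsoid, the direct generalisation of the two-class case; the
formulation is exercised at $C = 3$ in the tests.

Parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `lambda` | 1 | relative price of a node vs an edge feature (1 = equally important) |
| `alpha` | 0.1 | reward per unit of radius gap; smaller = fewer biomarkers |
| `penalty_C` | 100 | price per unit of slack; larger = fewer classification errors |
| `coexpression_cutoff` | 0.5 | the cutoff $k$ on $|B|$ |
| `weight_tol` | 1e-6 | $w_i$ at or above this counts as *selected* |

The class count and the slack penalty are both conventionally called $C$;
internally they are `n_classes` and `penalty_C`.

The all-zero point is feasible for any data, so the optimum is never
positive. The all-zero *optimum* ("trivial solution", flagged by
`extract_biomarkers()`) signals an over-regularised configuration — too
small an $\alpha$, too large a $C$, or data on too small a scale — not an
error. `grid_search()` scans the grid $\alpha \in \{0.02, 0.1, 0.5, 1\}
\times C \in \{0.1, 1, 10, 100\}$ and by default picks, among non-trivial
cells, the largest `penalty_C` and then the smallest `alpha`
(`"sparsest_accurate"`); an alternative rule picks the cell with the best
cross-validated AUC. The default grids brackets the regime where both
trade-offs bind; on a fixed dataset the selected-feature count is
non-decreasing in $\alpha$ and total slack is non-increasing in
`penalty_C`, which the acceptance suite asserts.

`weight_tol` exists because "selected" needs an operational definition: at
an optimal vertex most unselected weights are exactly zero, but a solver
may park a weight at $10^{-9}$; 1e-6 is far below any weight that carries
geometry and far above solver noise.

## The solver

No robust linear-programming backend is available to this package, so it
ships a small dense tableau simplex (`simplex_solve()`) specialised to this
model family: every row is a $\le$ constraint with non-negative right-hand
side, so the origin is a feasible vertex and no phase-1 is needed. Three
details matter in practice:

* **Equilibration.** Edge deviations can exceed node deviations by many
  orders of magnitude (squared products vs squared expressions), so columns
  and then rows are scaled to unit maximum magnitude before pivoting and
  the solution is unscaled afterwards.
* **Degeneracy.** Almost every right-hand side is zero, so vertices are
  massively degenerate. Pricing is Dantzig with a largest-pivot tie-break;
  if the objective stalls, the solver switches to Bland's rule, which
  cannot cycle.
* **Determinism.** No randomisation anywhere: the same instance always
  returns the same vertex, which makes selected panels reproducible.

Solves whose scaled feasibility residual exceeds $10^{-8}$ are reported as
`failed`, never silently returned. The test suite cross-checks optima
against an independently coded formulation solved by an unrelated
implementation on a hundred random instances, and the model can genuinely
be unbounded for extreme settings (large `alpha` with tiny `penalty_C`:
raising $Z2$ earns more than the slack it forces costs); that status is
detected and surfaced.

## Evaluation harness

`kfold_evaluate()` scores panels with a binomial GLM over the panel's
feature columns (affinity products for edges, expression for nodes),
stratified seeded folds, each sample scored exactly once out-of-fold;
Sn/Sp/ACC use a 0.5 score threshold (configurable) and AUC is the
tie-corrected Mann–Whitney statistic. Under perfect separation the GLM is
refitted with a small ridge penalty (an internal IRLS fit, checked against
`glm()` as the penalty vanishes) so scores stay finite and deterministic.

Two protocols:

* `mode = "select_once"` fixes the panel on the full data and
  cross-validates only the classifier — the protocol most published
  comparisons use, including the one this package replicates. Its estimates
  lean optimistic because selection saw the test folds.
* `mode = "nested"` re-runs selection inside every training fold and is
  leakage-free.

The acceptance suite demonstrates the direction of the bias on pure-noise
data (60 genes, 10 + 10 samples, 80 replicates): select-once CV AUC
averages ≈ 0.57 where nested CV sits at chance. Any select-once number
should be read with that offset in mind.

The node-only baselines are the same LP restricted to node features
(set `coexpression_cutoff` above 1, or pass `node_genes` only) and a
per-gene Welch t-test at $p < 5 \times 10^{-5}$ (`ttest_selector()`).

## The synthetic generator

`simulate_dataset()` produces the two kinds of planted truth the method
must distinguish:

* **Node plants**: a class-2 mean shift of $\Delta$ noise-SDs on the log
  scale (default $\Delta = 2$).
* **Edge plants**: a gene pair drawn bivariate-normal on the log scale with
  within-class correlation $\rho_1$ in class 1 and $\rho_2$ in class 2
  (defaults $0.8 / -0.8$) and *identical marginals*, then exponentiated.
  Because $E[XY] = e^{2\mu + \sigma^2(1+\rho)}$ for log-normal pairs, the
  product (affinity) distribution differs between classes while every
  per-gene test is exactly blind — the cleanest possible probe of whether
  a selector uses edge information.

Everything else is i.i.d. log-normal background, identical across classes:
log-mean 3 and log-SD 0.5 (a TPM-like scale around 20 with realistic
spread), 200 genes, 30 + 30 samples, 5 + 5 plants, 40 background edges in
the network. One integer seed makes datasets byte-identical.

What the generator does **not** emulate: batch or probe effects, library-size
variation, count noise, correlated background modules, heavy real-data
tails, or realistic PPI topology. Passing recovery tests therefore show the
algorithmic machinery works as designed; they do not promise field
performance on GEO- or TCGA-scale data.

## Observed behaviour and known limitations

These are properties of the method under the generator's conditions,
computed by the test suite and the acceptance script — worth knowing before
trusting any panel:

* **Scale sets the sparsity regime.** The radius-gap reward scales with the
  data (squared units) while weight costs are $O(1)$. On TPM-scale input
  the reward dominates: the LP is never trivial and willingly selects many
  small-weight noise nodes alongside the real signal (node recall ≈ 0.97,
  but ≈ 100 node features selected). Shrinking the data (or the reward)
  moves the same dataset through sparse regimes to the trivial solution —
  the grid-search test constructs exactly that transition. Interpret panel
  *membership* cautiously; weights order features within a panel.
* **Minimal panels exclude redundant truth.** With five exchangeable planted
  edges the optimum typically carries 2–3 of them and provably cannot be
  extended (missed plants have nonzero reduced costs), so edge recall
  plateaus near 0.5–0.6 with near-perfect edge precision. A selector built
  to minimise panel size is not a detector of *all* signal.
* **Over-selection hurts downstream classifiers.** A ~100-feature panel
  over 54 training samples saturates the GLM, so the select-once CV AUC of
  the full default panel on synthetic data is near chance, while the
  t-test baseline (which only sees the 5 shifted genes) excels there. On
  edge-only-signal data the tables turn: the t-test selects nothing at all
  while the cutoff-surviving affinity features alone reach CV AUC ≈ 0.64
  (0.52–0.85 across seeds). The affinity mean-ratio between classes is the
  convexity factor $e^{\sigma^2(\rho_1 - \rho_2)} = e^{0.25 \cdot 1.6}
  \approx 1.5$ against a product CV above 1, and a *linear* classifier on affinities cannot use
  the variance half of the signal — a quadratic read-out (which is what the
  LP's squared deviations are) would see far more.
* **Null data still yields selections.** Because triviality is
  scale-dependent, pure-noise TPM-scale data produce non-trivial panels at
  the default $(\alpha, C)$; that is precisely what the leakage experiment
  exploits. Do not read panel non-emptiness as evidence of signal; use
  `mode = "nested"` CV or a permutation control.

## Data hygiene filters

Before feature construction: `filter_missing()` removes genes with any
missing value; `entropy_filter()` removes low-information genes (per-gene
equal-width binning, default 10 bins, Shannon entropy in bits; either an
explicit threshold or, by default, the lowest decile); and
`replicate_ratio_filter()` removes genes whose max/min ratio within any
replicate group exceeds 100 (pseudocount 0 by default, configurable for
zero-heavy data; a 0/0 group is treated as consistent). Filters are
idempotent and commute when their criteria do not interact. The entropy
parameters are declared stand-ins: the upstream convention this mirrors
names no bin count or threshold.

## TSS-flanking signal normalisation

The companion `tss_signal` tools profile histone-modification signal around
transcription start sites. Conventions, stated because the upstream
description fixes none of them:

* Bins are half-open, 0-based, of equal length $L_j = 2f/n_\mathrm{bins}$,
  tiling $[\mathrm{TSS} - f, \mathrm{TSS} + f)$; the two standard layouts
  are $f = 5$ kb with 100 bins and $f = 3$ kb with 60 bins (100-bp bins in
  both). Two conflicting printed bin-span readings exist for the first
  layout; the 100-bp reading is taken as operative and both $f$ and
  $n_\mathrm{bins}$ are configurable.
* Bin order is transcript-oriented: for minus-strand genes bin 1 is the
  genomically rightmost interval, so "upstream" always means upstream of
  transcription.
* A fragment counts once, in the bin holding its midpoint
  ($\lfloor(\mathrm{start}+\mathrm{end})/2\rfloor$, boundary midpoints to
  the right bin). Whether to count reads, fragments or coverage is not
  fixed upstream; midpoint-of-record is this package's convention.
* Sequencing depth $h_l$ is the total fragment count of the sample's BED
  file, and $H_{ijl} = h_{ijl} \times 10^9 / (h_l L_j)$, averaged
  arithmetically over replicates. The $10^9$ keeps values on a TPM-like
  magnitude. The formula is exactly invariant to scaling a sample's counts
  and depth together, to bin refinement of a uniform signal, and to
  duplicating replicates; the acceptance suite asserts all three.
* Windows running past a chromosome start are kept with the clipped bin
  count recorded per gene (their counts are necessarily zero).

## Problem sizes in the test suite

The suite and acceptance script run entirely on generated data: recovery
uses the default design (200 genes, 60 samples) over 20 seeds; the leakage
experiment uses 80 pure-null replicates of 60 genes × 20 samples; solver
cross-checks use 100 random instances with at most 6 features and 12
samples; formula checks use 1000 (rank correlation) and 500 (AUC) random
cases plus all ≈ 12k valid confusion tables with counts ≤ 10. These sizes
give stable averages for the stochastic properties while keeping a full run
in the low minutes on one core.
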