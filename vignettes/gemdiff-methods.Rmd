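---
title: "Constraint-based differential flux analysis with gemdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based differential flux analysis with gemdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemdiff)
```

## The model and its assumptions

gemdiff analyses genome-scale metabolic models (GEMs): stoichiometric
networks in which each reaction $j$ carries a flux $v_j$ bounded by
$v_{min,j} \le v_j \le v_{max,j}$, and metabolite concentrations are assumed
stationary, $S\,v = 0$, where $S$ is the $m \times n$ stoichiometric matrix.
Flux balance analysis (FBA) maximizes a linear objective $c^T v$ — here
conventionally a pseudo-biomass drain aggregating precursor demands — over
that polytope. All quantities are in arbitrary flux units set by the bound
conventions of the input model; the default magnitude for unspecified
bounds, 1000, is a computational convention rather than a measured limit and
is exposed as `default_bound`.

Because a single LP optimum is rarely unique, three complementary views of
the flux space are provided:

* **FVA** (`run_fva`): per-reaction minimum and maximum flux subject to
  $c^T v \ge \alpha\, z_{opt}$. $\alpha = 1$ pins the objective; the default
  $\alpha = 0.9$ admits near-optimal alternatives.
* **Flux sampling** (`sample_fluxes`): an artificial-centering hit-and-run
  chain inside the polytope after tightening the box to the FVA ranges.
  Median sampled flux is the representative value used downstream.
* **pFBA** (`run_pfba`): among optimal solutions, the one minimizing total
  flux on the irreversible-split network — a parsimony argument against
  futile cycling.

Condition-specific models (e.g. a high-sugar-diet state) are built
declaratively (`condition_spec`, `apply_condition`): directionality updates,
then bound overrides, then artificial demand reactions, then scaling of the
exchange bounds of undetected metabolites (conventionally to one tenth of
the default). The fixed order makes overlapping edits reproducible, and an
audit log of every bound change is attached to the result. The reference
("unconstrained") comparator is defined as the same model with demand and
auxiliary reactions added but *without* the condition's bound reductions or
exchange scaling.

## Differential statistics

* **Cross-method consensus** (`differential_fluxes`): a reaction is called
  increased/decreased per method when its flux difference exceeds a
  threshold (default 1 flux unit, adjustable); the consensus sets require
  agreement of all methods. Consensus sets are monotone in the threshold.
* **Two-sample Z-test** (`flux_z_test`, `pathway_z_test`):
  $Z_i = (\bar X_{cond} - \bar X_{ref}) / \sqrt{\sigma^2_{cond}/n_{cond} +
  \sigma^2_{ref}/n_{ref}}$ on sampled fluxes, two-tailed p from the normal
  CDF. Bonferroni is the default correction for the reaction-level test on
  cofactor-dependent subsets, Benjamini–Hochberg for pathway-level tests;
  both are selectable. Zero pooled variance with equal means gives
  $Z = 0, p = 1$; with unequal means the row is flagged degenerate.
* **Pathway flux** $V_i$ is the mean of non-zero flux magnitudes over the
  pathway's members (zero tolerance $10^{-6}$); single-solution methods
  (pFBA) report only log2 fold changes, with no test.
* **Sensitivity coefficients** (`sensitivity_analysis`): each target
  reaction's flux is clamped (both bounds) to a fraction of its sampled
  median baseline, the pathway output — total consumption flux of a
  designated metabolite, e.g. cytosolic pyruvate as a proxy for glycolytic
  output — is re-measured, and
  $S_i = (\Delta v_{out}/\Delta v_i)(v_{i,base}/v_{out,base})$.
  The default levels $\{0.95, 0.90, 0.70, 0.50\}$ correspond to 5–50%
  perturbation magnitudes; clamping both bounds is the strictest reading of
  "constraining the flux to a fraction of baseline". "Active" reactions are
  those whose median |flux| exceeds the zero tolerance in at least one
  condition.

## Structure comparison and tasks

Binary reaction-presence matrices feed Hamming similarity
(distance = differing entries; similarity $= 1 - d/|universe|$),
average-linkage hierarchical clustering on Euclidean distances (for 0/1
vectors, $\sqrt{\text{Hamming}}$), and cluster-overlap Jaccard indices with
greedy maximum-overlap pair matching and optional merge-averaging for
groups split across clusters. Subsystem coverage deviation is
$(SC - SC_{mean})/SC_{mean} \times 100$; the display filter defaults to
subsystems with at least 15 reactions and a deviation above 50%, both
configurable (the narrower of the two published phrasings of this rule).
Metabolic tasks close all exchanges, add temporary uptakes (bounded by the
stated maxima) and sinks (with required minimum production), and test LP
feasibility; passes attach a mass-balanced witness flux vector. Fisher
association builds, per model and task system, the 2x2 table of the model's
passes in/outside the system against the pooled other models.

## Omics statistics

Over-representation uses the one-sided hypergeometric upper tail with
pathway membership intersected with the detected-feature universe and BH
adjustment. The weighted Jaccard index is
$\sum_{i \in A \cap B}\min(w_A, w_B) / \sum_{i \in A \cup B}\max(w_A, w_B)$
with $w_A \propto -\log_{10} q$ normalized to sum to one and uniform
$1/n_B$ weights for model-derived sets; with uniform equal-size weights it
reduces to the plain Jaccard index. A set whose q-values are all 1 falls
back to uniform weights. Isotopomer tables are normalized to per-metabolite
fractional labeling, then to a tracer reference (e.g. fully labeled
substrate), then scaled to the control-group mean, so control-group scaled
values average to one by construction. Flux-measurement correlations use an
explicit reaction-to-feature mapping, never inference.

**A caution on the bootstrap.** `bootstrap_weighted_jaccard` resamples the
experimental pathway set with replacement and recomputes the index per
replicate (duplicates keep their resampled weight mass). Because each
same-size resample omits roughly $1/e$ of the set, the replicate
distribution sits systematically *below* the point estimate — even two
identical sets yield replicate means near 0.46 rather than 1. The
distribution is therefore meaningful for *comparing* regions (its ranking
and the ANOVA/post-hoc tests are stable), not as an unbiased estimate of
the index itself. The package reports both the point estimate and the
replicate distribution so the two are never conflated.

## Numerical choices

* **LP solver.** All problems are pure LPs over bounded boxes. They are
  solved by an in-package dense two-phase tableau simplex with Bland's
  anti-cycling rule (`R/simplex.R`): variables are shifted to be
  non-negative, upper bounds become slack rows, and redundant equality rows
  (conserved moieties make $S$ rank-deficient) are absorbed by phase-1
  artificials and dropped. Pivot tolerance is $10^{-9}$; phase-1 residuals
  above $10^{-7}$ (scaled) report infeasibility. The solver is verified in
  the test suite against exhaustive vertex enumeration on small networks.
* **pFBA** minimizes total flux over *all* reactions after splitting, which
  matches the summation form of the published objective; a
  `gene_associated_only` flag provides the classic variant.
* **Sampling.** Warm-up points are the FVA extreme solutions, so chain
  states stay in the steady-state affine subspace by construction;
  directions are projected differences from the running center, the step is
  uniform on the feasible segment, thinning is 100 steps per sample, and
  states are re-projected onto the null space of $S$ at every collected
  sample to cap numerical drift (test assertion: $\max|Sv| \le 10^{-6}$).
  The FVA used for the sampling box runs at $\alpha = 0.9$ by default
  (exposed as `alpha`). Seeds are mandatory; chains are bit-reproducible.
* **Sensitivity fixtures.** The package's verification fixtures for
  sensitivity (a strict chain, where $S_i = 1$, and a full-capacity bypass,
  where $S_i = 0$) are evaluated at $\alpha = 1$: there the output flux is
  pinned and both identities are exact. At $\alpha < 1$ the sampled output
  marginal shifts slightly when an internal split is clamped, which is a
  property of the sampling geometry, not of the fixture's stoichiometry.
* **Degeneracy.** FBA may return any optimal vertex; cross-method
  comparisons therefore rely on pFBA and sampling medians rather than raw
  FBA fluxes alone. Log2 fold changes with zero denominators are reported
  as signed-infinity sentinels.

## What the synthetic data emulate — and what they do not

`make_toy_gem` builds a compartmentalized toy network: a glycolysis-like
cytosolic chain (optionally NAD(H)-coupled at a designated step), a
TCA-like mitochondrial cycle reducing mitochondrial NAD$^+$, cofactor
re-oxidation, a biomass drain, an overflow secretion route, and optionally
a futile cycle. Yields are hand-computable: with uptake bound $u$, the
biomass optimum is $u$ and the compartment-coupled NADH demand capacity is
$\min(y_c u,\; y_m (1 - f) u)$ for biomass fraction $f$. The other
generators plant known truths: bound-scaled bottlenecks, family-structured
model collections (disjoint deleted reaction blocks plus within-family
noise), log-normal metabolite intensities with group-shifted features
concentrated in designated pathways (the regional design: four groups,
$n = 4$, effect 2 log2 units, noise SD 0.25 log2 units), and steady-state
isotopomer bookkeeping whose downstream fractional labeling is attenuated
by the bottleneck scale.

These fixtures exercise every code path and make recovery claims testable,
but they are small (tens of reactions versus thousands), loop-sparse, and
noise-idealized: passing tests demonstrate correctness of the algorithms
and statistics, not predictive accuracy on real tissue models, where
degenerate alternate optima, thermodynamically infeasible loops, and
annotation errors dominate the error budget. The isotopomer generator is
deliberately bookkeeping, not an ODE labeling simulator.

## Problem sizes

The shipped tests and the acceptance script run at desk scale as the
package's own study conditions: toy models of 15–40 reactions, 200–1000
hit-and-run samples per condition (the full-scale convention is 10,000),
100 seeded conservation fixtures, 20-seed recovery replicates, and
1000-replicate bootstraps. All are parameters, and scale up unchanged.

## Known limitations

* The dense simplex targets small models (hundreds of reactions at most);
  genome-scale inputs with thousands of reactions need a sparse LP backend
  behind `solve_lp`.
* Flux sampling approximates, but does not guarantee, uniformity over the
  polytope; all sampled-flux statistics are conditional on the chain
  settings (seed, thinning, warm-up).
* No loopless or thermodynamic constraints: futile cycles are only
  suppressed by parsimony (pFBA), not excluded.
* The weighted-Jaccard bootstrap bias discussed above.
* SBML support covers the Level 3 core plus flux-bound/objective/GPR
  attributes as commonly emitted; exotic extensions are out of scope.
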