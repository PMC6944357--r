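---
title: "Graph-theoretic resting-state connectivity: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic resting-state connectivity: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfcnet)
```

## The problem

Resting-state functional connectivity (FC) asks how strongly the
spontaneous BOLD time courses of brain regions covary in the absence of a
task. When a lesion — for instance a post-chiasmatic stroke causing
hemianopia — damages one functional system, the question becomes whether
the network architecture of the whole brain reorganizes: does the damaged
subnetwork lose internal coherence, do other networks compensate, does
the balance of functional segregation (dense local clustering) and
integration (short communication paths) shift?

`rsfcnet` implements a complete group-level pipeline for this question
over the 90-region Automated Anatomical Labelling (AAL) parcellation:

1. **Connectivity**: Pearson full correlation between regional mean time
   courses; autocorrelations (the diagonal) and anti-correlations
   (negative coefficients) set to zero; Fisher r-to-z for aggregation.
2. **Thresholding**: absolute correlation thresholds (default r > 0.5,
   with a 0.40–0.50 sensitivity sweep), binarization.
3. **Graph metrics**: degree, clustering coefficient, local efficiency,
   characteristic path length, global efficiency on the binary graph.
4. **Triangle segregation**: Heron areas of all 3-cycles of pairwise
   correlations, with an area admission threshold.
5. **Statistics**: two-sided rank-sum comparisons of nodal metrics,
   BH-FDR control, and an equal-probability chi-square on admitted
   triangle counts.
6. **Synthetic cohorts**: a block-covariance generator so all of the
   above runs, and is testable, without raw imaging data.

## Connectivity model and conventions

For subject s, the regional time-series matrix is correlated pairwise to
give $r_{xy}$. Two zeroing conventions apply before anything else:
the diagonal is zero (self-correlation carries no information) and
negative coefficients are zeroed — their neurophysiological meaning at
rest is contested, and in the data this pipeline emulates they are small.
Everything downstream therefore works on matrices with entries in
$[0, 1]$.

Group aggregation happens in Fisher z space:
$\bar R = \tanh\!\big(\tfrac1S \sum_s \operatorname{artanh}(R_s)\big)$.
The transform stabilizes variance so the mean is not dominated by the
compressive tail of r near 1. Entries at or above $1 - 10^{-12}$ are
clipped before `artanh` so identical series (r = 1) stay finite; zeros
map to zeros in both directions.

Thresholds are interpreted on the r scale even though aggregation happens
in z space; the two conventions are compatible because $\tanh$ is
monotone. Thresholding is **strict**: an entry exactly equal to the
threshold is removed. An absolute threshold is used rather than a
proportional (fixed-cost) one: when one group is globally hypoconnected,
fixing the edge count would force spurious weak edges into the sparser
group, and false positives distort binary graph metrics more than false
negatives. The 0.40–0.50 sweep (step 0.01) quantifies sensitivity of
density to the cutoff; edge sets are nested across the sweep by
construction.

Whether to threshold subject-level or group-level matrices is genuinely
open; the pipeline thresholds the group matrix (subject matrices are
aggregated first), which matches the reporting of group graphs, and the
module functions accept per-subject matrices directly if a user prefers
the other order.

## The binary graph panel

With adjacency $A$ and degree $k_i = \sum_j A_{ij}$:

- **Clustering coefficient** $C_i = 2 t_i / (k_i (k_i - 1))$, where
  $t_i$ counts triangles through node i; defined as 0 when $k_i < 2$.
- **Global efficiency** $E = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}$,
  with $1/\infty = 0$ for unreachable pairs.
- **Local efficiency** of node i: the global efficiency of the subgraph
  induced by its neighbors; 0 when $k_i < 2$.
- **Characteristic path length**: the mean of $d_{ij}$ over *reachable*
  ordered distinct pairs. Thresholded patient graphs are routinely
  disconnected, so infinite distances must not enter the average; the
  number of excluded pairs is reported alongside. An edgeless graph has
  no defined path length and is flagged `not computable` rather than
  given a placeholder value.

Distances are unweighted breadth-first shortest paths (via igraph); the
test suite checks all five metrics exactly against an independent
brute-force BFS/triangle-counting oracle on 200 random graphs per run.

Nodal summaries report the mean and sample (n−1) standard deviation.
By default isolated (degree-0) nodes are **excluded** from nodal means:
reported group means of sparse networks (e.g. a 12-node network averaging
2.72 over its connected nodes) are only arithmetically consistent with
that convention. The flag is explicit in every output table (`n_used`
says how many nodes entered the mean), and `include_isolated = TRUE`
switches conventions, so both readings of a table can be reproduced.

## Triangle-area segregation

Every unordered triple of regions in scope defines a triangle whose sides
$a, b, c$ are the three pairwise correlations. Its area follows Heron's
formula, $A = \sqrt{s(s-a)(s-b)(s-c)}$ with $s = (a+b+c)/2$. Large areas
mean three mutually strong correlations — a densely connected 3-cycle —
so the count and size distribution of large triangles index functional
segregation.

A triple is admitted when its area reaches the area of the hypothetical
equilateral triangle with side 0.6:

```{r}
area_threshold(0.6)
```

Admission is inclusive at the boundary (`area >= threshold - 1e-12`):
observed minimum areas in practice equal the rounded threshold itself, so
the boundary must be admissible. All $\binom{n}{3}$ triples in scope are
examined — admission is purely by area, not restricted to triples whose
edges pass the graph threshold (that restricted variant is exposed via
`min_side` for users who want it, without any claim of equivalence).
Sides use raw r, not Fisher z, because the side threshold is phrased on
the correlation scale.

Two numerical caveats are handled explicitly. Correlation triples can
violate the triangle inequality (e.g. 0.9, 0.1, 0.1); such triples have
no real area, are excluded, and are counted in a diagnostics field.
And Heron's area is *not* monotone in a side: raising one side grows the
area only while that side stays within the right-angle bound
$a \le \sqrt{b^2 + c^2}$; beyond it the triangle flattens. The property
tests assert exactly this conditional monotonicity.

Estimator rows report N, mean, median, skewness, sample SD, min and max
of the admitted areas. Skewness is moment-based Fisher–Pearson
$g_1 = m_3 / m_2^{3/2}$ (the small-sample adjusted estimator is an
option); with two or fewer areas skewness is reported as 0, and an empty
set reports only N.

## Group statistics

Nodal metrics are compared between group graphs with the two-sided
Wilcoxon rank-sum test, one observation per node — a descriptive
convention (nodes are not independent samples), stated as such in the
documentation. The normal approximation with tie correction and
**without** continuity correction is used; the package returns the
standardized Z alongside p. At very small samples the normal
approximation is coarse — the exact null at $n = m = 4$ has only 70
support points and the approximation can sit ~0.12 from the enumerated
p — so the tests assert a tracking bound against the exhaustive oracle
rather than pretending the approximation is exact.

BH-FDR adjustment is applied across the full family of (metric × scope)
p-values produced in one run — 18 comparisons for the default three
metrics × six scopes — and the family size is recorded in the output
table, since the appropriate family is a reporting convention rather than
a derivable fact.

Admitted-triangle counts are compared with the chi-square test for given
(equal) probabilities, df = k − 1:

```{r}
chisq_equal_prob(c(944, 643))[c("chisq", "df")]
```

## The synthetic cohort generator

The generator draws each subject's 90-region series from a group-level
correlation matrix with compound-symmetry blocks: a single target
correlation within each resting-state network, a background level between
all other pairs, and the patient VN block multiplied by an attenuation
factor. This is the simplest structure that exercises everything the
pipeline measures (block density, within-network triangles, group
contrasts); it deliberately omits hemodynamics, physiological noise and
lesion geometry.

Defaults are the emulated study conditions: 10 + 10 subjects, 160
timepoints, additive white noise of sd 0.1 (targets are marginal — the
signal covariance is scaled so observed correlations hit them after
noise), i.i.d. samples by default with an optional AR(1) coefficient
(real BOLD is autocorrelated; the marginal covariance is preserved either
way). The control VN target is **0.67**: the reported control VN triangle
estimators (mean area 0.193 over 138 admitted triangles) correspond to an
equilateral side of $\sqrt{0.193/(\sqrt3/4)} \approx 0.667$, and a block
at that level is near-complete above the 0.5 edge threshold, matching the
reported 130/132 connections. A naive target of 0.6 would sit exactly on
the triangle admission boundary and make the control triangle count a
coin flip — a degenerate emulation. Patient attenuation 0.5 gives a
patient VN block of 0.335: no supra-threshold VN edges and no admitted VN
triangles, a starker version of the reported patient deficit. DMN/AN/SN
targets (0.48 / 0.45 / 0.42) are moderate, mostly sub-threshold blocks;
they emulate the qualitative sparseness of those networks (including the
salience network's "no computable metrics" behaviour) and make no
quantitative fidelity claim.

The assembled block matrix is checked for positive semidefiniteness and
repaired by eigenvalue flooring (then rescaled to unit diagonal) if
needed; at the defaults no repair is necessary.

What passing the recovery test shows — and what it does not: with
attenuation 0.5 the pipeline reports fewer patient VN connections, lower
VN metric means and fewer admitted VN triangles in ≥95/100 replicates,
and with attenuation 1.0 the sign of the group difference is a fair coin.
That validates the pipeline's sensitivity and calibration on data whose
generative truth is known; it does not validate the biological claims on
real BOLD data, whose noise structure is far richer.

## Problem sizes and numerical choices

The test suite and the analysis scripts run at the study's native scale
(90 regions, 160 timepoints, 10 + 10 subjects; 117,480 candidate triples
per whole-brain enumeration) — these sizes are fast because every stage
is vectorized or runs on sparse binary graphs. Oracle-based property
tests use 200 random graphs of up to 15 nodes, where exhaustive BFS is
exact and cheap. Monte-Carlo checks use 100 seeded replicates of the
full cohort.

Other conventions, collected: strict inequality at the edge threshold;
boundary-inclusive area admission with a $10^{-12}$ tolerance; r clipped
at $1 - 10^{-12}$ before `artanh`; sample (n−1) SD everywhere; skewness 0
for n ≤ 2; degenerate rank-sum (all values tied) reports Z = 0, p = 1;
all-zero chi-square counts report the degenerate statistic 0 with p = 1.

## Known limitations

- Nodal comparisons on group matrices are descriptive; no subject-level
  inference (mixed models, permutation NBS) is provided.
- Binary metrics only; no weighted-graph variants, community detection
  or small-world indices.
- The generator's compound-symmetry blocks cannot produce the partial
  within-network edge survival seen in real group matrices — each block
  is essentially all-or-nothing at a given threshold.
- The attentional-network membership follows the AAL-mappable definition
  (18 bilateral regions); prose definitions of attention networks that
  include non-AAL structures (frontal eye fields) cannot be represented
  on this atlas.
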