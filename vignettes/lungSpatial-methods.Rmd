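---
title: "Models and design choices in lungSpatial"
author: "lungSpatial authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in lungSpatial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungSpatial)
```

# Scope

lungSpatial implements the bespoke computational stages of a
developing-lung spatial atlas: cluster-graph trajectory skeletons,
simulation-driven targeted panel curation, spot-level co-localization
neighbourhoods, two-axis airway zonation, and hexagonal binning with
epithelial/neuroendocrine filters. Upstream steps that established tools
already cover (read alignment, normalisation-heavy integration, doublet
removal, differential-expression testing, deconvolution model fitting,
ligand–receptor inference, image processing) are deliberately out of
scope; the package consumes their outputs in plain formats (count
matrices, fraction matrices, molecule tables).

# Cluster-graph abstraction

Given a binary symmetric shared-nearest-neighbour graph $G$ over cells
and one-hot cluster memberships $O$, the shared-edge matrix is
$E = (G O)^\top O$: entry $(a, b)$ counts adjacency entries between
clusters $a$ and $b$, so each undirected edge contributes to both
ordered directions and within-cluster edges appear twice on the
diagonal — hence $\sum E$ equals twice the number of undirected edges,
an invariant the tests assert. Row-normalisation
$P = E \oslash (E J)$ turns counts into the share of a cluster's edges
reaching each neighbour.

Numerical choices:

* $G$ has a zero diagonal; self-adjacency is not a notion of the SNN
  construction, and within-cluster connectivity is already captured on
  $E$'s diagonal.
* Pruning zeroes entries strictly below $10^{-4}$ and does **not**
  renormalise rows, so surviving probabilities — and therefore the
  weights $w_{ij} = 1/p_{ij}$ — keep their original values. A
  `renormalize` flag restores unit row sums for users who prefer a
  proper stochastic matrix after pruning.
* Clusters whose edge row is entirely zero (isolated clusters) give
  zero rows in $P$; they are flagged with a warning and excluded from
  the path graph rather than failing.
* Shortest paths run on the *directed* weighted graph ($P$ is
  asymmetric after row normalisation) with igraph's Dijkstra
  implementation. Between equal-weight paths igraph's deterministic
  internal order decides; the tests therefore compare path weights
  against an exhaustive simple-path enumeration and compare the path
  itself only when the optimum is unique.

# Marker statistics

$\delta\mathrm{pct}$ for a (gene, cluster) pair is the fraction of
cluster cells with a nonzero count minus the same fraction outside the
cluster. "Positive" means a nonzero raw count, which makes the statistic
invariant to any monotone transform of the nonzero values — a property
the tests verify directly.

The marker filter keeps genes expressed in at least 25 % of the
cluster's cells, with at least 0.1 log-fold increase and at least 10
percentage points more positive cells than the rest; all bounds are
inclusive ("at least"). Fold changes are computed on counts normalised
to 10,000 per cell and log2(x+1)-transformed, as
$\log(\bar{x}_{in} + \varepsilon) - \log(\bar{x}_{out} + \varepsilon)$
with $\varepsilon = 10^{-9}$. The log base of the 0.1 threshold is not
fixed by convention alone, so it is configurable; the default is the
natural log, the convention of the Seurat era in which these thresholds
are customarily applied. The expression filter used for interactome
inputs keeps a gene when *any* cluster passes a strict mean bound
(> 0.3 on the log2 scale) together with the inclusive pct/delta/fold
criteria; each criterion can be disabled for the mean-only variant.
If a p-value column from an external test (e.g. MAST, which is out of
scope) is attached to the marker table, Bonferroni-adjusted values must
fall below 0.001.

# Panel selection

The curation loop mirrors targeted in-situ panel design: simulate a
field of cells with negative-binomial expression from reference
profiles, type each cell, score genes, shrink the panel, repeat.

* **Typer.** Full probabilistic cell typing for in-situ data
  (pciSeq-style) handles segmentation uncertainty; in simulation the
  read-to-cell assignment is known, so the minimal consistent model is
  a per-cell NB maximum-a-posteriori classifier:
  $\arg\max_t \sum_g \log \mathrm{NB}(x_g \mid \mu_{gt}, \theta) +
  \log \pi_t$ with a uniform prior by default. Profile means are
  floored at $10^{-6}$ so a single stray count against a zero profile
  cannot produce degenerate $-\infty$ ties; exact ties break towards
  the lexicographically first type for determinism.
* **Contribution.** The quantitative metric behind "contribution of
  each gene to predict each type" is not fixed by convention; the
  package defines it as the leave-one-gene-out drop in per-type
  accuracy, averaged over `n_rep = 5` independently simulated fields to
  damp Monte-Carlo noise. Contributions are not additive across genes
  (redundant markers shield each other), so tests assert signs and
  ranking behaviour rather than sums.
* **Convergence.** "Able to predict correctly all the cell types" is
  read as a per-type accuracy floor, default 0.95 and configurable;
  1.0 is attainable only in noiseless regimes. A round keeps the union
  over types of the top five genes by contribution. The loop stops once
  the target holds for a panel that retention can no longer shrink (or
  that already survived a reduction round); if the target is never
  met, the best panel seen is returned with `converged = FALSE`.

The negative-binomial simulator is parametrised by (mean, size). The
description of sampling "with r being the mean expression" is read as
the mean parameter — sizing the distribution by mean expression would
make dispersion grow with expression in an unusual way — and the shared
size parameter defaults to 2, a mid-range single-cell dispersion.

# Synthetic data and what it does (not) show

Every generator is a pure function of its parameters and seed and emits
its ground truth alongside the data; recovery tests consume only the
data.

* **Cell datasets** draw types from given proportions and counts from
  NB(mean, size). Planted-marker profiles (`plantedProfiles`) use a
  base mean of 0.25 counts per cell per gene with 8-fold markers —
  the sparse per-gene depth typical of decoded in-situ experiments,
  where a 30–150-gene panel yields tens of reads per cell. In this
  regime typing is good but imperfect, which is precisely where
  contribution scoring is informative; at droplet-scale depths every
  panel types perfectly and leave-one-out differences vanish into
  Monte-Carlo noise.
* **SNN graphs** place independent Bernoulli edges with per-cluster-pair
  probabilities (within 0.3, adjacent 0.05 along a planted chain,
  non-adjacent 0). Real SNN graphs have degree structure and
  transitivity this ignores; what passing tests show is that the
  abstraction recovers planted *topology*, not that it resolves subtle
  real-data connectivity.
* **Spot fractions** assign each spot to one co-occurrence block,
  Dirichlet(1) mass within the block, truncated half-normal noise
  (sd 0.02) outside, rows renormalised to 1. Block membership induces
  the positive within-block and negative cross-block correlations the
  neighbourhood graph thresholds.
* **Airway tissue** is a straight 2,000 µm trunk: epithelial cells along
  it express EPCAM at a constant rate and proximal/distal markers at
  linearly decreasing/increasing rates; four mesenchymal types sit at
  planted (radial, pd) positions — (20, −0.8), (60, −0.4), (40, 0.3),
  (100, 0.7) µm — with 8 µm / 0.05 jitter, emulating the
  airway-adjacent smooth-muscle versus peripheral adventitial-fibroblast
  arrangement around an embryonic airway at roughly cellular densities
  (40 reads per cell, Poisson, ~2 µm optical scatter). Real airways
  branch, curve and have lumens; the simulation validates coordinate
  recovery, not anatomical realism.

# Zonation

Reads are binned to the nearest lattice centre (squares of side
2 × radius; default radius 20 µm). Airway masks use strict
greater-than rules (EPCAM > 3 for in-situ bins; summed epithelial
markers > 8 UMIs for spots — the marker list is a user input since the
exact top-10 list depends on the dataset). Radial distances are
centre-to-centre Euclidean in µm, with positions strictly beyond 140 µm
flagged excluded.

The spot-mode proximal–distal score min–max scales each marker gene
across airway spots, averages the scaled proximal set ($p$) and distal
set ($d$), and returns $(d - p)/(d + p)$, defined as 0 when both
vanish. This form is bounded, symmetric, and reaches exactly −1/+1 for
spots expressing only one marker set — the printed endpoint convention;
a clipped difference $d - p$ is available as an alternative.

The in-situ-mode axis embeds airway-bin expression in 1-D. The
published analysis used the first UMAP dimension as a pseudotime; the
package's default is the first principal component, which is
deterministic and therefore testable (UMAP would additionally require a
package not among the dependencies). Bin vectors are library-size
normalised to the median airway-bin total, log1p-transformed and
column-standardised so no single abundant gene dominates; the component
is oriented so the proximal-marker aggregate correlates negatively with
the score. The oriented component is mapped to [−1, 1] through its
empirical ranks (the usual pseudotime normalisation) rather than a raw
min–max rescale, which proved outlier-sensitive and compressed at the
axis ends; `rescale = "minmax"` restores the plain behaviour. A `genes`
argument restricts the embedding, e.g. to the axis-defining epithelial
markers, shielding it from non-epithelial reads that spill into airway
bins — the proximal–distal axis is, by definition, an epithelial
patterning axis. Non-airway positions inherit the score of the nearest
airway bin, ties resolved to the lowest bin index.

Density maps discretise pd by rounding to a 0.1 grid (the grid step is
configurable) and radial to one bin diameter. In
label mode the per-cluster histogram is optionally Gaussian-smoothed; in
fraction mode fractions are averaged per occupied cell; each cluster's
grid is normalised to maximum 1. Internally the grid uses integer
indices, avoiding floating-point level mismatches at cell boundaries.

# Hexagonal binning and NE filters

Hexagons are pointy-top with a 7 µm circumradius; point-to-bin
assignment uses axial-coordinate cube rounding and is validated against
a point-in-polygon oracle. The source protocol states "7 µm radius" in
one place and "7 µm width" in another; circumradius is the default
reading, and a width-based interpretation is a one-line conversion
(`circumradius = width / sqrt(3)`). Filters follow the stated counting
rules exactly: SOX2 > 3 **and** EPCAM > 3 (strict); NE sum ≥ 12
(inclusive) **or** ASCL1 > 10 (strict). Whether bin counts were
normalised before the published Leiden step is unstated; the package
normalises retained bins to the median bin total and log1p-transforms
(flag `normalize = FALSE` for raw counts), builds a symmetrised
15-nearest-neighbour graph and runs igraph's Leiden with modularity
objective at resolution 0.1, fixed seed.

# Problem sizes

The test-suite and acceptance-script simulations use: 200 random graph
instances (N ≤ 30) plus 40 path graphs (k ≤ 8) for oracle equivalence;
20 seeds for chain recovery; 100 random inputs per filter; 10 curation
seeds at 3,000 cells per simulated field; 2,000 spots for neighbourhood
recovery; 10 tissue seeds at ~16,000 reads each; 1,000 random points
for binning geometry. These sizes give planted-effect signal well above
Monte-Carlo noise for every asserted property while keeping a full run
in the order of a minute (panel curation: a few minutes).

# Known limitations

* The simplified typer ignores geometry entirely; segmentation-aware
  typing on real in-situ data is out of scope.
* Neighbourhoods are connected components of a thresholded graph; a
  Leiden option exists for graphs that threshold into one component,
  but no community structure beyond that is inferred.
* The zonation axes assume a single dominant airway per neighbourhood
  of a position; sections with several airways closer than the radial
  cutoff attribute positions to the nearest one only.
* Published headline numbers that depend on restricted-access donor
  data (cell counts, the final 72-gene panel, the specific four
  neighbourhoods, module stability values) are outside what synthetic
  recovery can or should reproduce.
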