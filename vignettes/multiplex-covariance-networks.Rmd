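---
title: "Dual-layer multiplex structural covariance networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-layer multiplex structural covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiplexSCN)
```

# The analysis in one paragraph

Given per-subject regional tables of cortical thickness (CTH, mm) and
FDG-PET uptake (SUVR), the package removes age, sex, and education effects
from every region by linear regression, computes a group-level Pearson
correlation matrix per modality (a *structural covariance network*),
binarizes each matrix across a density sweep, couples the two binary layers
into a multiplex network through replica edges, computes multiplex graph
measures — intralayer degree $k_i^\alpha$, overlapping degree
$o_i = \sum_\alpha k_i^\alpha$, and the multiplex participation coefficient
$$p_i = \frac{M}{M-1}\Bigl(1 - \sum_{\alpha=1}^{M}
       \bigl(k_i^\alpha / o_i\bigr)^2\Bigr)$$
— and tests group differences of these measures with a subject-relabeling
permutation test under Benjamini–Hochberg FDR control. Because the networks
are *group-level* objects (one correlation matrix per group, not per
subject), no subject-wise network measures exist, and permutation of group
labels is the natural inference engine.

# Model and pipeline

## Covariate residualization

For each region and modality the model
$Y_i = \beta_0 + \beta_1\,\mathrm{Age} + \beta_2\,\mathrm{Sex} +
\beta_3\,\mathrm{Education} + \varepsilon_i$
is fitted by ordinary least squares through one QR decomposition of the
shared design matrix; the residuals $\varepsilon_i$ feed the network stage.
Two properties are enforced and tested: residual column means vanish
(intercept present) and residuals are orthogonal to every covariate.
Residualization is idempotent and scale-equivariant.

The regression is fitted on the **pooled sample of the two groups being
compared**, once, before any permutation. Under the permutation null the
subjects must be exchangeable; fitting per group would absorb part of a true
group difference into the covariate model, and refitting inside each
permutation would merely reproduce the identical pooled fit because group
membership does not enter the design matrix.

## Network construction

Within each group, entry $(i,j)$ of a layer is the Pearson correlation of
region $i$ and region $j$ residuals across subjects; the diagonal is defined
as 0. Layers are binarized at a threshold $d$ with two semantics:

* **density** (default): the $\mathrm{round}(d\,n(n-1)/2)$ strongest edges
  are kept. "Strongest" is made deterministic by a stable sort on
  $(-w, i, j)$ with $i<j$ in lexicographic order, and "round" is
  half-away-from-zero, so exact edge counts are platform-independent.
* **absolute**: an edge exists iff its weight exceeds $d$.

Negative correlations are removed before either rule and can never become
edges; in density mode the edge count is therefore
$\min(\mathrm{round}(d\,E), \#\{w > 0\})$ — the quota is truncated rather
than padded with non-edges. The default sweep is $d = 0.40$ to $0.70$ in
steps of 0.05.

The binary layers $A^{(1)}, A^{(2)}$ are assembled into the supra-adjacency
matrix
$$W = \begin{pmatrix} A^{(1)} & C \\ C & A^{(2)} \end{pmatrix},
  \qquad C = c\,I,$$
with replica coupling $C$ connecting each region only to its own copy in the
other layer — the multiplex topology the participation coefficient presumes.
The coupling strength $c$ (default 1) is structural bookkeeping: degrees
count intralayer edges only, so every measure in the package is invariant to
$c$ (tested).

## Multiplex measures

With $M$ layers, $k_i^\alpha$ is the row sum of layer $\alpha$,
$o_i = \sum_\alpha k_i^\alpha$, and $p_i$ is as above, so $p_i = 1$ for a
node with equal degree in all layers and $p_i = 0$ for a node confined to
one layer; for $M = 2$, $p_i = 4k_i^1 k_i^2/(k_i^1+k_i^2)^2$ algebraically.
An isolated node has $o_i = 0$ and the formula degenerates to $0/0$; the
package defines $p_i = 0$ there (a node participating in no layer), which
biases global MPC downward at sparse densities — global measures average
over **all** nodes, isolated ones included, so the node count is constant
across thresholds and groups.

## Permutation inference and FDR

The observed statistic is the group difference (first minus second group) of
a measure at one threshold. The null is built by pooling the subjects,
reassigning them at random to two pseudo-groups of the original sizes, and
re-running the entire per-group pipeline (correlation, thresholding,
supra-assembly, measure) on every reassignment; 5,000 permutations by
default. The two-tailed p-value uses the add-one estimator
$p = (\#\{|\Delta_{\mathrm{null}}| \ge |\Delta_{\mathrm{obs}}|\} + 1)/(n_{\mathrm{perm}}+1)$,
which cannot be 0 — a finite permutation sample cannot support $p = 0$. The
2.5% and 97.5% null quantiles are reported alongside, covering both readings
of "significance by 95% confidence interval".

The FDR family is the set of regions within one (comparison, measure,
threshold) triple — 68 nodal p-values for the default atlas — adjusted by
Benjamini–Hochberg; global measures are tested per threshold without FDR,
matching per-threshold reporting of global differences. Whether the family
should also span thresholds is a legitimate alternative; the choice is
echoed into the run manifest so results are self-describing.

# The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
patient data. Per subject it draws age ~ U(50, 80), sex ~ Bernoulli(0.5),
education ~ U(8, 22), and sets each region's value to a covariate linear
term plus `noiseSd` times a multivariate normal draw whose correlation
matrix is the group's **population target**. Group-level correlation
networks computed from the residuals then converge to that target, which is
returned as ground truth. Pearson correlation is scale-free, so the
covariate betas (defaults on a cortical-thickness-like and an SUVR-like
scale) and `noiseSd` exercise the residualization stage without influencing
the network topology.

## Background correlation structure

The background is a single-factor model with a deterministic node-loading
gradient: region $i$ has loading $a_i = \bar a + g\,u_i$ with $u_i$ equally
spaced in $[-1, 1]$, giving target correlations $a_i a_j$ off the diagonal —
positive semi-definite by construction. $\bar a$ is calibrated so the mean
off-diagonal correlation equals `baseCorrelation` exactly (default 0.3, a
typical mean structural covariance correlation; 0 gives fully independent
regions). The gradient amplitude `correlationSpread` (default 0.2) grades
the correlation spectrum the way real covariance matrices are graded.

The graded spectrum matters more than it may look. With an equicorrelated
(compound-symmetry) background — `correlationSpread = 0` — **every** edge has
the same population weight, so a density threshold resolves pure sampling
noise: node degrees at $n = 60$ subjects swing over nearly their full range,
driven by each node's sample covariance with the common factor, and any
nodal inference is drowned. A graded background gives the thresholded
population network a well-defined topology, of which sample networks are
noisy versions. Equicorrelated backgrounds remain available (and are used to
show the degeneracy), but validation experiments use graded ones.

## Planted epicenter effects

An epicenter is a region subset whose incident correlations are shifted by a
per-modality increment in one group. Opposite-signed increments across the
layers ("layer imbalance") change which layer dominates those nodes' edges,
creating a known nodal-MPC group difference — the construct the nodal test
is validated against.

Two facts discovered while designing the validation experiment, both
properties of correlation matrices rather than of this implementation:

* A uniform *elevation* of one node's correlations to all others is PSD-
  infeasible beyond roughly $\sqrt{b} - b \le 0.25$ above a background of
  mean $b$; requesting more triggers the repair step. Suppression (a loading
  reduction) is the feasible direction. Targets that leave the PSD cone are
  repaired to the nearest correlation matrix (Higham alternating
  projections) and the repair is flagged in the ground truth.
* The permutation null inherits **half** the planted correlation shift
  (pseudo-groups mix the two groups), so a planted effect is only cleanly
  detectable when half the increment still clears the sampling noise of a
  correlation coefficient, $\mathrm{sd}(\hat r) \approx (1-r^2)/\sqrt{n-3}$.
  At $n = 60$ this pushes the validation cohort toward a strongly covarying
  system: the recovery experiment uses `baseCorrelation = 0.78`,
  `correlationSpread = 0.04`, and increments (CTH $+0.10$, FDG $-0.30$) on 6
  of 34 mid-gradient regions. There the planted nodes are recovered at FDR
  0.05 with high sensitivity and the non-planted false-positive rate stays
  low (verified by the test suite and recomputed by
  `scripts/acceptance.R`). At a weakly covarying background ($r \approx
  0.3$) the same increment is *not* reliably detectable at these sample
  sizes — a power statement users should carry to real data.

## Problem sizes used in the tests

The suite validates size with 500 null pairs (30 subjects per group, 8
regions, 200 permutations each), power with the planted configuration above
(60 per group, 34 regions, 1,000 permutations), and Monte-Carlo correctness
against the exact 70-split enumeration for 4 + 4 subjects. These sizes keep
the whole suite within a few minutes while leaving the binding statistical
quantities (type-I error, sensitivity, false-positive rate) interpretable.

# Numerical choices

* Edge tie-break: stable $(-w, i, j)$; rounding: half away from zero —
  both fixed so exact edge-count assertions hold on any platform.
* Negative correlations: removed before thresholding (binary structural
  covariance convention); density quotas are truncated, never padded.
* $o_i = 0 \Rightarrow p_i = 0$; global means include isolated nodes.
* Residualization requires at least 5 subjects and a full-rank design;
  collinear covariates are reported by name, never silently dropped.
* Group correlation requires at least 3 subjects and rejects zero-variance
  regions by name; missing values are rejected at read time, not imputed.
* Seeds: one master seed; `runAnalysis()` derives per-comparison child
  seeds as `seed + 10007 * comparison_index` so comparisons never share a
  permutation stream. Identical seeds give bit-identical results end to end.
* Kruskal–Wallis on ordinal count tables uses the mid-rank closed form with
  the tie correction $1 - \sum_c (t_c^3 - t_c)/(N^3 - N)$, which agrees
  exactly with `kruskal.test()` on expanded per-subject data.

# Known limitations

* Group-level covariance networks have no subject-level measures; effect
  sizes are differences of group statistics and confidence intervals for
  them are not available from this design.
* At conventional structural covariance strength ($\bar r \sim 0.3$) and
  $n \le 60$ per group, density-thresholded binary topology is noisy; the
  threshold sweep is a sensitivity analysis, not a multiplicity fix, and
  nodal findings replicated across thresholds deserve more trust.
* The generator emulates the statistical structure the analysis assumes —
  group-level correlation targets, linear confounds, layer-imbalanced
  epicenters. It does not emulate site effects, atrophy trajectories,
  non-linear covariate effects, or measurement artefacts; passing tests
  say nothing about those.
* No site harmonization is provided; analyze sites separately.
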