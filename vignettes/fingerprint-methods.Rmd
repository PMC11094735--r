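---
title: "Adsorption free-energy fingerprints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adsorption free-energy fingerprints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bionanofp)
```

## The problem

A nanomaterial's "biological fingerprint" is the vector of adsorption
(binding) free energies of a panel of small biomolecules — amino-acid side
chains, lipid fragments, sugars — to its surface, in kJ/mol. Computing one
entry of that fingerprint by biased molecular dynamics costs hundreds of
nanoseconds of simulation, so a full panel for a new material is
expensive. This package implements a pipeline that (i) extracts adsorption
free energies from potential-of-mean-force (PMF) profiles, (ii) clusters
the biomolecules by their binding profiles across a reference set of
materials, (iii) selects one representative "probe" molecule per cluster,
(iv) fits regression models that predict every other molecule's free
energy on a material from the probe free energies alone, with repeated
70/30 hold-out validation over materials, and (v) groups nanomaterials by
their measured or predicted fingerprints. The practical payoff is that a
new material can be characterized by simulating (or measuring) only 3–5
probes.

## From PMF to adsorption free energy

The collective variable is the surface separation distance (SSD) $s$, the
distance along the surface normal between the material's outermost atom
layer and the adsorbate's center of mass. The PMF is obtained from the
average force $\langle F(s)\rangle$ on the adsorbate by

$$W(s) = -\int_{s_0}^{s} \langle F(s')\rangle\, ds',$$

with $s_0$ a far reference distance where the force has decayed, so
$W(s_0) = 0$. `pmf_from_mean_force()` evaluates this by trapezoidal
quadrature on the supplied grid (profiles arrive pre-gridded and smooth,
so higher-order quadrature buys nothing) and re-pins the reference
exactly. The adsorption free energy is a Boltzmann average over an
adsorption layer of thickness $\delta$:

$$\Delta G_{\mathrm{ads}} = -k_BT\,\ln\!\left[\frac{1}{\delta}
\int_{a}^{a+\delta} e^{-W(s)/k_BT}\, ds\right],$$

with defaults $\delta = 0.8$ nm and $T = 300$ K (`fe_params()`), matching
the conventions under which the reference fingerprint data were produced.
Negative values mean favorable binding; a flat PMF gives exactly zero and
a constant well of depth $w$ gives exactly $-w$ for any $\delta$.

Two numerical choices deserve a note. First, the integration window: the
layer start $a$ is caller-suppliable; by default it is placed so the
window of width exactly $\delta$ is centered on the PMF minimum (clipped
to the grid). This reads "adsorption layer" as the region around the
bound state and makes the flat-PMF limit exact. Second, the implementation
normalizes the Boltzmann integral by the trapezoid of the constant 1 over
the same nodes rather than by the nominal $\delta$; the two are equal
analytically, but the former makes the flat case exact in floating point
as well.

Statistical uncertainty is propagated the way block analysis of a long
biased run would do it: given PMFs from independent production windows on
a common grid, `windowed_bounds()` forms the pointwise mean and standard
deviation, evaluates $\Delta G$ for the mean and for the mean $\pm n$ sd
envelope curves, and re-sorts the three results (the Boltzmann average is
nonlinear, so envelope order need not survive integration). The envelope
multiplier defaults to 1 sd and is exposed, since only "the variance
across windows" — not a multiplier — is conventionally fixed.

## The synthetic study

Real fingerprint panels show a characteristic block structure: a group of
aromatic/cyclic molecules that bind strongly to hydrophobic carbon
surfaces (graphene-like), a small group of compact anionic molecules that
bind selectively to charged/polar surfaces, and a broad remainder.
`generate_matrix()` emulates exactly this:

$$y_{ij} = \mu + a_i + b_j + \gamma_{g(i),h(j)} + \varepsilon_{ij},$$

with molecule offsets $a_i$, material offsets $b_j$, a group-interaction
matrix $\gamma$, and cell noise $\varepsilon$. The defaults define the
study conditions used throughout the tests and the acceptance script:

* 32 molecules in groups of 7/22/3 and 33 materials in groups of 6/19/8,
  mirroring the empirical cluster sizes of measured panels;
* noise sd 0.5 kJ/mol — the typical statistical uncertainty of
  metadynamics-derived adsorption free energies;
* $\mu = -8$ kJ/mol and offset sds of 1.5 kJ/mol, giving realistic
  overall magnitudes and within-group spread;
* $\gamma = \begin{pmatrix} -30 & -8 & -4 \\ -10 & -7 & -3 \\ -5 & -8 &
  -26 \end{pmatrix}$ kJ/mol (rows: aromatic/remainder/anionic molecules;
  columns: hydrophobic/polar/charged materials), chosen once so that
  every between-group contrast is at least 15 kJ/mol, i.e. far above the
  noise, the regime in which the measured panels sit.

The magnitudes of $\gamma$ and the offsets are generator choices, not
measured values; they were fixed by separation arithmetic (between-group
squared distances a factor of several above the within-group spread), so
that cluster recovery is a property of the method, not luck. Because the
model is additive, each non-probe row is an exact affine function of its
group representative's row when the noise is switched off — which is what
makes the noiseless configuration a sharp oracle for the linear model
(training and held-out $R^2$ of exactly 1, planted coefficients
recovered).

What the generator does *not* emulate: force-field chemistry, correlated
errors between related materials (e.g. CNT functionalization series),
heavy-tailed outliers like a charged molecule on an oppositely charged
surface, or molecules that straddle groups. Passing the planted-recovery
tests therefore shows the clustering/selection/regression machinery is
correct, not that three probes suffice for any real material class.

`generate_pmf()` provides the matching toy for the free-energy module: a
Gaussian well of known depth, width and center plus optional pointwise
noise, tail-pinned to zero at the far end of the grid (the grid must
extend at least four widths past the center so a flat tail exists).

## Clustering and probe selection

Molecules are compared by the Euclidean distance between their rows
(binding profiles across all materials); the root-mean-squared variant
divides by $\sqrt{n_{\text{materials}}}$ and is a global rescaling that
cannot change any merge order or assignment, so it is offered only for
height readability. No standardization is applied before clustering or
PCA: every entry is already in kJ/mol on a common scale.

Agglomerative clustering uses the Ward criterion — merge the pair of
clusters whose union minimally increases the total within-cluster sum of
squares — via `stats::hclust(method = "ward.D2")` on the Euclidean
distances. Heights are on the distance scale (two singletons at distance
$d$ merge at height $d$) and are provably monotone for Ward. Tie-breaking
between exactly equal merge costs follows `hclust`'s internal order; on
continuous data exact ties have probability zero, and the test suite
verifies the full merge sequence against an exhaustive oracle that
recomputes every candidate merge cost from raw coordinates.

The cluster count is cross-checked three ways, as one would on a real
panel: the PCA variance spectrum with Minka's maximum-likelihood estimate
of the effective dimensionality (Laplace evidence over candidate ranks,
with a simple ratio threshold as fallback for degenerate spectra), the
k-means inertia elbow, and the dendrogram gap. `kmeans_partition()` runs
Lloyd iterations (`stats::kmeans`, algorithm "Lloyd", 300 iterations cap)
from k-means++ seedings, best of 10 restarts by inertia.
`inertia_curve()` additionally warm-starts each $k$ from the previous
solution's centers plus the worst-fit point, which guarantees the
reported curve is non-increasing in $k$; the suggested elbow is the point
of maximum discrete curvature, but the full curve is always reported —
the elbow is a reading aid, not a decision rule.

The probe ("representative") of a cluster is the member with the smallest
Euclidean distance to the cluster centroid (arithmetic mean of member
rows); ties break by input order and the distances are attached to the
result for inspection.

## Regression families

Probe free energies are the features (one column per probe, one row per
material); all other molecules are responses.

* **LR** — ordinary least squares with intercept, one independent model
  per response. A rank-deficient design falls back to the minimum-norm
  solution with a warning. On a panel whose groups are internally affine,
  LR contains the truth, which is why it is the reference family.
* **AdaBoost.R2** — per response, 50 boosting iterations of depth-3
  regression trees (`rpart`, variance-reduction splitting, `cp = 0`,
  `minsplit = 2`) fit on weighted bootstrap resamples, linear loss
  normalized by the largest absolute error, weight update
  $\beta^{1-\ell_i}$, prediction by the weighted median of base learners.
  Boosting stops early on a perfect fit or when the weighted loss reaches
  0.5. Within-tree split tie-breaks follow `rpart`'s internal rule.
* **NN** — a single network over all responses jointly: one hidden layer
  of 10 tanh units, linear outputs, L2 penalty $10^{-4}$, trained by
  full-batch Adam (step $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$, up
  to 2000 epochs, early stop after 20 epochs without loss improvement).
  The L2 strength, epoch budget and stopping rule are not dictated by any
  convention for this problem and are exposed in `regressor_spec()`.
  Features and responses are z-scaled internally for optimizer
  conditioning and predictions mapped back to kJ/mol; the penalty
  therefore acts on the scaled weights.

All stochastic elements (resampling, initialization) derive their seeds
from `regressor_spec(seed = )`, and the evaluation protocol derives one
seed per split as `seed + split index`, so every reported number is
reproducible bit-for-bit on one platform.

## Validation protocol

`make_splits()` draws repeated independent random 70/30 train/test
partitions of the *materials* (shuffle-split semantics; with 33 materials
that is 23 train / 10 test, and test sets may overlap across the 10
repeats). Metrics follow the standard definitions

$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2},
\qquad \mathrm{MAE} = \frac{1}{n}\sum_i |y_i - \hat y_i|.$$

$R^2$ of a constant truth vector is undefined and reported as `NA` with a
warning, never silently zero; negative held-out $R^2$ values are retained
as informative. The pooling order is fixed and documented because it is
otherwise ambiguous: $R^2$/MAE are computed per molecule across the
materials of a set, averaged with equal weight over molecules within a
split, then summarized as mean ± sd over splits. Per-molecule and
per-split tables are kept in the returned object so the aggregates can be
recomputed exactly.

`evaluate_leakage_free()` closes the subtle leak in the default protocol:
molecule clustering and probe selection themselves see the full material
panel. In the leakage-free variant both are redone per split on the
training materials only, so held-out materials influence nothing. The
per-split probe sets and their stability (fraction equal to the full-data
set) are reported alongside the metrics.

## Grouping nanomaterials

Materials are clustered with the same Ward engine on the transposed
matrix (each material described by its molecule profile).
`build_predicted_matrix()` constructs the matrix available after
measuring only the probes: probe rows carried over bit-identically,
every other row replaced by the model prediction. Whether the predicted
fingerprints group materials the same way as the full data is quantified
— not eyeballed — by the adjusted Rand index between the $k = 3$ cuts
and the cophenetic correlation between the trees
(`compare_groupings()`). On the default synthetic study the agreement is
exact (ARI 1) at the 0.5 kJ/mol noise level and degrades only when the
noise is pushed to a substantial fraction of the group contrasts.

## Problem sizes and runtime

The test suite and the acceptance script run entirely on generated data
at the study's native scale: 32 × 33 matrices, 10 splits, 10 PMF windows
on 1001-point grids, 200 random instances (n ≤ 8) for the Ward oracle
and 100 random matrices for the monotonicity properties. These sizes
were chosen because they are the scale of the scientific problem itself;
a full run of the analysis scripts takes a few minutes on one core, the
AdaBoost evaluation (≈ 15,000 tree fits) dominating.

## Known limitations

* The reference 32 × 33 panel of measured free energies is not
  redistributable with the package; the checks that reproduce published
  summary statistics require the user to supply it (see
  `?reference_matrix_path`). Everything else runs self-contained.
* Ward tie-breaks and `rpart` split tie-breaks follow the host
  implementations; exact ties are only reachable on constructed integer
  data.
* The PMF module assumes profiles already averaged over the sampling
  (no bias-potential reconstruction, no trajectory handling), and a
  strictly increasing SSD grid.
* The elbow suggestion is a curvature heuristic; on panels without clear
  block structure it will dutifully report a $k$ that means little —
  inspect the curve and the dendrogram.
* The NN is intentionally small (10 hidden units); it is the comparison
  family for panels of this size, not a general-purpose regressor.
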