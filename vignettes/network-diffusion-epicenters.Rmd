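---
title: "Mapping disease epicenters by network diffusion on structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping disease epicenters by network diffusion on structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndmap)
```

## The model

Many brain disorders show spatially structured gray-matter alteration that
looks less like independent regional damage and more like something that
spread along white-matter connections. The network diffusion model (NDM)
formalizes that idea as linear heat diffusion on the structural connectome.
Let $W$ be the weighted adjacency matrix of inter-regional connection
strengths from tractography, $D$ the diagonal matrix of node strengths, and

$$H = I - D^{-1/2} W D^{-1/2}$$

the symmetric normalized graph Laplacian. A pathology distribution
$\mathbf{x}(t)$ then evolves as

$$\frac{d\mathbf{x}}{dt} = -\beta H \mathbf{x}, \qquad
  \mathbf{x}(t) = U e^{-\Lambda \beta t} U^\top \mathbf{x}_0,$$

where $U \Lambda U^\top$ is the eigendecomposition of $H$ and $\beta$ is a
diffusivity constant. Eigenmodes with small eigenvalues are persistent
spatial patterns of diffusion; the zero mode, $D^{1/2}\mathbf{1}$ for a
connected graph, is the stationary limit.

**Epicenter mapping** inverts this forward model crudely but robustly: seed
each region in turn with a unit load, diffuse it over a time grid,
correlate (Pearson, across all regions) the predicted pattern at each time
with an observed alteration map, and rank seeds by their peak correlation
over time. The top-ranked seed is the candidate epicenter. The observed
map is a rectified per-region case-control contrast: a general linear
model per region, `volume ~ group + TIV`, with group coded so a positive
statistic means lower volume in cases. The positive part of the t-map is
the atrophy pattern, the positive part of its negation the expansion
pattern, and both directions are analyzed with the identical machinery.

Specificity is assessed against a null distribution from degree-preserving
randomized networks (Maslov–Sneppen double edge swaps of the binary
topology, with the original edge-weight multiset randomly permuted onto
the rewired edges), and within-case symptom severity is related to
regional volumes by Bonferroni-corrected correlations.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `beta` | 1 | 1/time | diffusivity; only the product $\beta t$ matters, so $\beta$ is fixed at 1 and time absorbs the scale |
| `times` | `0:50` | model time | evaluation grid; unit step matches the integer horizons used in robustness checks |
| `n_modes` | 5 | — | leading eigenmodes correlated with the observed map |
| eigenmode threshold | p < 0.01 | — | fixed raw threshold for five modes (≈ 0.05/5), applied as stated rather than via a separate adjustment procedure |
| `n_nulls` | 1000 | — | rewired networks in the null distribution |
| `n_swaps_per_edge` | 10 | — | Maslov–Sneppen mixing; a common heuristic, configurable |

Model time is left in arbitrary units throughout: with $\beta = 1$ the
time axis has no physical calibration, and the exact identity
$\mathbf{x}(t;\beta) = \mathbf{x}(\beta t;1)$ makes any labeling of years
a presentation choice, not a model property.

Because of that identity the epicenter ranking is invariant to $\beta$
whenever the horizon covers the rescaled peak time. On a discrete unit
grid the invariance of the *peak correlation* is exact only when the
rescaled peak time lands on the grid; otherwise it holds to well below
reporting precision. The tests assert both forms separately.

## Design choices

* **Statistic fed to the NDM.** The t-value map is the default input
  pattern (the coefficient-estimate map is available via
  `statistic = "estimate"`). t-values fold per-region variance into the
  map, which is what the repetitive-seeding analysis consumes.
* **Sign convention.** `loss_positive`: the group term is coded
  control-minus-case, so positive means atrophy in cases. The convention
  is recorded in the result object and all outputs, and half-wave
  rectification of the map is then literally "set negative values to
  zero".
* **All regions enter the pattern.** FDR at 5% across regions is computed
  and reported, but is not used to mask the pattern; the diffusion
  analysis consumes the full rectified map.
* **Correlation families.** Pearson for the epicenter curves, Spearman for
  the eigenmode analysis; each independently configurable.
* **Null statistic.** Within each rewired network the null value is the
  maximum peak correlation over *all* seeds — the conservative choice —
  with a `scope = "candidate_seed"` switch for seed-specific nulls. The
  empirical p uses the add-one estimator $(1 + \#\{r_{null} \ge
  r_{emp}\})/(1+K)$, so it is never exactly zero; the raw proportion is
  reported alongside.
* **Disconnected nulls.** Rewiring can occasionally fragment a graph;
  the Laplacian is still defined and diffusion conserves within
  components, so null networks proceed with a logged warning rather than
  an error.
* **Tie-breaking.** Seeds tie first on peak correlation, then earlier
  peak time, then lower region index — fully deterministic rankings.

## Numerical choices

* Diffusion is evaluated from one cached eigendecomposition
  (`eigen(symmetric = TRUE)`), not repeated matrix exponentials; the test
  suite pins the spectral path to an independent scaling-and-squaring
  series evaluation of $e^{-\beta H t}$ at $10^{-8}$.
* A predicted pattern that is numerically constant (relative spread below
  $10^{-12}$) has no defined correlation; it is recorded as $r = 0$ with
  a flag rather than propagating NaN.
* The per-region residual variance in the contrast GLM is floored at
  $10^{-16}\,\overline{y^2}$ so that noise-free, perfectly fitting
  regions keep a finite t statistic proportional to the estimate instead
  of degenerating to 0/0. With any realistic noise the floor is inert.
* Asymmetries up to $10^{-9}$ (relative) in a loaded connectome are
  averaged away; anything larger is treated as a corrupt file and
  refused. Self-loops are stripped with a warning since the degree
  definition presumes off-diagonal connections. Whether an input matrix
  should be thresholded, log-transformed or density-normalized before
  analysis is deliberately left to the caller; the matrix is consumed as
  given.

## What the synthetic generator emulates

Real inputs for this analysis — a tractography template connectome and a
subject-level regional volume table — cannot be bundled, so the package
generates studies with known ground truth:

* a modular weighted connectome (stochastic-block structure, lognormal
  weights, guaranteed connected; the last module plays the role of
  subcortex);
* a two-group cohort whose case group *loses* volume along
  $\mathbf{x}(t^\ast)$ diffused from a chosen seed — the planted effect IS
  the forward model, so recovering the seed is a genuine inverse problem;
* a TIV confound, i.i.d. Gaussian measurement noise, and craving scores
  linearly coupled to designated subcortical regions.

Default study conditions: 46 regions in 4 modules, 60 cases vs 40
controls, planting at $t^\ast = 3$, effect scale 3.5 and noise SD 0.25
cm³. The plant time sits in the early transient on purpose: past roughly
$t = 10$ on a 46-node graph the diffused map is dominated by the
seed-independent $D^{1/2}\mathbf{1}$ stationary pattern and epicenter
identity is simply not present in the data. The effect/noise pair was
calibrated once so the rectified t-map carries moderate noise (planted
pattern correlation well below 1 but recoverable); a weaker regime with
pattern–truth correlation ≈ 0.6 (effect scale 2) is exercised in the
property tests. All randomness flows from one master seed through named
substreams (graph / cohort / noise / craving), so fixtures are
bit-reproducible.

What passing tests do **not** show about real data: the generator has no
spatial autocorrelation beyond the graph structure, no hemispheric
symmetry, no site or age structure, Gaussian rather than heavy-tailed
noise, and an exactly linear planted effect. Recovery rates here are an
upper bound on what identical machinery achieves on neuroimaging data.

## A worked run

```{r example}
spec <- synthetic_spec(rng_seed = 42)
cm   <- generate_connectome(spec)
L    <- build_laplacian(cm)
g    <- generate_cohort(spec, cm)

rc  <- fit_regional_glm(g)
pat <- rectify_contrast(rc, "atrophy")
fit <- fit_epicenter(L, pat, pattern_mode = "atrophy")
fit
head(summary(fit), 3)
```

```{r null, eval = FALSE}
# specificity against 1000 degree-preserving rewired networks
nd <- null_distribution(cm, pat, candidate_seed = fit$ranking[1],
                        n_nulls = 1000, rng_seed = 1)
nd
```

The whole pipeline, both directions plus eigenmodes, null and craving
stages, is one call:

```{r pipeline, eval = FALSE}
report <- run_pipeline(list(synthetic = spec, n_nulls = 1000),
                       out_dir = "ndm-report")
```

Problem sizes in the shipped tests and acceptance script — 46-region
graphs, 50–100 replicates, 1000-network nulls, 200 pure-noise null
calibration replicates at 100 nulls each — were chosen so the full
evidence base recomputes in a few minutes on a laptop core while keeping
every binomial margin meaningful.

## Limitations

The model is linear and single-seed by construction: no epidemic-style
saturation, no multi-focal onset, no fitting of $\beta$ or $t^\ast$ by
optimization (time is scanned on a grid). Nulls preserve degree but not
spatial embedding — spin-test or variogram nulls are out of scope. The
craving stage is plain correlation, not mediation or regression modeling.
Atlas semantics (which region is "cingulate") live entirely in the labels
file; the package is atlas-agnostic.
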