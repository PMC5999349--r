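---
title: "Statistical methods for deformability cytometry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for deformability cytometry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdcstats)
```

Real-time deformability cytometry (RT-DC) pushes suspended cells through a
narrow microfluidic channel at rates of about a thousand cells per second.
A high-speed camera records each cell; on-line image analysis stores its
contour (an ordered pixel polygon) and a bright-field patch. Two regions of
interest matter: the *reservoir*, where cells experience essentially no
shear, and the *channel*, where hydrodynamic stress deforms them. From
these raw observations this package derives per-cell features, screens
their distributions, separates sub-populations, and tests treatment
effects across biological replicates.

## Per-cell features from the contour

All geometric features are polygon functionals; coordinates are pixel
centers (origin top-left, `x` along the flow, `y` downward) scaled by the
pixel size in µm.

* **Area** `A` is the shoelace area of the contour (µm²).
* **Circularity / deformation.** `C = 2*sqrt(pi*A)/l` with `l` the
  perimeter of the *convex hull* of the contour, and `D = 1 - C`. The hull
  matters: a corrugated contour has an inflated raw perimeter, which would
  overstate the deformation. `C = 1` and `D = 0` for a circle. (A commonly
  reproduced shorthand for this formula, `2*pi*A/l`, is dimensionally
  inconsistent; the square-root form is the quantity that is 1 for a
  circle and is what `contour_deformation()` implements.)
* **Volume** `V` assumes rotational symmetry about the axis through the
  centroid along the flow. The contour is clipped into its halves below
  and above that axis; each half is revolved (Pappus: `2*pi*|ybar|*A_half`,
  exact for a polygon half), and the two estimates are averaged. The
  symmetry assumption is considered valid for cells up to ~90% of the
  channel width.
* **Bounding box** `Lx`, `Ly`: axis-aligned extents.
* **Inertia ratio** `I = Iyy/Ixx` of the enclosed area about the centroid
  (closed-form polygon moments, raw contour, no hull — the area integral
  is robust to pixelation); 1 for a circle, larger for cells elongated
  along the flow. The **orientation** is
  `phi = 0.5*atan2(2*Mxy, Iyy - Ixx)` in `(-pi/2, pi/2]`, with 0 returned
  for isotropic shapes where the expression degenerates to 0/0.
* **Area ratio** `Delta = A_hull/A_contour >= 1` gates convexity: modulus
  extraction only trusts events with `1.0 <= Delta <= 1.05`, because the
  underlying linear-elastic theory produces convex shapes only.
* **Symmetry ratios** `Sx`, `Sy`: signed area imbalance of the two halves
  produced by splitting at the centroid along (and orthogonal to) the
  flow axis; 0 for mirror-symmetric cells.
* **Brightness** `B`, `BStD`: mean and SD of raw gray values whose pixel
  centers fall inside the contour (even-odd rule); no background
  correction.
* **Haralick features**: 13 classical statistics of a symmetric,
  normalized gray-level co-occurrence matrix accumulated from distance-1
  pixel pairs (4 unique offsets) with *both* pixels in-mask. Gray values
  are re-binned to 16 equal-width levels over the declared bit depth
  [0, 255] by default; the bin count bounds the matrix size and is
  configurable. The source text does not fix a binning, so ours is stated
  explicitly and tested against a brute-force pair-enumeration oracle.

## Distribution screening

Biological noise is often multiplicative, so many RT-DC features are
closer to log-normal than normal. The screen orders the `n` values and
plots them against the standard-normal inverse CDF of the Filliben
order-statistic probabilities

`m_1 = 1 - 0.5^(1/n)`, `m_i = (i - 0.3175)/(n + 0.365)`,
`m_n = 0.5^(1/n)`.

The squared Pearson correlation `r2` of that probability plot is computed
for the raw and the natural-log-transformed values; whichever is more
linear wins the verdict. Two conventions deserve a note. First, the plot
abscissa must be the *inverse-CDF positions*, not the raw probabilities —
only then is the plot linear for Gaussian data. Second, the interior
denominator is `n + 0.365` (Filliben's constant, which makes the interior
exactly symmetric, `m_i + m_{n+1-i} = 1`); a transposed variant
(`n + 0.635`) circulates in the literature and breaks that symmetry, so
we do not use it. Ties are kept by a stable sort and never jittered.

## Mixture models and the overlap assay

Sub-populations are modeled as a K-component Gaussian mixture with full
covariance matrices, fitted by EM (`fit_gmm()`). Numerical choices: 10
k-means-seeded restarts, each run for a 25-iteration burn-in, the best
restart by log-likelihood iterated to convergence (relative tolerance
1e-6, cap 500 iterations); a ridge of 1e-6 is added to every covariance
update; components are reported sorted by their first mean coordinate so
labels are reproducible; posterior ties in assignment go to the lowest
component index. The two-phase restart schedule is an efficiency choice
only — the winning run's likelihood path is continuous, so the EM
monotonicity guarantee survives intact (and is asserted in the tests).

The number of components is chosen where
`BIC = -2*ln L + t*ln n` is minimal, with
`t = (K-1) + K*k + K*k*(k+1)/2` free parameters. The default search range
is K = 1..4. BIC can overestimate K on non-Gaussian data; seed medians are
used wherever that matters.

Clustering uses the feature pair (area, log deformation): area is close to
normal and deformation close to log-normal, so the log transform makes the
Gaussian component assumption tenable.

**Overlap metric.** Two populations are compared after *joint* z-scoring
(the two features have incommensurate units; pooling both populations
before standardizing keeps a single common scale). Each population is
summarized by the Gaussian density at its sample mean and covariance; its
region is where the density exceeds 20% of its maximum (an ellipse with
Mahalanobis radius `sqrt(-2*ln 0.2)`). With `a1` the area of the
stationary population's region and `a3` the shared area, the overlap is
`a3/a1*100` percent — deliberately referenced to the stationary
population, hence asymmetric. Areas are summed on a 512×512 grid spanning
the pooled data ±5 SD; a Monte-Carlo membership oracle in the tests bounds
the grid error below 2 percentage points. Sample-estimated (not fitted or
generating) parameters define the contours.

**Shrinking-separation assay.** Two 1000-event populations at a common
modulus of 2.5 kPa: population 1 stationary at mean area 70 µm²,
population 2 starting at 120 µm² and shrinking in 5 µm² steps, so it
slides along an isoelasticity line toward population 1. At each step the
assay measures the overlap, lets BIC choose K on (area, log D), assigns
events by maximum posterior, and scores
`accuracy = (TP + TN)/total`, maximized over the label-to-class bijection
(mixture labels are arbitrary). All events lumped into one cluster against
two equal populations gives exactly 0.5.

## The surrogate mechanical model

The full hydrodynamic theory that links cell size, stress and elasticity
to deformation is out of scope here; the package instead ships a
documented closed-form stand-in behind a small interface
(`surrogate_deformation()`):

`D = c * (Q*eta/W^3) * exp(A/A0) / E`

with flow rate `Q` (µl/s), effective viscosity `eta` (mPa s; supply the
shear-thinned value for your flow rate — e.g. a buffer at 15 mPa s at rest
runs near 5.4 mPa s at 0.16 µl/s in a 30 µm channel), channel width `W`
(µm), area `A` (µm²), modulus `E` (kPa), and constants `c = 360`,
`A0 = 150 µm²`. The form was chosen for its qualitative fidelity, not its
absolute accuracy:

* `D` rises monotonically with `A` at fixed `E`; isoelasticity lines in
  the (A, D) plane are convex, non-crossing, increasing curves;
* `D` falls as `1/E` and vanishes as `E` grows;
* a normal area contributes an exactly Gaussian term `A/A0` to `ln D` and
  a normal modulus a mild right skew — so normally distributed (A, E)
  inputs produce the right-skewed, approximately log-normal deformation
  distributions seen in practice. A power-law area dependence (`A^1.5`)
  was considered and rejected: at realistic area spreads the left skew of
  `ln A^1.5` cancels the modulus-driven right skew, destroying exactly
  the distributional behaviour the screen is meant to detect.
* Calibration places the reference population (area N(343, 80²) µm²,
  modulus N(7, 1.2²) kPa, 0.04 µl/s, 15 mPa s, 20 µm channel) at a median
  deformation near 0.04 — inside the small-deformation regime where the
  linear-elastic picture applies.

All modulus statements made with the surrogate are self-consistency
statements (round trips through the lookup table recover `E` to 1%),
never absolute kPa claims about real cells. `build_modulus_lut()`
tabulates `D` on an (A, E) grid and inverts it by monotone interpolation;
queries outside the grid, events failing the `Delta <= 1.05` convexity
gate, and (optionally) deformations above the 0.03 small-deformation
bound return `NA` rather than extrapolating.

## PCA screening

`pca_fit()` z-scores every feature (units are incommensurate — the same
reason the overlap metric normalizes) and eigendecomposes the correlation
structure; `pca_project()` returns scores with diagonal covariance.
Component signs are fixed by making the largest-magnitude loading entry
positive. The intended use is screening for rare sub-populations: the
planted-cluster generator (`gen_rare_subpopulation()`) hides a 1–3%
population of smaller, darker, texturally distinct cells among an
11-feature table, and the tests require ≥95% recall from a threshold in
the (PC1, PC2) plane. No automatic cluster labeling of the scores is
attempted.

## Differential deformation

Deformation in the channel alone confounds stress response with the
initial shape of the cell; cells cannot be tracked individually between
the reservoir and the channel. `bootstrap_dd()` therefore resamples each
region's deformation vector with replacement at its own sample size,
takes the median (pluggable: mean, trimmed mean) of each resample, and
records the difference channel − reservoir. At the default 1000+
iterations the bootstrap distribution is approximately Gaussian (central
limit theorem; the tests demand a probability-plot r² above 0.98), and
the raw (untransformed) deformation is used. Channel is always drawn
before reservoir within one seeded stream, so runs are bit-reproducible.
Each sample's bootstrap distribution can feed directly into the mixed
model below, with replicate as the grouping factor — a convention, since
alternatives (e.g. summarizing each replicate by its DD mean) would
discard the distribution's width.

## Replicate-aware significance

With thousands of events per measurement, a t-test declares trivially
small distributional offsets significant. The package instead fits

`value ~ condition + (1 | replicate) + (0 + condition | replicate)`

by maximum likelihood (lme4; ML rather than REML so likelihoods of nested
models are comparable): a fixed treatment effect, a random intercept for
each replicate's baseline level, and a random slope for each replicate's
treatment response. The null model drops only the fixed effect. Wilks'
theorem turns `-2*ln(L_null/L_full)` into a chi-squared statistic with one
degree of freedom. Random intercept and slope are independent by default
(`correlated = TRUE` switches to an unstructured 2×2 covariance; the
choice is exposed because neither is canonical). Incomplete pairing — two
replicates in one condition, three in the other — is handled by the
likelihood itself; no data are dropped. Replicate-condition cells with a
single observation are rejected outright. Because the slope variance sits
on its boundary under the null, the test runs slightly conservative;
the suite checks the empirical type-I error stays within [0.01, 0.10] at
nominal 0.05. P-values are reported per feature; no multiplicity
correction is applied across features.

## What the generators emulate — and what they do not

`gen_population()` draws (area, modulus) from the stated normals
(truncated positive by resampling, preserving continuity of D),
and maps them through the surrogate. `gen_two_population_assay()`
reproduces the assay protocol above. Two of its spreads are not stated by
the protocol and were fixed once as realistic values: a within-population
area SD of 7 µm² (≈10% CV, typical of a cell line) and a multiplicative
log-normal measurement noise on deformation with sdlog 0.05 (camera and
pixelation noise; with a perfectly constant modulus and no noise the
(area, ln D) cloud would collapse onto a zero-thickness curve and
densities would be degenerate). `gen_replicates()` draws per-replicate
random intercepts and slopes around a fixed effect, exactly the data
model the LMM assumes.

None of the generators emulate camera physics, segmentation artifacts,
discrete pixel-quantized features (e.g. integer bounding-box lengths, for
which a Gaussian mixture would be misspecified), cell-type-specific
feature correlations, or shear-thinning rheology (the effective viscosity
is a user input). A passing suite therefore demonstrates that the
*statistics* behave as documented under their own assumptions — not that
any particular real sample satisfies those assumptions.

## Problem sizes and runtime choices

The test suite and the acceptance script run the assay at its native size
(1000 events per population, 11 steps, K = 1..4) over 10 seed
replications, the distribution screen at n = 5000 over 20 seeds, the
type-I-error simulation with 500 null mixed-model fits (5+5 replicates,
30 observations per cell), and the power simulation with 200 fits. These
sizes keep Monte-Carlo error comfortably below every asserted margin
while the whole suite stays desk-scale on a single CPU.

## Known limitations

* The surrogate is qualitative; absolute moduli require the real
  hydrodynamic model, for which the interface leaves a slot.
* BIC's component count is occasionally overestimated near the detection
  threshold; medians over seeds are the supported summary.
* The Wilks p-value relies on an asymptotic chi-squared reference; with
  very few replicates it is approximate (and conservative near variance
  boundaries).
* The contour formats assume simple (non-self-intersecting) polygons;
  self-intersections are not detected.
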