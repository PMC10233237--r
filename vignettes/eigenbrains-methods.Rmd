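---
title: "Latent spatial factors, data-driven subtypes, and Z maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent spatial factors, data-driven subtypes, and Z maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenbrains)
```

## The analysis in one paragraph

Given co-registered brain volumes for a patient cohort and a control cohort
(canonically FDG-PET), each patient image is intensity-normalized to a
reference region (SUVR; for FDG the pons), median-centered and scaled by its
interquartile range, masked to brain tissue, and flattened into one row of a
subject-by-voxel matrix. A singular value decomposition of that matrix yields
latent spatial factors — "eigenbrains", unit-norm voxel-loading maps whose
opposing poles express relative hypo- versus hyper-metabolism — and one score
per subject and factor (the subject's "eigenvalue" in the clinical usage;
its sign is arbitrary up to a global flip per component). Components are
retained while their latent root exceeds 1, with a Monte-Carlo parallel
analysis available as a stricter alternative. Retained scores feed three
downstream analyses: standardized multivariable regressions against clinical
and cognitive variables; affinity propagation clustering of subjects into
data-driven subtypes (negative squared distances between standardized
scores, preference at the 10% similarity quantile, distance metric selected
by mean silhouette, exemplars agglomerated into a merge tree); and
voxel-wise Z-score maps of each subtype (or individual patient) against the
control cohort.

## Preprocessing and the subject matrix

SUVR normalization divides every voxel by the mean intensity inside the
reference-region mask, so the output has reference mean exactly 1. Robust
scaling is per subject, within the mask: quartiles are computed by linear
interpolation between order statistics (the common `type = 7` default, fixed
and recorded), and each row becomes `(x - median) / IQR`. A constant image
(zero IQR) is a hard error naming the subject. Voxels are flattened in a
fixed raster order recorded in the mask object (column-major, R's native
order); any fixed order works as long as it is identical across subjects.
The per-subject `(median, IQR)` pairs are kept as a scaling record so new
subjects can be projected with the same procedure.

Two practical consequences of this preprocessing shaped the rest of the
package and are worth stating explicitly:

* **Median-centering removes the constant image direction.** Any structure a
  generator plants along the constant direction is destroyed; conversely a
  planted factor with a nonzero spatial mean is silently replaced by its
  centered version. The synthetic generator therefore produces factor maps
  with zero mean over the mask.
* **IQR scaling homogenizes per-subject energy.** After scaling, every
  subject's row has comparable total variance. Subject-targeted variance
  structure (e.g. one subgroup with much larger loadings) is largely undone
  by this step; cluster structure survives in the *directions* of the score
  vectors, not their magnitudes.

## Decomposition, retention, and scores

The SVD is computed in the dual (subject-by-subject Gram) form when voxels
outnumber subjects — the eigendecomposition of `X X'` is exact and cheap at
cohort sizes — and directly otherwise; the two agree to numerical precision
and the direct form serves as the oracle in tests. No voxel-wise centering or
variance normalization is applied beyond the row scaling (covariance-style
decomposition); voxel centering is available behind `center_voxels` and a
correlation-style variant is intentionally out of scope. Each eigenbrain is
oriented so its largest-magnitude voxel loading is positive: direction
carries no meaning, and the convention makes runs reproducible.

Latent roots rescale the component variances so that a same-size random
spectrum averages 1: `root_i = s_i^2 * min(n - 1, p) / sum(s^2)`. The default
retention rule keeps the prefix of components with root strictly above 1.
Parallel analysis draws `n_iter` standard-normal matrices of identical
dimensions, takes a per-component percentile (default 95) of their latent
roots, and keeps the longest prefix of observed roots exceeding their null
thresholds; it is reproducible under a seed and calibrated to retain nothing
on pure noise.

Scores can be rescaled to within-cohort 0–100 percentiles (rank-based, ties
averaged) for patient-level reporting.

## Brain–behavior statistics

Cognitive-domain composites are the arithmetic mean of available scaled
scores; missing tests are skipped, a fully missing domain is missing, and
discontinued tests are expected to be coded at the floor scaled score (1)
before entry. One regression is fit per outcome: the outcome and all
retained score columns are z-scored on the listwise-complete subsample, and
ordinary least squares yields standardized betas, their two-sided t-tests
(no multiple-testing correction — none is stated for the original analyses;
flagged here), R², adjusted R², and the omnibus F p-value. With orthogonal
score columns each standardized beta equals the simple correlation between
that component and the outcome — a property the tests verify to 1e-8.
Group comparisons use one-way ANOVA with Tukey's honestly-significant-
difference post-hocs in the Tukey–Kramer form (subtype sizes are unbalanced)
and Pearson chi-square for categorical variables. Spatial decoding of an
eigenbrain against named reference maps is a masked Pearson correlation,
deliberately descriptive: no significance testing is performed, and
interpretation should weigh direction and relative strength.

## Subtyping by affinity propagation

Retained score columns are standardized per component ("scaled
eigenvalues"); a singular-value-weighted alternative exists behind a flag
but is not the default. Pairwise distances (euclidean, manhattan, or
1 − Pearson correlation across components) become similarities via
`s(i,k) = -d(i,k)^2`, the diagonal (preference) is the 10% quantile of the
off-diagonal similarities — low preferences discourage many small clusters —
and Frey–Dueck responsibility/availability message passing runs with damping
0.9 until the exemplar set is stable for 200 sweeps (2000 maximum; a
non-converged run is flagged, not hidden). A tiny seeded noise
(1e-12 × similarity range) breaks degeneracies reproducibly. After
convergence the standard k-medoids polish re-selects the best exemplar
within each cluster and reassigns until stable; this measurably tightens the
net similarity (on 200 random small instances the ensemble shortfall versus
the exhaustive exemplar-set optimum drops to 0.3%, matching the reference
`apcluster` implementation instance-for-instance). Exemplars are then
agglomerated: the pair of clusters maximizing the average similarity of the
merged members to the best joint exemplar is merged repeatedly, recording a
dendrogram-compatible merge list.

The distance metric is selected by the highest mean silhouette (computed on
that metric's own distances; ties resolve in the documented order euclidean,
manhattan, correlation). Whether the original analysis used mean or median
silhouette, on distances or similarities, is not stated; we fixed mean on
distances. Two structural facts about this comparison emerged during design
and are documented because they affect interpretation: correlation distances
between angularly separated clusters shrink quadratically with within-cluster
angular spread, which systematically inflates the correlation metric's
silhouette on well-separated standardized score clouds; and on collinear
(severity-gradient) geometries the manhattan metric's silhouette dominates
the euclidean one whenever the separation direction is dense in components.
A selected metric should therefore be read as "best by this criterion", not
as evidence that the geometry is intrinsically correlation- or L1-shaped.
The subtype count is whatever affinity propagation returns at the 10%
preference quantile; there is no post-hoc forcing to a target number.

## Z-score maps

The control reference holds the per-voxel mean and sample standard deviation
(ddof 1) over controls within the mask; voxels with zero control sd are
excluded via a validity mask rather than producing infinities. A group map is
`(mean of patients - control mean) / control sd` per voxel — the control sd,
not a pooled sd — and an individual map is the same with a single subject.
Maps are invariant to any common affine intensity rescaling of all controls
and patients. Display thresholding censors voxels failing a criterion
(below / above / two-sided) and reports the survivor count; the mapping
between a nominal significance level and a Z threshold is left to the caller.
Note the two map levels have different null scales: an individual map has
unit voxel sd under the null (up to the `sqrt(1 + 1/n)` factor), while a
group map of `m` patients has sd `~ sqrt(1/m + 1/n)` — about 0.28 at 26 per
group — so "Z near 1 under the null" is a statement about individual maps.

## The synthetic world: what it emulates and what it does not

The generator states one world and keeps it fixed: 52 patients in four
subtypes of sizes 21/19/7/5 plus 52 controls on a 30×36×30 grid (about
10,000 masked voxels inside an ellipsoidal brain mask with a small spherical
reference region standing in for the pons); six smooth orthonormal spatial
factors (Gaussian random fields, smoothing sigma 2.5 voxels, zero mean over
the mask); subject images `baseline + loadings · factors + noise` with
baseline 10 and per-voxel noise sd 0.12; clinical variables generated
linearly from standardized loadings with planted standardized coefficients
(magnitudes in the range reported for real factor-cognition associations),
mapped to natural units, with per-variable missingness (none for
demographics, 0.35 for cognitive scores, matching the attrition pattern of
real cohorts).

The loading structure follows from three identifiability constraints, worked
out during design and frozen:

1. **Rank.** With four clusters, the space of cluster-label functions has
   rank 4; at most three weight-centered components can separate subtypes,
   plus one non-separating common offset along the constant direction. The
   default plants separation on components 1, 3 and 5 using patterns made
   mutually orthogonal under cluster-size weights (this keeps the planted
   loading covariance diagonal, which is exactly the condition for the
   planted factors to be the population principal axes), a common offset on
   the last component, and pure within-cluster spread on components 2 and 4.
2. **Retention compatibility.** The latent-root rule caps how fast the
   planted variance spectrum may decay: the smallest of six components must
   keep a root above 1, which bounds the spectrum ratio near 1.7–1.8 per
   step. The default second moments are (710, 417, 245, 144, 85, 50).
3. **Sampling noise at n = 52.** Pure-spread components have sample
   variances fluctuating by tens of percent at this cohort size, so the
   spread components are interleaved between the stable structured ones and
   the retention-critical last component is a stable offset.

These constraints interact: a retention-compatible spectrum plus i.i.d.
Gaussian loadings leaves adjacent components within sampling-collision
range, so per-factor recovery at 0.9 absolute correlation is exercised on a
cohort whose loadings are structured by eight balanced latent groups
(Hadamard sign patterns at the same descending amplitudes) — "cluster-
structured subject loadings", which suppress the variance and cross-moment
sampling noise by an order of magnitude. Conversely, the between-cluster
variance budget over six standardized components is capped at roughly 3 of 6
units in any basis (the rank argument again), which makes a 21-subject
subtype's split gain comparable to one exemplar preference at the 10%
quantile; subtype recovery through the full image pipeline is therefore
structurally marginal in any Gaussian world of this shape, and the
cluster-recovery guarantee is instead exercised where it is well-posed: in
score space with planted clusters separated by at least eight within-cluster
standard deviations, where every metric recovers the partition exactly.
A green test establishes recovery in the stated world at the tested seed;
it does not establish that real cohorts of this size yield stable subtypes,
and the generator makes no attempt at PET physics, partial-volume effects,
spatial registration error, or site effects.

## Numerical choices and degenerate inputs

Quartiles use interpolation type 7 everywhere a quantile appears (robust
scaling, preference, parallel-analysis thresholds). The numerical rank of
the subject matrix discards singular values below `1e-7` of the largest;
degenerate (rank-deficient) inputs return fewer components rather than
failing. Tied singular values are ordered by first occurrence. Constant
outcomes, constant score columns, single-cluster silhouettes, zero-IQR
images, empty masks, non-positive reference means, and 4D NIfTI inputs are
explicit errors; coincident points in the silhouette yield 0 with a warning;
a group entirely missing from an ANOVA is dropped with a warning. All
randomness — factor fields, loadings, noise, clinical residuals,
missingness, parallel-analysis nulls, and the affinity-propagation
degeneracy noise — derives from explicit seeds, and pipeline outputs record
them.

## Known limitations

* The minimal NIfTI-1 reader handles 3D single-file volumes (gzip, both
  endiannesses, common datatypes, scl slopes, sform affines) and nothing
  more; it exists because the execution environment provides no R NIfTI
  package.
* Spatial registration, smoothing and template construction are out of
  scope: all volumes must already share a grid.
* The affinity propagation preference couples cluster count to the
  similarity distribution; at the fixed 10% quantile, partitions of weakly
  separated cohorts are sensitive to sampling, and the package reports
  convergence flags and silhouettes rather than pretending otherwise.
* Per-beta p-values are uncorrected for multiple testing, mirroring the
  analysis framework this package implements; users comparing many outcomes
  should apply their own correction.
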