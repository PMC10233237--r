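# eigenbrains

Data-driven phenotyping of brain-imaging cohorts from voxel-wise latent
factors. The package targets the analysis style used to dissect
clinico-radiological heterogeneity in dementia syndromes from FDG-PET: a
cohort of patient volumes is reduced to a small set of latent spatial
factors ("eigenbrains"), per-subject factor scores are related to clinical
and cognitive variables and clustered into subtypes, and each subtype is
rendered as a voxel-wise Z-score map against a control cohort. Everything is
exercisable end-to-end on a synthetic cohort with known ground truth, so no
patient data are required to validate the machinery.

## The model

Let `X` be the `n x p` subject-by-voxel matrix of masked, reference-region
normalized (SUVR), per-subject median/IQR-scaled images. Its SVD

```
X = U D V',   scores = U D,   eigenbrains = rows of V'
```

gives unit-norm voxel-loading maps (eigenbrains `EB1..EBK`, each expressing
opposing poles of relative hypo-/hyper-metabolism) and one score per subject
and component (the subject's "eigenvalue"; sign arbitrary up to a global
flip). Components are retained while their latent root — the component
variance scaled so a same-size random spectrum averages 1 — exceeds 1
(`latent_root_retention()`), or by Monte-Carlo parallel analysis
(`parallel_analysis()`). Downstream:

* `fit_multivariable()` — standardized OLS of each clinical outcome on the
  retained scores (listwise deletion, standardized betas, omnibus F);
* `select_metric()` / `affinity_propagation()` — subtypes by Frey–Dueck
  affinity propagation on similarities `s(i,k) = -d(i,k)^2` between
  standardized scores, preference at the 10% similarity quantile, distance
  metric chosen by mean silhouette, exemplars agglomerated into a merge
  tree (`agglomerate_exemplars()`);
* `control_reference()` / `zmap_group()` / `zmap_individual()` — voxel-wise
  `Z(v) = (mean_patients(v) - mean_controls(v)) / sd_controls(v)` maps for
  any co-registered modality.

## Worked example

```r
library(eigenbrains)

cohort <- simulate_cohort(seed = 42)   # 52 patients (21/19/7/5), 52 controls
patients <- lapply(cohort$patient_volumes, suvr_normalize,
                   reference = cohort$reference)
sm <- build_subject_matrix(patients, cohort$mask)
decomp <- eb_decompose(sm)
ret <- latent_root_retention(decomp)
ret
#> retention_result: 6 components retained (rule: latent_root_gt1 )

scores <- decomp$scores[, 1:ret$n_retained]
fit_multivariable(scores, cohort$clinical$stms, "stms")
#> regression_result: stms (n = 47)  R2 = 0.546  R2adj = 0.477  p = 1.05e-05
#>    EB1    EB2    EB3    EB4    EB5    EB6
#> -0.411 -0.310  0.501  0.206 -0.002  0.106

sel <- select_metric(scores, seed = 42)
sel$best
#> clustering_result: 5 clusters, exemplars: 10, 32, 33, 42, 52 (converged)
#>   mean silhouette: 0.482

controls <- lapply(cohort$control_volumes, suvr_normalize,
                   reference = cohort$reference)
ref <- control_reference(controls, cohort$mask)
zmap_group(patients[sel$best$labels == 1], ref, id = "subtype_1")
#> zmap (group): subtype_1, Z range [-7.12, 11.06] over 10120 valid voxels
```

Reading the output: six components clear the latent-root threshold and carry
about 92% of the covariance; the cognitive-screen outcome (`stms`, generated
with planted standardized coefficients `(-0.45, -0.15, 0.35, 0.15, 0, 0)` on
the true loadings) is recovered with the expected sign pattern on the
corresponding estimated components; affinity propagation at the 10%
preference quantile returns five subtypes here — subtype recovery through
the full image pipeline is structurally marginal at these cohort sizes, a
point analyzed in the methods vignette, which is why the clustering
guarantees are validated in score space (see `tests/testthat/test-acceptance.R`,
criterion 5, where the planted 21/19/7/5 partition is recovered with
adjusted Rand index 1.0). The Z map summarizes subtype 1 against the 52
controls over the 10,120 masked voxels.

The full pipeline (normalize → matrix → decompose → retain → regress →
cluster → Z maps → manifest) runs from one config:

```r
dir <- tempfile(); write_cohort(simulate_cohort(seed = 42), dir)
cfg <- pipeline_config(
  patients = file.path(dir, "patients"), controls = file.path(dir, "controls"),
  brain_mask = file.path(dir, "brain_mask.nii.gz"),
  reference_mask = file.path(dir, "reference_mask.nii.gz"),
  clinical = file.path(dir, "clinical.csv"),
  outcomes = c("age_at_onset", "stms"), categorical = "sex", seed = 42)
manifest <- run_pipeline(cfg, file.path(dir, "out"))
```

A command-line wrapper with `simulate` and `run-all` subcommands is in
`inst/cli/eigenbrains-cli.R`.

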