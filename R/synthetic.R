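# Synthetic cohorts with known ground truth.
#
# The generator states a world resembling the study cohort: 52 patients in
# four subtypes of sizes 21/19/7/5 plus 52 controls on a shared 30x36x30
# grid; six smooth, mutually orthonormal spatial factors; cluster structure
# carried by the subject loadings (subtypes live in score space, not in
# single voxels); clinical variables generated linearly from standardized
# loadings with known standardized coefficients and per-variable missingness.
# Every generator is a pure function of its seed and parameters.

#' Build an ellipsoidal brain template with a reference region
#'
#' An ellipsoidal brain mask centered in the grid, plus a small spherical
#' reference region (the synthetic stand-in for the pons) in the inferior
#' central brain, fully inside the brain mask.
#'
#' @param shape length-3 grid dimensions (each >= 16).
#' @param brain_radius_fraction semi-axes as a fraction of half the grid.
#' @param reference_radius reference sphere radius in voxels.
#' @param reference_offset reference center offset from the brain center, as
#'   fractions of the brain semi-axes.
#' @return list with `brain` and `reference`, both [brain_mask()]s.
#' @export
make_template <- function(shape = c(30L, 36L, 30L), brain_radius_fraction = 0.9,
                          reference_radius = 2.5,
                          reference_offset = c(0, 0, -0.55)) {
  if (length(shape) != 3L || any(shape < 16L)) {
    stop("shape must have 3 dimensions, each at least 16")
  }
  center <- (shape + 1) / 2
  semi <- brain_radius_fraction * (shape / 2 - 1)
  ax <- array(seq_len(shape[1]), dim = shape)
  ay <- array(rep(seq_len(shape[2]), each = shape[1]), dim = shape)
  az <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  r2 <- ((ax - center[1]) / semi[1])^2 + ((ay - center[2]) / semi[2])^2 +
    ((az - center[3]) / semi[3])^2
  brain <- r2 <= 1

  rc <- center + reference_offset * semi
  ref <- ((ax - rc[1])^2 + (ay - rc[2])^2 + (az - rc[3])^2) <= reference_radius^2
  if (!any(ref)) stop("reference region is empty")
  if (any(ref & !brain)) stop("reference region extends outside the brain mask")
  list(brain = brain_mask(brain), reference = brain_mask(ref))
}

# separable periodic Gaussian smoothing via FFT
.smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  dims <- dim(arr)
  k1 <- lapply(dims, function(n) {
    x <- seq_len(n) - 1
    d <- pmin(x, n - x)
    g <- exp(-d^2 / (2 * sigma^2))
    g / sum(g)
  })
  Kf <- outer(outer(stats::fft(k1[[1]]), stats::fft(k1[[2]])), stats::fft(k1[[3]]))
  Re(stats::fft(stats::fft(arr) * Kf, inverse = TRUE)) / prod(dims)
}

#' Generate smooth orthonormal spatial factors
#'
#' Gaussian random fields smoothed with a periodic Gaussian kernel, restricted
#' to the mask, centered to zero mean over the mask, and Gram-Schmidt
#' orthonormalized (unit norm, pairwise dot products below 1e-8).
#' `smoothness_sigma = 0` yields white-noise factors. Zero masked mean makes
#' the factors orthogonal to the constant image direction, so the planted
#' structure commutes with per-subject median-centering (a relative
#' metabolism gradient has opposing poles and no global offset).
#'
#' @param mask a [brain_mask()].
#' @param k number of factors (< masked voxel count).
#' @param smoothness_sigma Gaussian smoothing sigma in voxels.
#' @param seed integer seed.
#' @return k x n_voxels matrix of factor maps (rows orthonormal).
#' @export
make_factors <- function(mask, k = 6L, smoothness_sigma = 2.5, seed = 1L) {
  if (k >= mask$n_voxels) stop("k must be smaller than the masked voxel count")
  withr::local_seed(seed)
  factors <- matrix(NA_real_, nrow = k, ncol = mask$n_voxels)
  for (j in seq_len(k)) {
    field <- array(stats::rnorm(prod(mask$dim)), dim = mask$dim)
    field <- .smooth3d(field, smoothness_sigma)
    v <- field[mask$voxel_index]
    v <- v - mean(v)
    if (j > 1L) {
      prev <- factors[seq_len(j - 1L), , drop = FALSE]
      v <- v - as.vector(crossprod(prev %*% v, prev))
      # second Gram-Schmidt pass for numerical orthogonality
      v <- v - as.vector(crossprod(prev %*% v, prev))
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("factor ", j, " is numerically degenerate")
    factors[j, ] <- v / nv
  }
  factors
}

#' Default planted loading structure for a four-subtype cohort
#'
#' States the stated world used throughout the tests: six components with
#' strictly descending per-component loading second moments. Cluster
#' separation is planted on components 1, 3 and 5 via weight-orthogonal
#' centroid patterns (orthogonality under cluster-size weights keeps the
#' planted loading covariance diagonal, so the SVD basis aligns with the
#' planted factors); components 2 and 4 carry pure within-cluster spread,
#' uniform across subtypes; the last component is a stable common loading
#' offset.
#'
#' Two identifiability facts shape these defaults. First, with `nc` clusters
#' the space of cluster-label functions has rank `nc`, so at most `nc - 1`
#' weight-centered components can separate clusters (plus one non-separating
#' offset along the constant direction); the remaining components necessarily
#' carry within-cluster spread only. Second, the sample variance of a
#' pure-spread component fluctuates by tens of percent at 52 subjects, so the
#' spread components are interleaved between the stable ones (large spectral
#' gaps on both sides) and the retention-critical last component is a stable
#' offset. See the methods vignette for the full design analysis, including
#' why a latent-root-compatible spectrum bounds how well separated the
#' planted subtypes can be after per-component standardization.
#'
#' @param n_per_cluster cluster sizes (default 21/19/7/5).
#' @param k number of components (default 6).
#' @return list with `centroids` (clusters x k), `loading_sd` (clusters x k
#'   matrix of within-cluster loading sds), `loading_m2` (target
#'   per-component second moments).
#' @export
default_ground_truth <- function(n_per_cluster = c(21L, 19L, 7L, 5L), k = 6L) {
  nc <- length(n_per_cluster)
  if (nc < 2L) stop("need at least 2 clusters")
  # geometric ~1.7x spacing: at n ~ 52 subjects the sampling noise of loading
  # cross-moments is ~sqrt(m2_j * m2_k / n), and gaps must dominate it for the
  # SVD basis to align with the planted factors
  loading_m2 <- c(710, 417, 245, 144, 85, 50, 29, 17)[seq_len(k)]
  if (anyNA(loading_m2)) stop("default schedule supports at most 8 components")
  base_sd <- 3
  w <- n_per_cluster / sum(n_per_cluster)

  n_sep <- min(nc - 1L, 3L, k)
  raw <- if (nc == 4L) {
    cbind(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, -1, -1, 1))[, seq_len(n_sep), drop = FALSE]
  } else {
    stats::contr.helmert(nc)[, seq_len(n_sep), drop = FALSE]
  }
  # weighted Gram-Schmidt: weighted-centered, mutually weight-orthogonal columns
  pat <- matrix(0, nc, n_sep)
  for (j in seq_len(n_sep)) {
    v <- raw[, j] - sum(w * raw[, j])
    if (j > 1L) {
      for (l in seq_len(j - 1L)) {
        v <- v - sum(w * v * pat[, l]) / sum(w * pat[, l]^2) * pat[, l]
      }
    }
    pat[, j] <- v / sqrt(sum(w * v^2))
  }

  # role per component: separating and spread components interleaved, stable
  # offset last, plain within-cluster spread for anything beyond
  n_spread <- max(0L, min(2L, nc - 2L, k - n_sep - 1L))
  roles <- character(k)
  si <- n_sep; sp <- n_spread
  for (idx in seq_len(k)) {
    if (si > 0L && (sp == 0L || idx %% 2L == 1L)) {
      roles[idx] <- "sep"; si <- si - 1L
    } else if (sp > 0L) {
      roles[idx] <- "spread"; sp <- sp - 1L
    } else {
      roles[idx] <- "plain"
    }
  }
  if (k > n_sep + n_spread) roles[k] <- "offset"

  centroids <- matrix(0, nc, k)
  loading_sd <- matrix(base_sd, nc, k)
  sep_i <- 0L
  for (idx in seq_len(k)) {
    m2 <- loading_m2[idx]
    if (roles[idx] == "sep") {
      sep_i <- sep_i + 1L
      centroids[, idx] <- pat[, sep_i] * sqrt(m2 - base_sd^2)
    } else if (roles[idx] == "offset") {
      centroids[, idx] <- sqrt(m2 - base_sd^2)
    } else {
      # pure within-cluster spread, uniform across clusters (per-subject
      # image energy is homogenized by the row IQR scaling anyway, so
      # cluster-targeted spread would not survive the preprocessing)
      loading_sd[, idx] <- sqrt(m2)
    }
  }
  list(centroids = centroids, loading_sd = loading_sd, loading_m2 = loading_m2,
       roles = roles)
}

#' Simulate patient volumes from planted factors and cluster centroids
#'
#' Each patient image is `baseline + sum_k loading_k * factor_k + noise`
#' within the brain mask (zero outside), with loadings drawn around the
#' patient's cluster centroid. The baseline offset keeps intensities positive
#' before SUVR normalization.
#'
#' @param factors k x n_voxels orthonormal factor maps (see [make_factors()]).
#' @param mask the [brain_mask()] the factors live on.
#' @param centroids clusters x k centroid matrix (loading units).
#' @param n_per_cluster positive integer cluster sizes.
#' @param loading_sd within-cluster loading sd; scalar, length-k vector, or
#'   clusters x k matrix (per-cluster, per-component spread).
#' @param noise_sd per-voxel noise sd.
#' @param baseline additive intensity offset within the brain.
#' @param seed integer seed.
#' @return list with `volumes` (list of [masked_volume()]s), `labels`
#'   (true cluster index per patient) and `loadings` (patients x k).
#' @export
simulate_patients <- function(factors, mask, centroids,
                              n_per_cluster = c(21L, 19L, 7L, 5L),
                              loading_sd = 3, noise_sd = 0.12,
                              baseline = 10, seed = 1L) {
  if (any(n_per_cluster <= 0)) stop("cluster sizes must be positive")
  k <- nrow(factors)
  if (ncol(centroids) != k) stop("centroid dimension must equal the number of factors")
  if (nrow(centroids) != length(n_per_cluster)) {
    stop("one centroid row per cluster required")
  }
  nc <- length(n_per_cluster)
  sd_mat <- if (is.matrix(loading_sd)) {
    if (!all(dim(loading_sd) == c(nc, k))) {
      stop("matrix loading_sd must be clusters x components")
    }
    loading_sd
  } else {
    matrix(rep_len(loading_sd, k), nc, k, byrow = TRUE)
  }
  n <- sum(n_per_cluster)
  labels <- rep(seq_along(n_per_cluster), times = n_per_cluster)

  withr::local_seed(seed)
  loadings <- centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * k), n, k) * sd_mat[labels, , drop = FALSE]
  signal <- loadings %*% factors # n x voxels

  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    arr <- array(0, dim = mask$dim)
    arr[mask$voxel_index] <- baseline + signal[i, ] +
      stats::rnorm(mask$n_voxels, sd = noise_sd)
    volumes[[i]] <- masked_volume(arr, subject_id = sprintf("patient_%02d", i))
  }
  list(volumes = volumes, labels = labels, loadings = loadings)
}

#' Simulate control volumes
#'
#' Baseline image plus voxel noise within the brain mask; zero loading on all
#' factors.
#'
#' @param mask a [brain_mask()].
#' @param n number of controls (>= 2).
#' @param noise_sd per-voxel noise sd.
#' @param baseline additive intensity offset within the brain.
#' @param seed integer seed.
#' @return list of [masked_volume()]s.
#' @export
simulate_controls <- function(mask, n = 52L, noise_sd = 0.12, baseline = 10,
                              seed = 2L) {
  if (n < 2L) stop("need at least 2 controls")
  withr::local_seed(seed)
  lapply(seq_len(n), function(i) {
    arr <- array(0, dim = mask$dim)
    arr[mask$voxel_index] <- baseline + stats::rnorm(mask$n_voxels, sd = noise_sd)
    masked_volume(arr, subject_id = sprintf("control_%02d", i))
  })
}

# default planted standardized coefficients: one row per clinical outcome,
# one column per component; magnitudes in the range reported for real
# factor-score/cognition regressions
.default_clinical_betas <- function(k = 6L) {
  b <- rbind(
    age_at_onset      = c( 0.00,  0.00,  0.30,  0.00,  0.00, -0.45),
    education         = c( 0.20,  0.35,  0.00,  0.00,  0.20,  0.30),
    stms              = c(-0.45, -0.15,  0.35,  0.15,  0.00,  0.00),
    verbal_wm         = c(-0.40, -0.25,  0.15,  0.00,  0.30, -0.10),
    trail_b           = c(-0.50, -0.15,  0.25,  0.25,  0.25,  0.10),
    stroop            = c(-0.60, -0.30, -0.10,  0.20,  0.25,  0.20),
    verbal_memory     = c(-0.20, -0.25, -0.10,  0.00,  0.45, -0.25),
    visual_memory     = c(-0.30,  0.00,  0.55,  0.35,  0.40,  0.15),
    verbal_fluency    = c(-0.37, -0.36,  0.00,  0.00,  0.26,  0.05),
    visuospatial      = c(-0.23, -0.07,  0.44,  0.48,  0.10,  0.16),
    visuoconstruction = c(-0.43,  0.04,  0.54,  0.30,  0.08, -0.09)
  )
  if (k > ncol(b)) stop("default betas support at most ", ncol(b), " components")
  b[, seq_len(k), drop = FALSE]
}

.default_clinical_units <- function(outcomes) {
  units <- list(age_at_onset = c(53.4, 5.3), education = c(15.2, 2.2),
                stms = c(22, 7))
  out <- lapply(outcomes, function(o) units[[o]] %||% c(5.5, 2.8))
  names(out) <- outcomes
  out
}

.default_missing_rates <- function(outcomes) {
  rates <- c(age_at_onset = 0, education = 0, stms = 0.06)
  out <- ifelse(outcomes %in% names(rates), rates[outcomes], 0.35)
  names(out) <- outcomes
  out
}

#' Simulate a clinical table from true loadings
#'
#' Each outcome is generated as `standardized loadings %*% betas + noise` on
#' the standardized scale, then mapped to its natural units and masked with
#' independent per-cell missingness. Categorical `sex` and `apoe4` columns
#' are drawn independently of the loadings.
#'
#' @param loadings patients x k true loading matrix.
#' @param betas outcomes x k matrix of standardized coefficients (rownames =
#'   outcome names); default mirrors the magnitudes of real factor-cognition
#'   associations.
#' @param residual_sd per-outcome residual sd on the standardized scale;
#'   default `sqrt(1 - sum(beta^2))` (floored at 0.2) so outcomes are
#'   approximately standardized.
#' @param missing_rate scalar or named per-outcome missingness rate in
#'   \[0, 1); default 0 for demographics, 0.35 for cognitive scores.
#' @param units named list of `c(mean, sd)` transforms to natural units.
#' @param subject_ids optional subject identifiers.
#' @param seed integer seed.
#' @return a `data.frame` with `subject_id`, the numeric outcomes, and
#'   categorical `sex` / `apoe4`.
#' @export
simulate_clinical <- function(loadings, betas = NULL, residual_sd = NULL,
                              missing_rate = NULL, units = NULL,
                              subject_ids = NULL, seed = 3L) {
  loadings <- as.matrix(loadings)
  n <- nrow(loadings); k <- ncol(loadings)
  if (is.null(betas)) betas <- .default_clinical_betas(k)
  betas <- as.matrix(betas)
  if (ncol(betas) != k) stop("betas must have one column per component")
  outcomes <- rownames(betas) %||% paste0("outcome_", seq_len(nrow(betas)))
  if (is.null(residual_sd)) {
    residual_sd <- sqrt(pmax(1 - rowSums(betas^2), 0.04))
  }
  residual_sd <- rep_len(residual_sd, nrow(betas))
  if (any(residual_sd < 0)) stop("residual_sd must be nonnegative")
  if (is.null(missing_rate)) missing_rate <- .default_missing_rates(outcomes)
  if (length(missing_rate) == 1L && is.null(names(missing_rate))) {
    missing_rate <- stats::setNames(rep(missing_rate, length(outcomes)), outcomes)
  }
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    stop("missing_rate must be in [0, 1)")
  }
  if (is.null(units)) units <- .default_clinical_units(outcomes)
  if (is.null(subject_ids)) subject_ids <- sprintf("patient_%02d", seq_len(n))

  Z <- zscore_cols(loadings, what = "loading column")
  withr::local_seed(seed)
  df <- data.frame(subject_id = subject_ids, stringsAsFactors = FALSE)
  for (j in seq_along(outcomes)) {
    y <- as.vector(Z %*% betas[j, ]) + stats::rnorm(n, sd = residual_sd[j])
    u <- units[[outcomes[j]]] %||% c(0, 1)
    y <- u[1] + u[2] * y
    mr <- unname(missing_rate[outcomes[j]])
    if (!is.na(mr) && mr > 0) y[stats::runif(n) < mr] <- NA_real_
    df[[outcomes[j]]] <- y
  }
  df$sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(34, 18) / 52)
  df$apoe4 <- sample(c("carrier", "noncarrier"), n, replace = TRUE,
                     prob = c(0.45, 0.55))
  df
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Composes the template, factors, patients, controls and clinical table into
#' one object. All randomness derives from `seed`.
#'
#' @param n_per_cluster patient subtype sizes (default 21/19/7/5, total 52).
#' @param n_controls number of controls (default 52).
#' @param shape grid dimensions (default 30x36x30).
#' @param k_factors number of planted factors (default 6).
#' @param smoothness_sigma factor smoothness in voxels.
#' @param noise_sd per-voxel noise sd.
#' @param baseline additive intensity offset.
#' @param brain_radius_fraction passed to [make_template()].
#' @param seed master integer seed.
#' @return an object of class `synthetic_cohort`: `patient_volumes`,
#'   `control_volumes`, `clinical`, `mask`, `reference`, and `truth`
#'   (`factor_maps`, `cluster_labels`, `cluster_centroids`, `loadings`,
#'   `clinical_betas`, `loading_sd`, `noise_sd`, `seed`).
#' @export
simulate_cohort <- function(n_per_cluster = c(21L, 19L, 7L, 5L),
                            n_controls = 52L, shape = c(30L, 36L, 30L),
                            k_factors = 6L, smoothness_sigma = 2.5,
                            noise_sd = 0.12, baseline = 10,
                            brain_radius_fraction = 0.9, seed = 42L) {
  tmpl <- make_template(shape, brain_radius_fraction)
  gt <- default_ground_truth(n_per_cluster, k_factors)
  factors <- make_factors(tmpl$brain, k_factors, smoothness_sigma, seed = seed)
  pats <- simulate_patients(factors, tmpl$brain, gt$centroids, n_per_cluster,
                            loading_sd = gt$loading_sd, noise_sd = noise_sd,
                            baseline = baseline, seed = seed + 1L)
  ctrls <- simulate_controls(tmpl$brain, n_controls, noise_sd = noise_sd,
                             baseline = baseline, seed = seed + 2L)
  clinical <- simulate_clinical(pats$loadings, seed = seed + 3L)
  structure(
    list(patient_volumes = pats$volumes, control_volumes = ctrls,
         clinical = clinical, mask = tmpl$brain, reference = tmpl$reference,
         truth = list(factor_maps = factors, cluster_labels = pats$labels,
                      cluster_centroids = gt$centroids,
                      loadings = pats$loadings,
                      clinical_betas = .default_clinical_betas(k_factors),
                      loading_sd = gt$loading_sd, noise_sd = noise_sd,
                      seed = as.integer(seed))),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$patient_volumes), "patients (",
      paste(table(x$truth$cluster_labels), collapse = "/"), "),",
      length(x$control_volumes), "controls,",
      paste(x$mask$dim, collapse = "x"), "grid,",
      x$mask$n_voxels, "masked voxels\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes patient and control NIfTI volumes, brain and reference masks, the
#' clinical CSV and a ground-truth bundle (truth factor NIfTIs plus
#' `truth.json` with labels, centroids, betas, and the seed).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` instead of `.nii`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  ext <- if (gzip) ".nii.gz" else ".nii"
  pd <- file.path(dir, "patients"); cd <- file.path(dir, "controls")
  td <- file.path(dir, "truth")
  for (d in c(dir, pd, cd, td)) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  for (v in cohort$patient_volumes) {
    write_nifti(v$data, file.path(pd, paste0(v$subject_id, ext)), v$affine)
  }
  for (v in cohort$control_volumes) {
    write_nifti(v$data, file.path(cd, paste0(v$subject_id, ext)), v$affine)
  }
  write_nifti(array(as.double(cohort$mask$indicator), dim = cohort$mask$dim),
              file.path(dir, paste0("brain_mask", ext)))
  write_nifti(array(as.double(cohort$reference$indicator), dim = cohort$reference$dim),
              file.path(dir, paste0("reference_mask", ext)))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  for (j in seq_len(nrow(cohort$truth$factor_maps))) {
    write_nifti(unflatten_row(cohort$truth$factor_maps[j, ], cohort$mask),
                file.path(td, sprintf("factor_%d%s", j, ext)))
  }
  jsonlite::write_json(
    list(cluster_labels = cohort$truth$cluster_labels,
         cluster_centroids = cohort$truth$cluster_centroids,
         clinical_betas = cohort$truth$clinical_betas,
         loading_sd = cohort$truth$loading_sd,
         noise_sd = cohort$truth$noise_sd, seed = cohort$truth$seed),
    file.path(td, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
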