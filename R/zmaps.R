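# Voxel-wise Z-score maps against a control cohort. The control reference is
# the per-voxel mean and sample standard deviation over controls within the
# brain mask; a patient group (or single patient) is expressed as
# Z(v) = (mean_patients(v) - mean_controls(v)) / sd_controls(v). The control
# sd (not a pooled sd) is used. Voxels with zero control sd are excluded via
# a validity mask rather than producing infinities. The machinery is
# modality-agnostic (FDG, tau, amyloid, gray matter): modality is metadata.

.masked_rows <- function(volumes, mask) {
  if (inherits(volumes, "masked_volume")) volumes <- list(volumes)
  rows <- matrix(NA_real_, nrow = length(volumes), ncol = mask$n_voxels)
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!all(dim(v$data) == mask$dim)) {
      stop("grid mismatch for subject ", v$subject_id)
    }
    rows[i, ] <- v$data[mask$voxel_index]
  }
  rownames(rows) <- vapply(volumes, function(v) v$subject_id, character(1))
  rows
}

#' Per-voxel control reference (mean and sd maps)
#'
#' @param control_volumes list of [masked_volume()]s (>= 2 controls).
#' @param mask a [brain_mask()].
#' @param modality metadata label (e.g. `"fdg"`).
#' @return an object of class `control_reference`: `mean_map`, `sd_map`
#'   (masked vectors), `valid` (logical; sd > 0), `n_controls`, `modality`,
#'   `mask`.
#' @export
control_reference <- function(control_volumes, mask, modality = "fdg") {
  if (length(control_volumes) < 2L) stop("need at least 2 controls")
  rows <- .masked_rows(control_volumes, mask)
  mean_map <- colMeans(rows)
  sd_map <- apply(rows, 2L, stats::sd) # sample sd, ddof 1
  structure(
    list(mean_map = mean_map, sd_map = sd_map, valid = sd_map > 0,
         n_controls = nrow(rows), modality = modality, mask = mask),
    class = "control_reference"
  )
}

#' @export
print.control_reference <- function(x, ...) {
  cat("control_reference:", x$n_controls, "controls,", x$modality, "modality,",
      sum(x$valid), "/", length(x$valid), "valid voxels\n")
  invisible(x)
}

.zmap_from_mean <- function(patient_mean, reference, source, id) {
  z <- rep(0, length(patient_mean))
  v <- reference$valid
  z[v] <- (patient_mean[v] - reference$mean_map[v]) / reference$sd_map[v]
  structure(
    list(values = unflatten_row(z, reference$mask),
         z = z, valid = v, mask = reference$mask,
         source = source, id = id, threshold_applied = NULL,
         modality = reference$modality),
    class = "zmap"
  )
}

#' Group-level voxel-wise Z-score map
#'
#' @param patient_volumes list of [masked_volume()]s (>= 1) on the reference
#'   grid.
#' @param reference a [control_reference()].
#' @param id group label carried into the result.
#' @return an object of class `zmap` with `values` (3D array; zero outside the
#'   brain mask and at invalid voxels), `z` (masked vector), `valid`,
#'   `source`, `id`.
#' @export
zmap_group <- function(patient_volumes, reference, id = "group") {
  rows <- .masked_rows(patient_volumes, reference$mask)
  .zmap_from_mean(colMeans(rows), reference, "group", id)
}

#' Individual voxel-wise Z-score map
#'
#' @param patient_volume one [masked_volume()].
#' @param reference a [control_reference()].
#' @return a `zmap` with `source = "individual"`.
#' @export
zmap_individual <- function(patient_volume, reference) {
  rows <- .masked_rows(list(patient_volume), reference$mask)
  .zmap_from_mean(rows[1L, ], reference, "individual", patient_volume$subject_id)
}

#' @export
print.zmap <- function(x, ...) {
  cat("zmap (", x$source, "): ", x$id, ", Z range [",
      sprintf("%.2f", min(x$z[x$valid])), ", ",
      sprintf("%.2f", max(x$z[x$valid])), "] over ",
      sum(x$valid), " valid voxels\n", sep = "")
  invisible(x)
}

#' Censor a Z map at a display threshold
#'
#' Voxels failing the criterion are set to 0 and the number of surviving
#' voxels is recorded. The mapping between a nominal significance level and a
#' Z threshold is left to the caller.
#'
#' @param zmap a `zmap`.
#' @param z_threshold finite threshold value.
#' @param direction `"below"` (keep Z < threshold, e.g. hypometabolism),
#'   `"above"` (keep Z > threshold), or `"two_sided"` (keep |Z| >= |threshold|).
#' @return a censored `zmap` with `threshold_applied` and `n_surviving` set.
#' @export
threshold_map <- function(zmap, z_threshold, direction = c("below", "above", "two_sided")) {
  direction <- match.arg(direction)
  stopifnot_scalar(z_threshold, "z_threshold")
  keep <- switch(direction,
    below = zmap$z < z_threshold,
    above = zmap$z > z_threshold,
    two_sided = abs(zmap$z) >= abs(z_threshold)
  )
  keep <- keep & zmap$valid
  z <- ifelse(keep, zmap$z, 0)
  out <- zmap
  out$z <- z
  out$values <- unflatten_row(z, zmap$mask)
  out$threshold_applied <- z_threshold
  out$direction <- direction
  out$n_surviving <- sum(keep)
  out
}
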