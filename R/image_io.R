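#' Brain mask with a fixed voxel flattening order
#'
#' Wraps a 3D logical indicator together with the ordered index mapping masked
#' voxels to flat column positions. The order is R's native column-major
#' raster scan; it is recorded in the object and is identical for every
#' subject, which is all the downstream algebra requires.
#'
#' @param indicator 3D logical (or numeric; nonzero = included) array.
#' @return an object of class `brain_mask` with fields `indicator`, `dim`,
#'   `voxel_index` (integer positions into the flattened array) and
#'   `n_voxels`.
#' @export
brain_mask <- function(indicator) {
  if (length(dim(indicator)) != 3L) stop("mask indicator must be a 3D array")
  ind <- array(as.logical(indicator != 0), dim = dim(indicator))
  idx <- which(ind)
  if (length(idx) < 1L) stop("mask contains no voxels")
  structure(
    list(indicator = ind, dim = dim(ind), voxel_index = idx,
         n_voxels = length(idx), order = "column-major"),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("brain_mask:", paste(x$dim, collapse = "x"), "grid,",
      x$n_voxels, "voxels,", x$order, "flattening\n")
  invisible(x)
}

#' Read a NIfTI mask
#'
#' @param path NIfTI file; nonzero voxels are included.
#' @param expected_shape optional length-3 integer vector to validate against.
#' @return a [brain_mask()].
#' @export
read_mask <- function(path, expected_shape = NULL) {
  nii <- read_nifti(path)
  if (!is.null(expected_shape) && !all(dim(nii$data) == expected_shape)) {
    stop("mask shape (", paste(dim(nii$data), collapse = "x"),
         ") does not match expected (", paste(expected_shape, collapse = "x"), ")")
  }
  brain_mask(nii$data != 0)
}

#' One subject's volume with its affine context
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param subject_id subject identifier string.
#' @return an object of class `masked_volume`.
#' @export
masked_volume <- function(data, affine = diag(4), subject_id = "subject") {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  structure(list(data = data, affine = affine, subject_id = as.character(subject_id)),
            class = "masked_volume")
}

#' @export
print.masked_volume <- function(x, ...) {
  cat("masked_volume:", x$subject_id, "-",
      paste(dim(x$data), collapse = "x"), "\n")
  invisible(x)
}

#' Read one subject volume from NIfTI
#'
#' @param path NIfTI path (3D; 4D files are rejected).
#' @param expected_shape optional length-3 shape to validate against.
#' @param subject_id subject identifier; defaults to the file basename.
#' @return a [masked_volume()].
#' @export
read_volume <- function(path, expected_shape = NULL, subject_id = NULL) {
  nii <- read_nifti(path)
  shp <- dim(nii$data)
  if (!is.null(expected_shape) && !all(shp == expected_shape)) {
    stop("volume shape (", paste(shp, collapse = "x"),
         ") does not match expected (", paste(expected_shape, collapse = "x"),
         "): ", path)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  masked_volume(nii$data, nii$affine, subject_id)
}

#' Normalize a volume to a reference region (SUVR)
#'
#' Divides every voxel by the mean intensity within the reference region
#' (for FDG-PET, conventionally the pons), so the output has reference-region
#' mean exactly 1.
#'
#' @param vol a [masked_volume()].
#' @param reference a [brain_mask()] delimiting the reference region.
#' @return a [masked_volume()] on the SUVR scale.
#' @export
suvr_normalize <- function(vol, reference) {
  if (!inherits(vol, "masked_volume")) stop("'vol' must be a masked_volume")
  if (!inherits(reference, "brain_mask")) stop("'reference' must be a brain_mask")
  if (!all(dim(vol$data) == reference$dim)) {
    stop("reference mask grid does not match volume grid")
  }
  m <- mean(vol$data[reference$voxel_index])
  if (!is.finite(m) || m <= 0) {
    stop("reference region mean is not positive for subject ", vol$subject_id,
         " (mean = ", format(m), ")")
  }
  masked_volume(vol$data / m, vol$affine, vol$subject_id)
}

#' Robustly scale one subject's masked voxel vector
#'
#' Median-centers the vector at zero and scales it by its interquartile range.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), which is documented and fixed.
#'
#' @param values numeric vector of masked voxel intensities (length >= 4).
#' @param subject_id optional identifier used in degenerate-input errors.
#' @return a list with `scaled`, `median` and `iqr`.
#' @export
robust_scale_row <- function(values, subject_id = "subject") {
  if (length(values) < 4L) stop("need at least 4 values to robustly scale")
  if (anyNA(values)) stop("NA values in masked voxels for ", subject_id)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (iqr <= 0) {
    stop("degenerate input: zero interquartile range (constant image) for subject ",
         subject_id)
  }
  list(scaled = (values - q[2]) / iqr, median = q[2], iqr = iqr)
}

#' Assemble the subject-by-voxel matrix
#'
#' Flattens each subject's masked voxels in the mask's fixed raster order into
#' one row, optionally applying per-subject robust (median/IQR) scaling.
#'
#' @param volumes list of [masked_volume()]s sharing the template grid.
#' @param mask a [brain_mask()].
#' @param scale if `TRUE` (default), each row is median-centered and divided
#'   by its IQR, computed within the mask.
#' @return an object of class `subject_matrix` with fields `values`
#'   (subjects x voxels), `subject_ids`, `scaling_record` (per-subject median
#'   and IQR, or NA when `scale = FALSE`), `mask_dim`, `n_voxels`, `scaled`.
#' @export
build_subject_matrix <- function(volumes, mask, scale = TRUE) {
  if (!inherits(mask, "brain_mask")) stop("'mask' must be a brain_mask")
  if (length(volumes) < 1L) stop("no volumes supplied")
  ids <- vapply(volumes, function(v) v$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  p <- mask$n_voxels
  values <- matrix(NA_real_, nrow = length(volumes), ncol = p)
  med <- iqr <- rep(NA_real_, length(volumes))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!all(dim(v$data) == mask$dim)) {
      stop("volume shape mismatch for subject ", ids[i])
    }
    row <- as.double(v$data[mask$voxel_index])
    if (anyNA(row) || any(!is.finite(row))) {
      stop("non-finite voxels inside mask for subject ", ids[i])
    }
    if (scale) {
      rs <- robust_scale_row(row, subject_id = ids[i])
      row <- rs$scaled; med[i] <- rs$median; iqr[i] <- rs$iqr
    }
    values[i, ] <- row
  }
  rownames(values) <- ids
  structure(
    list(values = values, subject_ids = ids,
         scaling_record = data.frame(subject_id = ids, median = med, iqr = iqr,
                                     stringsAsFactors = FALSE),
         mask_dim = mask$dim, n_voxels = p, scaled = scale),
    class = "subject_matrix"
  )
}

#' @export
print.subject_matrix <- function(x, ...) {
  cat("subject_matrix:", nrow(x$values), "subjects x", x$n_voxels, "voxels",
      if (x$scaled) "(robustly scaled)" else "(unscaled)", "\n")
  invisible(x)
}

#' Place a flat masked row back into the 3D grid
#'
#' Inverse of the masking/flattening step: voxels outside the mask are set to
#' `fill`.
#'
#' @param row numeric vector of length `mask$n_voxels`.
#' @param mask a [brain_mask()].
#' @param fill value outside the mask (default 0).
#' @return 3D numeric array on the mask's grid.
#' @export
unflatten_row <- function(row, mask, fill = 0) {
  if (length(row) != mask$n_voxels) stop("row length does not match mask voxel count")
  out <- array(fill, dim = mask$dim)
  out[mask$voxel_index] <- row
  out
}

#' Export / import a subject matrix as flat binary + JSON sidecar
#'
#' `write_subject_matrix` writes `<prefix>.bin` (row-major float64, little
#' endian) and `<prefix>.json` recording dimensions, subject order, scaling
#' record and a mask checksum; `read_subject_matrix` reads them back.
#'
#' @param sm a `subject_matrix`.
#' @param prefix output path prefix (no extension).
#' @return `write_subject_matrix`: the prefix, invisibly.
#'   `read_subject_matrix`: a `subject_matrix`.
#' @export
write_subject_matrix <- function(sm, prefix) {
  bin <- paste0(prefix, ".bin")
  con <- file(bin, "wb")
  writeBin(as.double(t(sm$values)), con, size = 8L, endian = "little")
  close(con)
  meta <- list(
    n_subjects = nrow(sm$values), n_voxels = sm$n_voxels,
    subject_ids = sm$subject_ids, scaled = sm$scaled,
    scaling_record = sm$scaling_record, mask_dim = sm$mask_dim,
    storage = "row-major float64 little-endian",
    bin_md5 = unname(tools::md5sum(bin))
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_subject_matrix
#' @export
read_subject_matrix <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$n_subjects; p <- meta$n_voxels
  con <- file(paste0(prefix, ".bin"), "rb")
  vals <- readBin(con, "double", n = n * p, size = 8L, endian = "little")
  close(con)
  values <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  rownames(values) <- meta$subject_ids
  structure(
    list(values = values, subject_ids = meta$subject_ids,
         scaling_record = as.data.frame(meta$scaling_record),
         mask_dim = meta$mask_dim, n_voxels = p, scaled = meta$scaled),
    class = "subject_matrix"
  )
}
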