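# Minimal NIfTI-1 volume I/O.
#
# The runtime environment provides no R NIfTI package, so the package carries
# a small self-contained implementation of the single-file NIfTI-1 format
# (348-byte header + 4 extension bytes), sufficient for 3D volumes:
# little/big endian, optional gzip, datatypes uint8/int16/int32/float32/float64,
# scl_slope/scl_inter applied on read, sform affine honoured.

.nifti_datatypes <- list(
  "2"  = list(what = "integer", size = 1L, signed = FALSE),
  "4"  = list(what = "integer", size = 2L, signed = TRUE),
  "8"  = list(what = "integer", size = 4L, signed = TRUE),
  "16" = list(what = "double",  size = 4L, signed = TRUE),
  "64" = list(what = "double",  size = 8L, signed = TRUE)
)

#' Read a 3D NIfTI-1 volume
#'
#' Reads a single-volume (3D) NIfTI-1 file (`.nii` or `.nii.gz`). 4D files are
#' rejected: this package operates on one volume per subject.
#'
#' @param path path to a NIfTI-1 file.
#' @return a list with elements `data` (3D numeric array) and `affine`
#'   (4x4 voxel-to-world matrix; sform if present, else voxel spacings on the
#'   diagonal).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)

  endian <- "little"
  if (readBin(hdr[1:4], "integer", size = 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", size = 4L, endian = endian) != 348L) {
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    }
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI not supported: ", path)

  rb <- function(offset, what, n, size) {
    readBin(hdr[(offset + 1L):(offset + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dim8 <- rb(40L, "integer", 8L, 2L)
  ndim <- dim8[1L]
  dims <- dim8[2:8]
  dims[dims <= 0L] <- 1L
  if (ndim > 3L && any(dims[4:7] > 1L)) {
    stop("4D NIfTI not supported (one volume per subject expected): ", path)
  }
  shape <- dims[1:3]
  datatype <- rb(70L, "integer", 1L, 2L)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  pixdim <- rb(76L, "double", 8L, 4L)
  vox_offset <- rb(108L, "double", 1L, 4L)
  scl_slope <- rb(112L, "double", 1L, 4L)
  scl_inter <- rb(116L, "double", 1L, 4L)
  sform_code <- rb(254L, "integer", 1L, 2L)
  srow <- rb(280L, "double", 12L, 4L)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  data <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < n_vox) stop("truncated NIfTI data section: ", path)
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  affine <- if (sform_code > 0L) {
    rbind(matrix(srow, nrow = 3L, ncol = 4L, byrow = TRUE), c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2:4], 1))
  }
  list(data = array(data, dim = shape), affine = affine)
}

#' Write a 3D array as a NIfTI-1 volume
#'
#' Writes float32 (default) or float64 data as a single-file NIfTI-1 volume;
#' gzip compression is selected by a `.gz` path suffix.
#'
#' @param data 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix, stored as the sform.
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "float32") {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  if (!is.matrix(affine) || any(dim(affine) != 4L)) stop("'affine' must be 4x4")
  dt_code <- switch(datatype, float32 = 16L, float64 = 64L,
                    stop("unsupported write datatype: ", datatype))
  dt_size <- if (dt_code == 16L) 4L else 8L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x, size = 4L) writeBin(as.double(x), con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  pix <- sqrt(colSums(affine[1:3, 1:3]^2))
  pix[pix == 0] <- 1

  wi(348L, 4L)                       # sizeof_hdr
  wraw(10L + 18L)                    # data_type, db_name
  wi(0L, 4L); wi(0L, 2L)             # extents, session_error
  writeBin(charToRaw("r"), con)      # regular
  wraw(1L)                           # dim_info
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)         # intent_p1-3, intent_code
  wi(dt_code, 2L); wi(dt_size * 8L, 2L); wi(0L, 2L)  # datatype, bitpix, slice_start
  wf(c(1, pix, 1, 1, 1, 1))          # pixdim[8] (qfac = 1)
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope, scl_inter
  wi(0L, 2L); wraw(2L)               # slice_end, slice_code + xyzt_units
  wf(0); wf(0); wf(0); wf(0)         # cal_max, cal_min, slice_duration, toffset
  wi(0L, 4L); wi(0L, 4L)             # glmax, glmin
  wraw(80L); wraw(24L)               # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)             # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))            # quatern_b/c/d, qoffset_x/y/z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x/y/z
  wraw(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)      # magic
  wraw(4L)                           # extension flag
  writeBin(as.double(data), con, size = dt_size, endian = "little")
  invisible(path)
}
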