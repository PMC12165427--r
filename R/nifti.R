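# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package ships with this stack, so the 348-byte NIfTI-1 header is
# handled directly. Coverage is deliberately narrow: 3D single-frame images,
# the common datatypes, sform affine, mm units — exactly what the rest of
# the pipeline produces and consumes. Cross-checked against nibabel in the
# test suite.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,   bitpix = 8L),
  int16   = list(code = 4L,   bitpix = 16L),
  int32   = list(code = 8L,   bitpix = 32L),
  float32 = list(code = 16L,  bitpix = 32L),
  float64 = list(code = 64L,  bitpix = 64L),
  uint16  = list(code = 512L, bitpix = 16L)
)

nii_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D array as a NIfTI-1 file
#'
#' @param data 3D numeric/integer array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing Voxel spacing in mm.
#' @param affine Optional 4x4 voxel-to-world matrix (sform); defaults to a
#'   diagonal spacing matrix.
#' @param datatype One of `"float32"`, `"float64"`, `"int16"`, `"int32"`,
#'   `"uint8"`, `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), affine = NULL,
                        datatype = "float32") {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop("write_nifti expects a 3D array", call. = FALSE)
  dt <- NIFTI_DTYPES[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype, call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  con <- tryCatch(nii_connection(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  zeros <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                                   # sizeof_hdr
  zeros(36)                                     # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(dt$code, 2)                                # datatype
  wi(dt$bitpix, 2)                              # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, spacing, 0, 0, 0, 0))                 # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); zeros(1)                           # slice_end, slice_code
  writeBin(as.raw(10L), con)                    # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  desc <- charToRaw("glioseg3d")
  writeBin(c(desc, raw(80 - length(desc))), con)  # descrip[80]
  zeros(24)                                     # aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern/qoffset
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x/y/z
  zeros(16)                                     # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  zeros(4)                                      # extension flag
  vals <- as.vector(data)
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(vals), con, size = dt$bitpix / 8, endian = "little")
  } else {
    writeBin(as.integer(round(vals)), con, size = dt$bitpix / 8,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return List with `data` (array), `spacing`, `affine`, `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path, call. = FALSE)
  pick <- function(off, n, what, size, signed = TRUE, endian) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (pick(0, 1, "integer", 4, endian = endian) != 348L) {
    endian <- "big"
    if (pick(0, 1, "integer", 4, endian = endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  dim8 <- pick(40, 8, "integer", 2, endian = endian)
  nd <- dim8[1]
  if (nd < 3 || any(dim8[1 + seq_len(nd)][-(1:3)] > 1))
    if (nd != 3) stop("only 3D NIfTI volumes are supported: ", path,
                      call. = FALSE)
  d <- dim8[2:4]
  dtcode <- pick(70, 1, "integer", 2, endian = endian)
  pixdim <- pick(76, 8, "numeric", 4, endian = endian)
  vox_offset <- pick(108, 1, "numeric", 4, endian = endian)
  scl_slope <- pick(112, 1, "numeric", 4, endian = endian)
  scl_inter <- pick(116, 1, "numeric", 4, endian = endian)
  sform_code <- pick(254, 1, "integer", 2, endian = endian)
  srow <- matrix(pick(280, 12, "numeric", 4, endian = endian), nrow = 3,
                 byrow = TRUE)
  dtname <- names(NIFTI_DTYPES)[vapply(NIFTI_DTYPES, function(x)
    x$code == dtcode, logical(1))]
  if (!length(dtname))
    stop("unsupported NIfTI datatype code ", dtcode, ": ", path,
         call. = FALSE)
  dt <- NIFTI_DTYPES[[dtname]]
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- switch(dtname,
    uint8   = readBin(con, "integer", n, size = 1, signed = FALSE,
                      endian = endian),
    int16   = readBin(con, "integer", n, size = 2, endian = endian),
    uint16  = readBin(con, "integer", n, size = 2, signed = FALSE,
                      endian = endian),
    int32   = readBin(con, "integer", n, size = 4, endian = endian),
    float32 = readBin(con, "numeric", n, size = 4, endian = endian),
    float64 = readBin(con, "numeric", n, size = 8, endian = endian))
  if (length(vals) < n) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- abs(pixdim[2:4])
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(spacing, 1))
  list(data = array(vals, d), spacing = spacing, affine = affine,
       datatype = dtname)
}
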