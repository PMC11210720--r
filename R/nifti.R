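#' @name nifti
#' @title Minimal NIfTI-1 volume I/O
#' @description
#' A deliberately small single-file NIfTI-1 (.nii / .nii.gz) reader and
#' writer covering what dynamic volumetric data needs here: 3D and 4D
#' images, datatypes uint8 / int16 / int32 / float32 / float64, scl
#' slope/intercept scaling, and an sform affine. Both-endian files are read;
#' files are written little-endian with datatype float32 by default.
NULL

nifti_datatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE),
  name = c("uint8", "int16", "int32", "float32", "float64"))

#' Read a NIfTI-1 volume
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return Numeric array (3D or 4D) with attributes `pixdim` (voxel sizes)
#'   and `affine` (4 x 4 voxel-to-world matrix; identity-based fallback when
#'   the file stores no sform).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path, call. = FALSE)
  con <- gzfile(path, "rb")   # transparently handles uncompressed files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path,
                         call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)
  rd <- function(off, what, n, size)
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian)
  dim8 <- rd(40L, "integer", 8L, 2L)
  ndim <- dim8[1L]
  if (ndim < 3L || ndim > 4L)
    stop("only 3D/4D NIfTI volumes are supported (ndim = ", ndim, ")",
         call. = FALSE)
  dims <- dim8[2L:(1L + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- nifti_datatypes[nifti_datatypes$code == datatype, ]
  if (nrow(dt) != 1L)
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  pixdim <- rd(76L, "double", 8L, 4L)[2L:(1L + ndim)]
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  srow <- rbind(rd(280L, "double", 4L, 4L), rd(296L, "double", 4L, 4L),
                rd(312L, "double", 4L, 4L), c(0, 0, 0, 1))
  # skip the extension gap between the 348-byte header and the data
  gap <- as.integer(round(vox_offset)) - 348L
  if (gap > 0L) readBin(con, "raw", n = gap)
  nvox <- prod(dims)
  data <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) != nvox) stop("truncated NIfTI data: ", path, call. = FALSE)
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- array(data, dim = dims)
  affine <- if (sform_code > 0L) srow else {
    a <- diag(4)
    diag(a)[1:3] <- ifelse(pixdim[1:3] != 0, pixdim[1:3], 1)
    a
  }
  attr(arr, "pixdim") <- pixdim
  attr(arr, "affine") <- affine
  arr
}

#' Write a NIfTI-1 volume
#'
#' @param arr Numeric 3D or 4D array.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param affine 4 x 4 voxel-to-world matrix stored as the sform (default:
#'   the array's `affine` attribute, else identity).
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, affine = NULL, datatype = c("float32",
                                                               "float64")) {
  datatype <- match.arg(datatype)
  dims <- dim(arr)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L))
    stop("arr must be a 3D or 4D array", call. = FALSE)
  if (is.null(affine)) affine <- attr(arr, "affine")
  if (is.null(affine)) affine <- diag(4)
  dt <- nifti_datatypes[nifti_datatypes$name == datatype, ]

  dim8 <- integer(8L)
  dim8[1L] <- length(dims)
  dim8[2L:(1L + length(dims))] <- dims
  dim8[dim8 == 0L] <- 1L
  pixdim <- c(1, sqrt(colSums(affine[1:3, 1:3]^2)), rep(1, 4))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wr_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wr_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wr_raw <- function(n) writeBin(raw(n), con)

  wr_i32(348L)                 # sizeof_hdr
  wr_raw(36L)                  # data_type, db_name, extents, session_error,
                               # regular, dim_info
  wr_i16(dim8)                 # dim[8]
  wr_raw(14L)                  # intent_p1..p3, intent_code
  wr_i16(dt$code)              # datatype
  wr_i16(8L * dt$size)         # bitpix
  wr_i16(0L)                   # slice_start
  wr_f32(pixdim[1:8])          # pixdim[8]
  wr_f32(352)                  # vox_offset
  wr_f32(1); wr_f32(0)         # scl_slope, scl_inter
  wr_i16(0L); wr_raw(2L)       # slice_end, slice_code + xyzt_units
  wr_f32(c(0, 0))              # cal_max, cal_min
  wr_f32(c(0, 0))              # slice_duration, toffset
  wr_i32(c(0L, 0L))            # glmax, glmin
  wr_raw(80L + 24L)            # descrip, aux_file
  wr_i16(0L)                   # qform_code
  wr_i16(1L)                   # sform_code
  wr_f32(rep(0, 6))            # quatern b/c/d, qoffset x/y/z
  wr_f32(affine[1, ]); wr_f32(affine[2, ]); wr_f32(affine[3, ])
  wr_raw(16L)                  # intent_name
  writeBin(charToRaw("n+1"), con); wr_raw(1L)   # magic
  wr_raw(4L)                   # pad to vox_offset = 352
  writeBin(as.numeric(arr), con, size = dt$size, endian = "little")
  invisible(path)
}
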