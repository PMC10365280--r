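# Minimal NIfTI-1 reader/writer.
#
# Only what the pipeline needs: single-file .nii / .nii.gz, 3D images,
# little- or big-endian headers, sform/qform affines, scl_slope/scl_inter
# scaling, common datatypes. Kept in-package because no NIfTI reader is a
# declared dependency of this package's target environments.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,   size = 1L, what = "integer", signed = FALSE),
  int16   = list(code = 4L,   size = 2L, what = "integer", signed = TRUE),
  int32   = list(code = 8L,   size = 4L, what = "integer", signed = TRUE),
  float32 = list(code = 16L,  size = 4L, what = "double",  signed = TRUE),
  float64 = list(code = 64L,  size = 8L, what = "double",  signed = TRUE),
  int8    = list(code = 256L, size = 1L, what = "integer", signed = TRUE),
  uint16  = list(code = 512L, size = 2L, what = "integer", signed = FALSE)
)

nifti_dtype_by_code <- function(code) {
  for (nm in names(NIFTI_DTYPES))
    if (NIFTI_DTYPES[[nm]]$code == code) return(c(NIFTI_DTYPES[[nm]], name = nm))
  stop("unsupported NIfTI datatype code: ", code)
}

quaternion_to_matrix <- function(b, c, d, qfac) {
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 > 0) sqrt(a2) else 0
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d),           2 * (b * d + a * c),
    2 * (b * c + a * d),           a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c),           2 * (c * d + a * b),           a * a + d * d - b * b - c * c
  ), nrow = 3, byrow = TRUE)
  R[, 3] <- R[, 3] * qfac
  R
}

#' Read a NIfTI-1 image from disk
#'
#' Supports single-file `.nii` and `.nii.gz` volumes, 3D only. The
#' voxel-to-world affine is taken from the sform when `sform_code > 0`,
#' otherwise from the qform, otherwise from the pixdim diagonal.
#' `scl_slope`/`scl_inter` scaling is applied on read.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with `data` (3D array), `affine` (4x4 matrix) and
#'   `header` (named list of raw header fields).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", n = 348)
  if (length(hdr_raw) < 348) stop("not a NIfTI-1 file (truncated header): ", path)
  sz_le <- readBin(hdr_raw[1:4], "integer", size = 4, endian = "little")
  endian <- if (identical(sz_le, 348L)) "little" else "big"
  if (endian == "big") {
    sz_be <- readBin(hdr_raw[1:4], "integer", size = 4, endian = "big")
    if (!identical(sz_be, 348L)) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  at <- function(off, what, n, size, signed = TRUE)
    readBin(hdr_raw[(off + 1):(off + n * size)], what,
            n = n, size = size, signed = signed, endian = endian)

  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  dims <- at(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 1 || ndim > 7) stop("bad dim[0] in ", path)
  if (ndim > 3 && any(dims[5:(1 + ndim)] > 1))
    stop("only 3D images are supported (got ", ndim, "D): ", path)
  d <- dims[2:4]
  if (ndim < 3) d[(ndim + 1):3] <- 1L
  if (any(d <= 0)) stop("non-positive image dimension in ", path)

  datatype <- at(70, "integer", 1, 2)
  dt <- nifti_dtype_by_code(datatype)
  pixdim <- at(76, "double", 8, 4)
  vox_offset <- at(108, "double", 1, 4)
  scl_slope <- at(112, "double", 1, 4)
  scl_inter <- at(116, "double", 1, 4)
  qform_code <- at(252, "integer", 1, 2)
  sform_code <- at(254, "integer", 1, 2)
  quat <- at(256, "double", 6, 4)
  srow <- rbind(at(280, "double", 4, 4), at(296, "double", 4, 4), at(312, "double", 4, 4))

  if (sform_code > 0) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    qfac <- if (pixdim[1] < 0) -1 else 1
    R <- quaternion_to_matrix(quat[1], quat[2], quat[3], qfac)
    affine <- diag(4)
    affine[1:3, 1:3] <- R %*% diag(pixdim[2:4])
    affine[1:3, 4] <- quat[4:6]
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  if (abs(det(affine)) < 1e-12) stop("non-invertible affine in ", path)

  # skip from end of header to vox_offset (extensions)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)

  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = isTRUE(dt$signed), endian = endian)
  if (length(vals) < n) stop("truncated image data in ", path)
  vals <- as.double(vals)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  list(data = array(vals, dim = d), affine = affine,
       header = list(datatype = dt$name, pixdim = pixdim[2:4],
                     scl_slope = scl_slope, scl_inter = scl_inter,
                     qform_code = qform_code, sform_code = sform_code))
}

#' Write a 3D array + affine as a NIfTI-1 file
#'
#' Writes single-file NIfTI-1 (`.nii`, gzip-compressed when the path ends
#' in `.gz`), little-endian, with the affine stored in the sform
#' (`sform_code = 2`). No intensity scaling is applied (`scl_slope = 1`).
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param dtype storage type: one of `"float32"`, `"float64"`, `"int16"`,
#'   `"int32"`, `"uint8"`.
#' @keywords internal
write_nifti <- function(data, affine, path, dtype = "float32") {
  stopifnot(length(dim(data)) == 3, all(dim(affine) == c(4, 4)))
  dt <- NIFTI_DTYPES[[dtype]]
  if (is.null(dt)) stop("unsupported dtype: ", dtype)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)

  d <- dim(data)
  pixdim <- c(1, sqrt(colSums(affine[1:3, 1:3]^2)), 1, 1, 1, 1)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                                  # sizeof_hdr
  w_raw(36)                                   # data_type..dim_info
  w_i16(c(3, d, 1, 1, 1, 1))                  # dim[8]
  w_f32(c(0, 0, 0))                           # intent_p1..p3
  w_i16(0)                                    # intent_code
  w_i16(dt$code)                              # datatype
  w_i16(dt$size * 8L)                         # bitpix
  w_i16(0)                                    # slice_start
  w_f32(pixdim)                               # pixdim[8]
  w_f32(352)                                  # vox_offset
  w_f32(1)                                    # scl_slope
  w_f32(0)                                    # scl_inter
  w_i16(0); w_raw(2)                          # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                        # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                              # glmax, glmin
  w_raw(80 + 24)                              # descrip, aux_file
  w_i16(0)                                    # qform_code
  w_i16(2)                                    # sform_code (aligned)
  w_f32(c(0, 0, 0, 0, 0, 0))                  # quatern b,c,d + qoffset x,y,z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  w_raw(4)                                    # extender

  vals <- as.vector(data)
  if (dt$what == "integer") {
    vals <- round(vals)
    writeBin(as.integer(vals), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
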