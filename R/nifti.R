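# Minimal uncompressed NIfTI-1 I/O. Only what the searchlight pipeline
# needs: 3-d/4-d double or float volumes, isotropic-or-not voxel sizes, a
# diagonal sform. No R NIfTI reader is available in the target
# environment, hence this hand-rolled single-file implementation.

#' Write a volume as an uncompressed NIfTI-1 file
#'
#' @param data Numeric 3-d or 4-d array (stored as float64).
#' @param path Output path (`.nii`).
#' @param voxel_size Voxel size in mm (scalar or length 3).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = 1.5) {
  dims <- dim(data)
  if (length(dims) < 3 || length(dims) > 4) {
    stop("only 3-d or 4-d volumes are supported", call. = FALSE)
  }
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                          # sizeof_hdr
  w_raw(35)                           # data_type, db_name, extents, ...
  w_raw(1)                            # dim_info
  dim8 <- c(length(dims), dims, rep(1L, 7 - length(dims)))
  w_i16(dim8)                         # dim[8]
  w_f32(c(0, 0, 0))                   # intent_p1..p3
  w_i16(0)                            # intent_code
  w_i16(64)                           # datatype: FLOAT64
  w_i16(64)                           # bitpix
  w_i16(0)                            # slice_start
  pixdim <- c(1, voxel_size, rep(1, 4))
  w_f32(pixdim)                       # pixdim[8]
  w_f32(352)                          # vox_offset
  w_f32(1); w_f32(0)                  # scl_slope, scl_inter
  w_i16(0); w_raw(1); w_raw(1)        # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                      # glmax, glmin
  w_raw(80); w_raw(24)                # descrip, aux_file
  w_i16(0); w_i16(1)                  # qform_code, sform_code
  w_f32(rep(0, 6))                    # quatern_b..d, qoffset_x..z
  w_f32(c(voxel_size[1], 0, 0, 0))    # srow_x
  w_f32(c(0, voxel_size[2], 0, 0))    # srow_y
  w_f32(c(0, 0, voxel_size[3], 0))    # srow_z
  w_raw(16)                           # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1)  # magic
  w_raw(4)                            # extension flag
  writeBin(as.numeric(data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' Supports float32/float64/int16/uint8 data, applying the scale slope and
#' intercept when set.
#'
#' @param path Input path.
#' @return A list: `data` (array), `voxel_size` (length 3).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2, endian = "little")
  r_f32 <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  hdr_size <- r_i32(1)
  if (!identical(hdr_size, 348L)) {
    stop("not a NIfTI-1 file (unexpected header size; big-endian and .nii.gz",
         " are not supported)", call. = FALSE)
  }
  readBin(con, "raw", 36)
  dim8 <- r_i16(8)
  r_f32(3); r_i16(1)
  datatype <- r_i16(1); r_i16(1); r_i16(1)
  pixdim <- r_f32(8)
  vox_offset <- r_f32(1)
  scl_slope <- r_f32(1); scl_inter <- r_f32(1)
  seek(con, where = vox_offset, origin = "start")
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  n <- prod(dims)
  vals <- switch(as.character(datatype),
    `2`  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    `4`  = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    `16` = readBin(con, "numeric", n, size = 4, endian = "little"),
    `64` = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  )
  if (length(vals) != n) stop("truncated NIfTI data in ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = dims), voxel_size = pixdim[2:4])
}
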