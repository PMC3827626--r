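# Minimal NIfTI-1 single-file (.nii) IO for 4D float32 volumes.
# No NIfTI package exists in the target R environment; the format's fixed
# 348-byte header is written and parsed directly.

nifti_affine_from_header <- function(srow_x, srow_y, srow_z) {
  rbind(srow_x, srow_y, srow_z, c(0, 0, 0, 1))
}

#' Write a 4D volume series as NIfTI-1
#'
#' Single-file `.nii`, float32, with the affine stored in the sform
#' (`sform_code = 1`) and TR in `pixdim[4]`.
#'
#' @param vol a `volume_series`.
#' @param path output path ending in `.nii`.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(vol, path) {
  d <- dim(vol$data)
  if (length(d) != 4) stop("write_nifti requires 4D data")
  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_i8 <- function(x) writeBin(as.integer(x), con, size = 1, endian = "little")

  w_i32(348)                       # sizeof_hdr
  w_i8(rep(0, 36))                 # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(c(4, d, 1, 1, 1))          # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1..p3
  w_i16(0)                         # intent_code
  w_i16(16)                        # datatype = NIFTI_TYPE_FLOAT32
  w_i16(32)                        # bitpix
  w_i16(0)                         # slice_start
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  w_f32(c(1, vox, vol$tr_s, 1, 1, 1))  # pixdim[8]; pixdim[4] = TR (s)
  w_f32(352)                       # vox_offset
  w_f32(c(1, 0))                   # scl_slope, scl_inter
  w_i16(0)                         # slice_end
  w_i8(c(0, 0))                    # slice_code, xyzt_units (set below via seek? keep 0)
  w_f32(c(0, 0, 0))                # cal_max, cal_min, slice_duration
  w_f32(0)                         # toffset
  w_i32(c(0, 0))                   # glmax, glmin
  w_i8(rep(0, 80 + 24))            # descrip, aux_file
  w_i16(c(0, 1))                   # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                 # quatern b,c,d, qoffset x,y,z
  w_f32(t(vol$affine[1:3, ]))      # srow_x, srow_y, srow_z
  w_i8(rep(0, 16))                 # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  w_i8(0)
  w_i8(rep(0, 4))                  # extender
  w_f32(vol$data)
  invisible(path)
}

#' Read a NIfTI-1 file as a volume series
#'
#' Accepts single-file `.nii` with float32/float64/int16 data; rejects
#' non-4D images.
#'
#' @param path path to a `.nii` file.
#' @return a `volume_series` with `tr_s` from `pixdim[4]` and the sform
#'   affine.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2, endian = "little")
  r_f32 <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  skip <- function(n) invisible(readBin(con, "raw", n))

  if (r_i32(1) != 348) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  skip(36)
  dims <- r_i16(8)
  ndim <- dims[1]
  if (ndim != 4)
    stop("expected a 4D BOLD series; file is ", ndim, "D")
  d <- dims[2:5]
  skip(12); skip(2)
  datatype <- r_i16(1)
  skip(2); skip(2)
  pixdim <- r_f32(8)
  vox_offset <- r_f32(1)
  scl <- r_f32(2)
  skip(2 + 2 + 12 + 4 + 8 + 80 + 24)
  skip(2)                           # qform_code
  sform_code <- r_i16(1)
  skip(24)
  srows <- matrix(r_f32(12), nrow = 3, byrow = TRUE)
  affine <- if (sform_code > 0) rbind(srows, c(0, 0, 0, 1)) else diag(4)

  seek(con, vox_offset)
  nvox <- prod(d)
  data <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", nvox, size = 8, endian = "little"),
    "4" = readBin(con, "integer", nvox, size = 2, endian = "little"),
    stop("unsupported NIfTI datatype code ", datatype))
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    data <- data * scl[1] + scl[2]
  new_volume_series(array(data, dim = d), tr_s = pixdim[5], affine = affine)
}

#' Round-trip helper for 4D BOLD series
#'
#' Reads a path into a [new_volume_series()] object, or writes one to disk,
#' depending on the argument type.
#'
#' @param x a file path (read) or a `volume_series` (write).
#' @param path when writing, the destination path.
#' @return a `volume_series` (read) or the path written (write).
#' @export
volume_io <- function(x, path = NULL) {
  if (is.character(x)) return(read_nifti(x))
  if (inherits(x, "volume_series")) {
    if (is.null(path)) stop("path required to write a volume_series")
    return(write_nifti(x, path))
  }
  stop("volume_io expects a path or a volume_series")
}
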