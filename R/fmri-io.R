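# Minimal NIfTI-1 single-file (.nii) reader/writer, little-endian,
# covering the datatypes this package emits/consumes (float32, float64,
# int16). No R NIfTI package ships with the supported environment; the
# format's fixed 348-byte header makes a scoped implementation preferable
# to an unvetted dependency.

#' Write a 3D/4D array as an uncompressed NIfTI-1 file
#'
#' @param img numeric 3D or 4D array, or a [bold_series()] (whose TR and
#'   zooms populate the header).
#' @param path output path (`.nii`).
#' @param zooms voxel sizes in mm (length 3).
#' @param TR repetition time (s), written to `pixdim[4]`.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, zooms = c(1, 1, 1), TR = 1,
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  if (inherits(img, "bold_series")) {
    TR <- img$TR; zooms <- img$zooms; img <- img$data
  }
  d <- dim(img)
  stopifnot(length(d) %in% c(3, 4))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info
  dim8 <- c(length(d), d, rep(1, 7 - length(d)))
  wi(dim8, 2)                                  # dim[8]
  wf(c(0, 0, 0))                               # intent_p1..3
  wi(0, 2)                                     # intent_code
  dt <- if (datatype == "float32") c(16L, 32L) else c(64L, 64L)
  wi(dt[1], 2)                                 # datatype
  wi(dt[2], 2)                                 # bitpix
  wi(0, 2)                                     # slice_start
  wf(c(1, zooms, TR, 1, 1, 1))                 # pixdim[8]
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  wi(0, 2); writeBin(raw(1), con)              # slice_end, slice_code
  writeBin(as.raw(10L), con)                   # xyzt_units: mm | sec
  wf(c(0, 0, 0))                               # cal_max, cal_min, slice_dur
  wf(0)                                        # toffset
  wi(c(0, 0), 4)                               # glmax, glmin
  writeBin(raw(104), con)                      # descrip + aux_file
  wi(c(0, 0), 2)                               # qform_code, sform_code
  wf(rep(0, 18))                               # quatern + srow
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  writeBin(as.numeric(img), con,
           size = if (datatype == "float32") 4 else 8, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' Supports datatypes 4 (int16), 16 (float32) and 64 (float64), single-file
#' little-endian layout, applying `scl_slope`/`scl_inter` when set.
#'
#' @param path path to a `.nii` file.
#' @return list with `data` (array), `zooms`, `TR`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  assert_that(ri(0, 4) == 348, "not a NIfTI-1 file")
  dim8 <- ri(40, 2, 8)
  nd <- dim8[1]
  d <- dim8[2:(1 + nd)]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl <- rf(112, 2)
  seek(con, vox_offset)
  n <- prod(d)
  data <- switch(as.character(datatype),
                 "4"  = readBin(con, "integer", n, size = 2, endian = "little"),
                 "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
                 "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
                 stop("unsupported NIfTI datatype ", datatype))
  data <- as.numeric(data)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    data <- data * scl[1] + scl[2]
  list(data = array(data, d), zooms = pixdim[2:4], TR = pixdim[5])
}
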