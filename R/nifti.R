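# Minimal NIfTI-1 input/output.
#
# No NIfTI reader is available among this package's allowed dependencies, so
# a small self-contained implementation is provided.  It covers what the
# pipeline needs: single-file .nii / .nii.gz, 3D/4D volumes, datatypes uint8,
# int16, int32, float32, float64 (and uint16 on read), scl_slope/scl_inter
# scaling, and both byte orders on read.  Orientation metadata beyond the
# voxel size is not interpreted: all volumes in one analysis are assumed to
# share one grid (registration is upstream of this package).

NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
              float64 = 64L, uint16 = 512L)
NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L,
                  float64 = 64L, uint16 = 16L)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return numeric (or integer) array with attribute `pixdim` giving the
#'   voxel dimensions (mm) for the spatial axes.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) {
    stop_devoxel("file too short for a NIfTI-1 header: ", path,
                 class = "devoxel_io_error")
  }
  endian <- "little"
  if (readBin(hdr_raw[1:4], "integer", size = 4, endian = endian) != 348L) {
    endian <- "swap"
    if (readBin(hdr_raw[1:4], "integer", size = 4, endian = endian) != 348L) {
      stop_devoxel("not a NIfTI-1 file (sizeof_hdr != 348): ", path,
                   class = "devoxel_io_error")
    }
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop_devoxel("unsupported NIfTI magic '", magic, "' in ", path,
                 class = "devoxel_io_error")
  }
  dim8 <- readBin(hdr_raw[41:56], "integer", n = 8, size = 2, endian = endian)
  ndim <- dim8[1]
  if (ndim < 1 || ndim > 7) {
    stop_devoxel("invalid dim[0] = ", ndim, " in ", path,
                 class = "devoxel_io_error")
  }
  dims <- dim8[2:(1 + ndim)]
  datatype <- readBin(hdr_raw[71:72], "integer", size = 2, endian = endian)
  pixdim8 <- readBin(hdr_raw[77:108], "double", n = 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr_raw[109:112], "double", size = 4, endian = endian)
  scl_slope <- readBin(hdr_raw[113:116], "double", size = 4, endian = endian)
  scl_inter <- readBin(hdr_raw[117:120], "double", size = 4, endian = endian)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  x <- switch(as.character(datatype),
    "2"   = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    "4"   = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                    endian = endian),
    "8"   = readBin(con, "integer", n = n, size = 4, endian = endian),
    "16"  = readBin(con, "double", n = n, size = 4, endian = endian),
    "64"  = readBin(con, "double", n = n, size = 8, endian = endian),
    "512" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                    endian = endian),
    stop_devoxel("unsupported NIfTI datatype code ", datatype, " in ", path,
                 class = "devoxel_io_error")
  )
  if (length(x) < n) {
    stop_devoxel("truncated NIfTI data in ", path, class = "devoxel_io_error")
  }
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    x <- x * scl_slope + scl_inter
  }
  out <- array(x, dim = dims)
  attr(out, "pixdim") <- pixdim8[2:(1 + min(ndim, 3L))]
  out
}

#' Write a NIfTI-1 volume
#'
#' @param x numeric, integer or logical array (1--4 dimensions).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param pixdim voxel dimensions in mm for the spatial axes (recycled /
#'   padded to length 3; a 4th element, if given, is the repetition spacing).
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`; defaults to `"uint8"` for logical, `"int32"` for integer
#'   and `"float32"` for double data.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = attr(x, "pixdim") %||% c(1, 1, 1),
                        datatype = NULL) {
  dims <- dim(x) %||% length(x)
  if (length(dims) > 7L) {
    stop_devoxel("arrays above 7 dimensions are not valid NIfTI",
                 class = "devoxel_io_error")
  }
  if (is.null(datatype)) {
    datatype <- if (is.logical(x)) "uint8" else if (is.integer(x)) "int32"
                else "float32"
  }
  dt <- NIFTI_DT[[datatype]]
  bitpix <- NIFTI_BITPIX[[datatype]]
  pd <- rep(0, 8)
  pd[1] <- 1
  pixdim <- as.numeric(pixdim)
  pd[seq_along(pixdim) + 1L] <- pixdim
  if (all(pd[2:4] == 0)) pd[2:4] <- 1
  dim8 <- integer(8)
  dim8[1] <- length(dims)
  dim8[2:(1 + length(dims))] <- dims
  dim8[dim8 == 0L] <- 1L

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v, size = 4) writeBin(as.numeric(v), con, size = size,
                                       endian = "little")
  wc <- function(s, width) {
    r <- raw(width)
    b <- charToRaw(s)
    r[seq_len(min(length(b), width))] <- b[seq_len(min(length(b), width))]
    writeBin(r, con)
  }
  wi(348L, 4)                 # sizeof_hdr
  writeBin(raw(36), con)      # data_type, db_name, extents, session_error,
                              # regular, dim_info (unused)
  wi(dim8, 2)                 # dim
  wf(c(0, 0, 0))              # intent_p1..3
  wi(0L, 2)                   # intent_code
  wi(dt, 2)                   # datatype
  wi(bitpix, 2)               # bitpix
  wi(0L, 2)                   # slice_start
  wf(pd)                      # pixdim
  wf(352)                     # vox_offset
  wf(1); wf(0)                # scl_slope, scl_inter
  wi(0L, 2)                   # slice_end
  writeBin(as.raw(c(0L, 2L)), con)  # slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))           # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)            # glmax, glmin
  wc("devoxel", 80)           # descrip
  wc("", 24)                  # aux_file
  wi(0L, 2); wi(1L, 2)        # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))     # quaternion + qoffset
  wf(c(pd[2], 0, 0, 0))       # srow_x
  wf(c(0, pd[3], 0, 0))       # srow_y
  wf(c(0, 0, pd[4], 0))       # srow_z
  wc("", 16)                  # intent_name
  wc("n+1", 4)                # magic (includes trailing NUL)
  writeBin(raw(4), con)       # no header extensions

  v <- as.vector(x)
  switch(datatype,
    uint8   = writeBin(as.integer(v), con, size = 1),
    int16   = writeBin(as.integer(v), con, size = 2, endian = "little"),
    int32   = writeBin(as.integer(v), con, size = 4, endian = "little"),
    float32 = writeBin(as.numeric(v), con, size = 4, endian = "little"),
    float64 = writeBin(as.numeric(v), con, size = 8, endian = "little")
  )
  invisible(path)
}
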