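# Minimal NIfTI-1 reader/writer.
#
# The pipeline only needs 3D scalar images (PDFF maps and binary masks), so
# this implements exactly that slice of NIfTI-1: single-file .nii/.nii.gz,
# dtypes uint8/int8/int16/uint16/int32/float32/float64, scl_slope/scl_inter
# applied on read, both endiannesses detected via sizeof_hdr. Orientation
# fields are passed through opaquely; all computation downstream is in voxel
# space.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

read_file_raw <- function(path) {
  con <- gzfile(path, "rb")   # transparently handles uncompressed files too
  on.exit(close(con))
  chunks <- list()
  repeat {
    ch <- readBin(con, "raw", n = 2^20)
    if (length(ch) == 0L) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  do.call(c, chunks)
}

#' Read a 3D NIfTI-1 image
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `values` (3D numeric array), `voxel_size` (length-3,
#'   mm), `datatype` (NIfTI code) and `header` (raw 348-byte header).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path))
    stop_pdff("NIfTI file not found: %s", path, class = "pdff_io_error")
  bytes <- read_file_raw(path)
  if (length(bytes) < 352L)
    stop_pdff("file too short for a NIfTI-1 header: %s", path,
              class = "pdff_io_error")
  endian <- "little"
  if (readBin(bytes[1:4], "integer", 1L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(bytes[1:4], "integer", 1L, 4L, endian = endian) != 348L)
      stop_pdff("not a NIfTI-1 file (bad sizeof_hdr): %s", path,
                class = "pdff_io_error")
  }
  rd_i16 <- function(off, n) readBin(bytes[(off + 1):(off + 2 * n)],
                                     "integer", n, 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(bytes[(off + 1):(off + 4 * n)],
                                     "double", n, 4L, endian = endian)
  dim       <- rd_i16(40L, 8L)
  datatype  <- rd_i16(70L, 1L)
  pixdim    <- rd_f32(76L, 8L)
  voxoff    <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)

  ndim <- dim[1L]
  extents <- dim[seq(2L, length.out = max(ndim, 1L))]
  extents[extents == 0L] <- 1L
  if (ndim > 3L && any(extents[-(1:3)] > 1L))
    stop_pdff("expected a 3D scalar image, got %dD with dim %s: %s",
              ndim, paste(extents, collapse = "x"), path,
              class = "pdff_shape_error")
  shape <- c(extents[seq_len(min(ndim, 3L))], rep(1L, max(0L, 3L - ndim)))

  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt))
    stop_pdff("unsupported NIfTI datatype code %d in %s", datatype, path,
              class = "pdff_io_error")
  n <- prod(shape)
  off <- as.integer(round(voxoff))
  need <- off + n * dt$size
  if (length(bytes) < need)
    stop_pdff("truncated NIfTI data in %s", path, class = "pdff_io_error")
  vals <- readBin(bytes[(off + 1):need], dt$what, n, dt$size,
                  signed = dt$signed, endian = endian)
  vals <- as.double(vals)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  vox <- pixdim[2:4]
  vox[!is.finite(vox) | vox <= 0] <- 1
  list(values = array(vals, dim = shape), voxel_size = vox,
       datatype = datatype, header = bytes[1:348])
}

#' Write a 3D array as NIfTI-1
#'
#' @param values 3D numeric array.
#' @param path output path; `.gz` suffix selects gzip compression.
#' @param voxel_size voxel spacing in mm (length 3).
#' @param datatype `"float32"` (default) or `"uint8"` (for masks).
#' @keywords internal
write_nifti <- function(values, path, voxel_size = c(1.5, 1.5, 1.5),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(values)) == 3L, length(voxel_size) == 3L)
  code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(n) writeBin(raw(n), con)

  wb(348L, 4L)                      # sizeof_hdr
  pad(36L)                          # data_type..dim_info
  wb(as.integer(c(3L, dim(values), 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  pad(12L)                          # intent_p1..p3
  wb(0L, 2L)                        # intent_code
  wb(code, 2L)                      # datatype
  wb(bitpix, 2L)                    # bitpix
  wb(0L, 2L)                        # slice_start
  wb(c(1, voxel_size, 1, 1, 1, 1), 4L)   # pixdim[8]
  wb(352, 4L)                       # vox_offset
  wb(1, 4L)                         # scl_slope
  wb(0, 4L)                         # scl_inter
  pad(4L)                           # slice_end, slice_code, xyzt_units
  pad(16L)                          # cal_max..toffset
  pad(8L)                           # glmax, glmin
  pad(80L + 24L)                    # descrip, aux_file
  wb(c(0L, 0L), 2L)                 # qform_code, sform_code
  pad(24L)                          # quaterns/qoffsets
  srow <- rbind(c(voxel_size[1], 0, 0, 0),
                c(0, voxel_size[2], 0, 0),
                c(0, 0, voxel_size[3], 0))
  wb(as.double(t(srow)), 4L)        # srow_x/y/z
  pad(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  pad(4L)                           # extension flag
  if (datatype == "float32") wb(as.double(values), 4L)
  else writeBin(as.integer(values), con, size = 1L)
  invisible(path)
}
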