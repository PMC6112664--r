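#' Minimal NIfTI-1 writer and reader
#'
#' Writes a numeric 2D-5D array as an uncompressed single-file NIfTI-1
#' image (.nii, float32 or float64, RAS+ diagonal sform, little-endian).
#' The array must already be in (x, y, z[, t]) index order. The reader
#' handles the same subset (magic `n+1`, datatypes float32, float64,
#' int16, uint8; no compression, no extensions beyond skipping
#' `vox_offset`). This is deliberately a minimal implementation for the
#' package's own exports, not a general-purpose NIfTI library.
#'
#' @param img numeric array (x fastest).
#' @param path output file path (.nii).
#' @param voxel_size mm per voxel along x, y, z.
#' @param time_step seconds per frame for 4D data.
#' @param datatype "float32" or "float64".
#' @return `write_nifti()`: the path, invisibly. `read_nifti()`: a list
#'   with `data` (array) and `pixdim`.
#' @export
write_nifti <- function(img, path, voxel_size = c(1, 1, 1), time_step = 1,
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  nd <- length(dim(img))
  stopifnot(nd >= 2, nd <= 5)
  dims <- rep(1L, 8); dims[1] <- nd; dims[1 + seq_len(nd)] <- dim(img)
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- voxel_size[1:3]
  if (nd >= 4) pixdim[5] <- time_step
  dt_code <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  ws <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348)                          # sizeof_hdr
  wc(36)                           # data_type..dim_info (unused)
  ws(dims)                         # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..3
  ws(0)                            # intent_code
  ws(dt_code); ws(bitpix); ws(0)   # datatype, bitpix, slice_start
  wf(pixdim)                       # pixdim[8]
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  ws(0); wc(1)                     # slice_end, slice_code
  writeBin(as.raw(10L), con)       # xyzt_units: mm (2) | sec (8)
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_dur, toffset
  wi(c(0, 0))                      # glmax, glmin
  wc(80); wc(24)                   # descrip, aux_file
  ws(0); ws(1)                     # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                    # quatern_b/c/d, qoffset_x/y/z
  wf(c(voxel_size[1], 0, 0, 0))    # srow_x
  wf(c(0, voxel_size[2], 0, 0))    # srow_y
  wf(c(0, 0, voxel_size[3], 0))    # srow_z
  wc(16)                           # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); wc(1)  # magic "n+1\0"
  wc(4)                            # extension indicator
  writeBin(as.numeric(img), con, size = bitpix / 8, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n = 1) readBin(con, "integer", n, size = 4, endian = "little")
  rs <- function(n = 1) readBin(con, "integer", n, size = 2, endian = "little")
  rf <- function(n = 1) readBin(con, "numeric", n, size = 4, endian = "little")
  hdr_size <- ri()
  if (hdr_size != 348) stop("not an uncompressed NIfTI-1 file")
  invisible(readBin(con, "raw", 36))
  dims <- rs(8)
  invisible(rf(3)); invisible(rs(1))
  dt_code <- rs(); bitpix <- rs(); invisible(rs(1))
  pixdim <- rf(8)
  vox_offset <- rf()
  invisible(rf(2)); invisible(rs(1)); invisible(readBin(con, "raw", 2))
  invisible(rf(4)); invisible(ri(2))
  invisible(readBin(con, "raw", 104))  # descrip + aux_file
  invisible(rs(2))                     # qform_code, sform_code
  invisible(rf(18))                    # quatern/qoffset (6) + srow (12)
  invisible(readBin(con, "raw", 16))   # intent_name
  magic <- rawToChar(readBin(con, "raw", 3))
  if (magic != "n+1") stop("unsupported NIfTI magic: ", magic)

  nd <- dims[1]
  shape <- dims[1 + seq_len(nd)]
  n <- prod(shape)
  seek(con, where = vox_offset, origin = "start")
  data <- switch(as.character(dt_code),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "4" = readBin(con, "integer", n, size = 2, endian = "little"),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                             endian = "little")),
    stop("unsupported NIfTI datatype code: ", dt_code))
  list(data = array(data, dim = shape), pixdim = pixdim[1 + seq_len(nd)])
}

#' Export phantom ground-truth maps as NIfTI
#'
#' Writes pd, t1, t2s and labels of a phantom volume as one NIfTI file per
#' map (arrays are `[z, y, x]` internally and written in (x, y, z) order).
#'
#' @param vol a `phantom_volume`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named character vector of the written paths.
#' @export
export_ground_truth <- function(vol, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- rev(vol$voxel_size)   # (nz, ny, nx) sizes -> (x, y, z)
  paths <- c()
  for (m in c("pd", "t1", "t2s", "labels")) {
    arr <- aperm(vol[[m]] * 1.0, c(3, 2, 1))
    p <- file.path(dir, sprintf("%s_%s.nii", prefix, m))
    write_nifti(arr, p, voxel_size = vs)
    paths[m] <- p
  }
  paths
}

#' Export a reconstructed series as 4D NIfTI, one file per echo
#'
#' @param recon a `recon_result` (with or without frame dimension).
#' @param dir output directory.
#' @param voxel_size mm per voxel (x, y, z).
#' @param time_step frame spacing, s.
#' @param prefix file-name prefix.
#' @return character vector of written paths.
#' @export
export_recon_nifti <- function(recon, dir, voxel_size = c(3.1, 3.1, 5),
                               time_step = 1, prefix = "recon") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- recon$slice_images
  if (length(dim(img)) == 4) dim(img) <- c(dim(img), 1L)
  ne <- dim(img)[4]
  paths <- character(ne)
  for (e in seq_len(ne)) {
    # [ny, nx, slice, frame] -> (x, y, z, t)
    arr <- img[, , , e, , drop = FALSE]
    dim(arr) <- dim(img)[c(1, 2, 3, 5)]
    arr <- aperm(arr, c(2, 1, 3, 4))
    paths[e] <- file.path(dir, sprintf("%s_echo%d.nii", prefix, e))
    write_nifti(arr, paths[e], voxel_size = voxel_size,
                time_step = time_step)
  }
  paths
}
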