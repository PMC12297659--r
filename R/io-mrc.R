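# MRC2014 density-map I/O.
#
# Hand-written reader/writer for the small MRC subset the pipeline needs
# (modes 0/1/2, little-endian): no R package in this stack reads MRC.
# Conventions: 0-based voxel indexing; the origin is the physical position
# of the centre of voxel (0,0,0); the ORIGIN header field is preferred and,
# when all-zero, NXSTART*voxel_size is used instead (common cryo-EM
# practice; packages genuinely disagree here).

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32), little-endian.
#' The axis order is normalized to x-fastest using the MAPC/MAPR/MAPS
#' header words, so `values[i, j, k]` always indexes (x, y, z). The voxel
#' size is taken from CELLA/MX and must be isotropic within 0.1%.
#'
#' @param path path to an MRC file.
#' @return A [density_map].
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fsz <- file.info(path)$size
  if (fsz < MRC_HEADER_BYTES)
    stop(sprintf("malformed MRC header: file has %d bytes, need %d",
                 fsz, MRC_HEADER_BYTES), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", MRC_HEADER_BYTES)
  int_at <- function(w, n = 1L)
    readBin(hdr[(4 * (w - 1) + 1):(4 * (w - 1) + 4 * n)], "integer",
            n = n, size = 4L, endian = "little")
  dbl_at <- function(w, n = 1L)
    readBin(hdr[(4 * (w - 1) + 1):(4 * (w - 1) + 4 * n)], "double",
            n = n, size = 4L, endian = "little")
  nc <- int_at(1, 3)               # nx, ny, nz (columns, rows, sections)
  mode <- int_at(4)
  nstart <- int_at(5, 3)
  m <- int_at(8, 3)                # mx, my, mz
  cella <- dbl_at(11, 3)
  mapcrs <- int_at(17, 3)
  nsymbt <- int_at(24)
  origin_hdr <- dbl_at(50, 3)
  magic <- rawToChar(hdr[209:211])
  if (!identical(substr(magic, 1, 3), "MAP"))
    stop("malformed MRC header: missing 'MAP ' magic at byte 208",
         call. = FALSE)
  if (!(mode %in% c(0L, 1L, 2L)))
    stop("unsupported MRC mode ", mode, " (modes 0/1/2 supported)",
         call. = FALSE)
  if (any(nc < 1L) || any(m < 1L))
    stop("malformed MRC header: non-positive dimensions", call. = FALSE)
  if (!all(sort(mapcrs) == 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS is not a permutation of 1:3",
         call. = FALSE)
  vox3 <- cella / m
  if (any(vox3 <= 0))
    stop("malformed MRC header: non-positive cell dimensions", call. = FALSE)
  if ((max(vox3) - min(vox3)) / mean(vox3) > 1e-3)
    stop(sprintf("anisotropic voxel size (%.6g, %.6g, %.6g) not supported",
                 vox3[1], vox3[2], vox3[3]), call. = FALSE)
  voxel <- mean(vox3)

  bpv <- c(`0` = 1L, `1` = 2L, `2` = 4L)[as.character(mode)]
  nvox <- prod(as.numeric(nc))
  need <- MRC_HEADER_BYTES + nsymbt + nvox * bpv
  if (fsz < need)
    stop(sprintf("truncated MRC file: %d bytes present, %d required (data ends at byte offset %d)",
                 fsz, need, need), call. = FALSE)
  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))
  vals <- if (mode == 2L)
    readBin(con, "double", n = nvox, size = 4L, endian = "little")
  else
    readBin(con, "integer", n = nvox, size = bpv, signed = TRUE,
            endian = "little")
  if (!all(is.finite(vals)))
    stop("map contains non-finite values", call. = FALSE)
  arr <- array(as.numeric(vals), dim = nc)

  # columns/rows/sections carry axes mapcrs; permute to (x, y, z).
  perm <- match(1:3, mapcrs)
  if (!all(perm == 1:3)) arr <- aperm(arr, perm)
  nstart_xyz <- nstart[perm]
  origin <- if (all(abs(origin_hdr) < 1e-12)) nstart_xyz * voxel
            else origin_hdr
  density_map(arr, voxel, origin)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' Round-trips exactly: values are stored as float32 so a map produced by
#' this package (float32-representable) reads back bitwise-equal, and the
#' voxel size is reproduced within 1e-6.
#'
#' @param map a [density_map].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  if (!all(is.finite(map$values)))
    stop("refusing to write non-finite density values", call. = FALSE)
  d <- dim(map$values)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- map$values
  wi(d)                       # nx ny nz
  wi(2L)                      # mode 2 = float32
  wi(c(0L, 0L, 0L))           # nstart
  wi(d)                       # mx my mz
  wf(d * map$voxel_size)      # cella
  wf(c(90, 90, 90))           # cellb
  wi(1:3)                     # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))
  wi(c(1L, 0L))               # ispg, nsymbt
  wi(rep(0L, 2))              # extra words 25-26
  writeBin(charToRaw("MRCO"), con)  # exttyp (word 27)
  wi(20140L)                  # nversion
  wi(rep(0L, 21))             # extra words 29-49
  wf(map$origin)              # origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(sd(as.vector(v)))        # rms
  wi(1L)                      # nlabl
  lab <- sprintf("%-80s", "axofit")
  writeBin(charToRaw(paste0(lab, strrep(" ", 80 * 9))), con)
  wf(as.vector(v))
  invisible(path)
}
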