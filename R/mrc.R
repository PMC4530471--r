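#' Read an MRC/CCP4 density map
#'
#' Supports mode 2 (32-bit float) maps, the format used for deposited
#' cryo-EM reconstructions.  Axis order is normalised to X-fastest on
#' read using the MAPC/MAPR/MAPS header words.  The origin is taken
#' from the ORIGIN header words; when those are all zero and the start
#' indices are not, it falls back to start-index times voxel size.
#'
#' @param path MRC/CCP4 file.
#' @return A `density_map`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_flt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2 float)")
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_flt[11:13]
  mapcrs <- hdr_int[17:19]
  nsymbt <- hdr_int[24]
  origin_words <- hdr_flt[50:52]
  voxel <- cella[1] / mxyz[1]
  if (!isTRUE(all.equal(cella / mxyz, rep(cella[1] / mxyz[1], 3),
                        tolerance = 1e-4)))
    warning("anisotropic voxel size; using the x spacing")
  seek(con, 1024 + nsymbt)
  n <- prod(nxyz)
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n) stop("truncated MRC data block")
  arr <- array(vals, dim = nxyz)           # file order: col, row, section
  # permute so that array index 1 is crystal axis X, 2 is Y, 3 is Z
  perm <- order(mapcrs)                    # position of axis 1,2,3 in file order
  if (!all(perm == 1:3)) arr <- aperm(arr, perm)
  if (all(origin_words == 0) && any(nstart != 0)) {
    origin <- nstart[perm] * voxel
  } else {
    origin <- origin_words
  }
  density_map(arr, voxel, origin)
}

#' Write a density map as MRC/CCP4 (mode 2)
#'
#' Voxel size and origin are stored in the CELLA and ORIGIN header
#' words and survive a read/write round trip bit-exactly (values are
#' stored as 32-bit floats, so map values themselves are rounded to
#' single precision).
#'
#' @param map a `density_map`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_mrc <- function(map, path) {
  v <- map$values
  d <- dim(v)
  con <- file(path, "wb")
  on.exit(close(con))
  w_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_flt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  vox <- map$voxel_size
  w_int(d)                       # NX NY NZ
  w_int(2L)                      # MODE 2
  w_int(c(0L, 0L, 0L))           # NXSTART..
  w_int(d)                       # MX MY MZ
  w_flt(d * vox)                 # CELLA
  w_flt(c(90, 90, 90))           # CELLB
  w_int(c(1L, 2L, 3L))           # MAPC MAPR MAPS
  w_flt(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  w_int(1L)                      # ISPG
  w_int(0L)                      # NSYMBT
  w_int(rep(0L, 25))             # EXTRA (words 25-49)
  w_flt(map$origin)              # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  w_flt(stats::sd(as.vector(v))) # RMS
  w_int(0L)                      # NLABL
  writeBin(raw(800), con)        # labels
  w_flt(as.vector(v))
  invisible(path)
}
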