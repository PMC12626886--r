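#' Read and write MRC2014 density maps
#'
#' Minimal MRC2014 support for mode 2 (32-bit float) maps, the mode used by
#' subtomogram-averaging depositions. `write_mrc` then `read_mrc`
#' round-trips grid values bit-exactly (at float32 precision) and the voxel
#' size to float32 precision. Non-cubic grids are read with a warning
#' because the alignment operations require cubic grids.
#'
#' @param path file path.
#' @param vol a [density_volume()].
#' @return `read_mrc` returns a [density_volume()]; `write_mrc` returns
#'   `path` invisibly.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  if (length(hdr_ints) < 10) stop("read_mrc(): truncated MRC header")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  if (mode != 2L) {
    stop(sprintf("read_mrc(): unsupported MRC mode %d (only mode 2, 32-bit float)", mode))
  }
  mxyz <- hdr_ints[8:10]                                               # mx my mz
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little") # dmin dmax dmean
  ispg_nsym <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  if (length(ispg_nsym) < 2) stop("read_mrc(): truncated MRC header")
  extra <- readBin(con, "integer", n = 25, size = 4, endian = "little")
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map_tag <- rawToChar(readBin(con, "raw", n = 4))
  machst <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  rms <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  nlabl <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(nlabl) < 1) stop("read_mrc(): truncated MRC header")
  labels <- readBin(con, "raw", n = 800)
  if (length(labels) < 800) stop("read_mrc(): truncated MRC header")
  if (nchar(map_tag) >= 3 && substr(map_tag, 1, 3) != "MAP") {
    warning("read_mrc(): MAP magic tag missing; attempting to read anyway")
  }
  nvox <- as.double(nx) * ny * nz
  dat <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(dat) < nvox) stop("read_mrc(): truncated data section")
  if (mxyz[1] <= 0) mxyz[1] <- nx
  voxel <- cella[1] / mxyz[1]
  if (voxel <= 0) voxel <- 1
  if (!(nx == ny && ny == nz)) {
    warning("read_mrc(): non-cubic grid; alignment operations require cubic volumes")
  }
  density_volume(array(dat, c(nx, ny, nz)), voxel_size = voxel, origin = origin)
}

#' @rdname read_mrc
#' @export
write_mrc <- function(vol, path) {
  stopifnot(inherits(vol, "density_volume"))
  d <- dim(vol$grid)
  g <- as.numeric(vol$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2L)                      # mode 2
  wi(c(0L, 0L, 0L))           # nxstart
  wi(d)                       # mx my mz
  wf(d * vol$voxel_size)      # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))
  wi(c(1L, 0L))               # ispg, nsymbt
  wi(rep(0L, 25))             # extra
  wf(vol$origin)              # MRC2014 origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(sd(g))
  wi(1L)                      # nlabl
  lab <- charToRaw(sprintf("%-80s", "porekit density map"))
  writeBin(c(lab, raw(800 - length(lab))), con)
  wf(g)
  invisible(path)
}
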