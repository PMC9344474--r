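# MRC2014 / CCP4 mode-2 (float32) map writer and reader for density grids.
# Orthogonal axes only: voxel size equals the grid spacing and the Cartesian
# grid origin is stored in the MRC2014 ORIGIN header words.

#' Write a density grid as an MRC2014/CCP4 map
#'
#' Writes a mode-2 (32-bit float) map with column/row/section order x, y, z,
#' cubic voxels of size `grid$spacing` and the Cartesian origin recorded in
#' the ORIGIN header fields, readable by standard molecular viewers.
#'
#' @param grid a `dnahydro_grid` from [accumulate_density()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_density_map <- function(grid, path) {
  stopifnot(inherits(grid, "dnahydro_grid"))
  dims <- grid$dims
  if (any(dims < 1L)) stop("grid must have dims >= 1 on each axis")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.vector(grid$values)

  wi(dims)                      # NX NY NZ (columns, rows, sections)
  wi(2L)                        # MODE 2 = float32
  wi(c(0L, 0L, 0L))             # NXSTART NYSTART NZSTART
  wi(dims)                      # MX MY MZ
  wf(dims * grid$spacing)       # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(c(1L, 2L, 3L))             # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(1L)                        # ISPG
  wi(0L)                        # NSYMBT
  wi(rep(0L, 25L))              # EXTRA (words 26-50)
  wf(grid$origin)               # ORIGIN (MRC2014, words 50-52)
  writeBin(charToRaw("MAP "), con)                     # MAP stamp
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)     # MACHST little-endian
  wf(stats::sd(v) * sqrt(max(1, length(v) - 1) / length(v)))  # RMS (population)
  wi(0L)                        # NLABL
  writeBin(raw(800L), con)      # labels
  wf(v)                         # data, x fastest
  invisible(path)
}

#' Read an MRC2014/CCP4 map written by [write_density_map()]
#'
#' @param path map file path.
#' @param category category label to attach (`"base"`, `"backbone"` or other).
#' @return a `dnahydro_grid`.
#' @export
read_density_map <- function(path, category = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")

  dims <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2)")
  ri(3L)                        # NxSTART
  ri(3L)                        # MX MY MZ
  cella <- rf(3L)
  rf(3L)                        # CELLB
  mapcrs <- ri(3L)
  if (!identical(mapcrs, 1:3)) stop("unsupported axis order in MRC file")
  rf(3L)                        # DMIN DMAX DMEAN
  ri(1L)                        # ISPG
  nsymbt <- ri(1L)
  ri(25L)                       # EXTRA
  origin <- rf(3L)
  readBin(con, "raw", n = 4L)   # MAP stamp
  readBin(con, "raw", n = 4L)   # MACHST
  rf(1L)                        # RMS
  ri(1L)                        # NLABL
  readBin(con, "raw", n = 800L + nsymbt)
  v <- rf(prod(dims))
  spacing <- cella[1L] / dims[1L]
  new_grid(origin = origin, spacing = spacing, dims = dims,
           values = array(v, dim = dims), category = category)
}
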