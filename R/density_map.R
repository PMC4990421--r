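#' Volumetric density map
#'
#' A 3-D scalar grid with a physical origin and voxel spacing.  The first
#' array index runs along x and is the fastest-varying axis, matching the
#' column order of MRC/CCP4 files written with MAPC/MAPR/MAPS = 1/2/3.  The
#' world coordinate of 0-based grid index \code{(i, j, k)} is
#' \code{origin + (i, j, k) * voxel}.
#'
#' @param values 3-D numeric array of densities (arbitrary units).
#' @param origin numeric length-3, world coordinate (Angstrom) of voxel
#'   \code{(0, 0, 0)}.
#' @param voxel numeric length-3 (or scalar), voxel spacing in Angstrom; all
#'   entries must be strictly positive.
#' @return An object of class \code{density_map}.
#' @export
density_map <- function(values, origin = c(0, 0, 0), voxel = c(1, 1, 1)) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  if (!is.array(values) || length(dim(values)) != 3)
    stop("`values` must be a 3-D array")
  if (length(origin) != 3 || !all(is.finite(origin)))
    stop("`origin` must be a finite coordinate triple")
  if (length(voxel) != 3 || !all(is.finite(voxel)) || any(voxel <= 0))
    stop("`voxel` spacings must be strictly positive")
  if (!all(is.finite(values)))
    stop("map values must all be finite")
  structure(list(values = values, origin = as.numeric(origin),
                 voxel = as.numeric(voxel)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels, spacing (%g, %g, %g) A\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3]))
  cat(sprintf("  origin (%g, %g, %g) A, range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$values)

# world coordinates of every voxel along one axis (0-based indexing)
axis_coords <- function(map, axis) {
  n <- dim(map$values)[axis]
  map$origin[axis] + (seq_len(n) - 1) * map$voxel[axis]
}

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$voxel - b$voxel) < tol)
}

#' Read an MRC/CCP4 density map
#'
#' Reads mode-2 (float32) MRC/CCP4 volumes with the standard 1/2/3 axis
#' order.  The origin is taken from the MRC2014 ORIGIN header words; when all
#' of those are zero and a start index is set, the CCP4-style fallback
#' \code{nstart * voxel} is used instead.
#'
#' @param path path to an existing MRC/CCP4 file.
#' @return A \code{\link{density_map}}.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  mgrid <- hdr_int[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "integer", n = 2, size = 4, endian = "little") # ispg, nsymbt
  readBin(con, "integer", n = 25, size = 4, endian = "little") # extra
  org <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readChar(con, 4, useBytes = TRUE) # "MAP "
  readBin(con, "integer", n = 1, size = 4, endian = "little") # machst
  readBin(con, "numeric", n = 1, size = 4, endian = "little") # rms
  readBin(con, "integer", n = 1, size = 4, endian = "little") # nlabl
  readBin(con, "raw", n = 800) # labels
  if (any(c(nx, ny, nz) <= 0))
    stop("malformed MRC header: non-positive dimension NX/NY/NZ")
  if (mode != 2)
    stop("unsupported MRC MODE ", mode, " (only mode 2, float32, is handled)")
  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal cell: CELLB angles must all be 90 degrees")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported axis order: MAPC/MAPR/MAPS must be 1/2/3")
  if (any(mgrid <= 0))
    stop("malformed MRC header: non-positive sampling MX/MY/MZ")
  voxel <- cella / mgrid
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop("malformed MRC header: non-positive voxel spacing (CELLA/MX)")
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4, endian = "little")
  if (length(vals) < nx * ny * nz)
    stop("malformed MRC file: truncated data section")
  origin <- if (all(org == 0) && any(nstart != 0)) nstart * voxel else org
  density_map(array(vals, dim = c(nx, ny, nz)), origin = origin, voxel = voxel)
}

#' Write a density map as MRC/CCP4
#'
#' Writes mode-2 (float32) volumes; round trips through
#' \code{\link{read_map}} preserve geometry and values to float32 precision.
#'
#' @param map a \code{\link{density_map}}.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(d * map$voxel, 90, 90, 90)), con, size = 4, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  v <- map$values
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(integer(25), con, size = 4, endian = "little") # extra
  writeBin(as.numeric(map$origin), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con) # little-endian machine stamp
  writeBin(stats::sd(as.numeric(v)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little") # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(NULL)
}
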