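#' Density map container
#'
#' A 3-D voxel grid of density values with its physical geometry. The
#' coordinate convention used throughout the package: all positions are in
#' Angstrom in the map frame, and voxel (i, j, k) (1-based in R) has its
#' centre at \code{origin + ((i-1)*sx, (j-1)*sy, (k-1)*sz)}.
#'
#' @param data 3-D numeric array of density values (arbitrary units).
#' @param voxel_size numeric length-3, Angstrom per voxel along x, y, z.
#' @param origin numeric length-3, Angstrom position of voxel (1,1,1).
#' @param axis_order integer length-3 permutation mapping file axes to
#'   (x, y, z); kept for provenance, data is always stored x,y,z.
#' @return an object of class \code{density_map}.
#' @export
density_map <- function(data, voxel_size, origin = c(0, 0, 0),
                        axis_order = c(1L, 2L, 3L)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  origin <- rep_len(as.numeric(origin), 3)
  if (any(voxel_size <= 0)) stop("voxel_size components must be > 0")
  if (any(!is.finite(origin))) stop("origin must be finite")
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 axis_order = as.integer(axis_order)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map %d x %d x %d, voxel %.4g/%.4g/%.4g A, origin (%.4g, %.4g, %.4g) A>\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$data)

# check two maps share a grid
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# voxel-centre coordinates along each axis
grid_axes <- function(map) {
  d <- dim(map$data)
  lapply(1:3, function(k) map$origin[k] + (seq_len(d[k]) - 1) * map$voxel_size[k])
}

#' Read an MRC2014 / CCP4 density map
#'
#' Data modes 0 (int8), 1 (int16) and 2 (float32) are accepted. The data
#' array is re-ordered to x,y,z axis order. The origin is taken from the
#' ORIGIN header record when set, otherwise from NXSTART/NYSTART/NZSTART
#' times the voxel size; when both are set and inconsistent the ORIGIN
#' record wins with a warning.
#'
#' @param path path to an MRC/CCP4 file.
#' @return a \code{\link{density_map}}.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_flt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_flt[11:13]
  mapcrs <- hdr_int[17:19]
  nsymbt <- hdr_int[24]
  orig <- hdr_flt[50:52]

  if (any(nxyz <= 0) || any(nxyz > 1e5))
    stop("malformed header: NX/NY/NZ out of range: ", paste(nxyz, collapse = ","))
  if (!(mode %in% c(0L, 1L, 2L)))
    stop("unsupported MODE ", mode, " (only modes 0/1/2 accepted)")
  if (!identical(sort(mapcrs), 1:3))
    stop("malformed header: MAPC/MAPR/MAPS is not a permutation of 1..3: ",
         paste(mapcrs, collapse = ","))
  if (any(mxyz <= 0))
    stop("malformed header: MX/MY/MZ must be positive: ", paste(mxyz, collapse = ","))
  if (any(!is.finite(cella)) || any(cella <= 0))
    stop("malformed header: CELLA must be positive finite: ", paste(cella, collapse = ","))

  seek(con, 1024 + max(0, nsymbt))
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(vals) < n) stop("truncated data section: expected ", n,
                             " values, got ", length(vals))
  raw <- array(vals, dim = nxyz)

  # file dim j runs along crystal axis mapcrs[j]; permute to x,y,z
  perm <- match(1:3, mapcrs)
  data <- aperm(raw, perm)

  voxel <- cella / mxyz                  # per crystal axis x,y,z
  nstart_axis <- integer(3)
  nstart_axis[mapcrs] <- nstart          # per-axis start indices
  origin_nstart <- nstart_axis * voxel
  if (any(orig != 0)) {
    if (any(nstart_axis != 0) &&
        any(abs(orig - origin_nstart) > 0.5 * max(voxel)))
      warning("ORIGIN and NSTART records disagree; using ORIGIN")
    origin <- orig
  } else {
    origin <- origin_nstart
  }
  density_map(data, voxel, origin, axis_order = mapcrs)
}

#' Write a density map as MRC2014 (mode 2, float32)
#'
#' @param map a \code{\link{density_map}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)
  voxel <- map$voxel_size
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  nstart <- round(map$origin / voxel)
  exact_nstart <- all(abs(nstart * voxel - map$origin) < 1e-6)
  wi(d)                                  # NX NY NZ
  wi(2)                                  # MODE
  wi(if (exact_nstart) nstart else c(0, 0, 0))
  wi(d)                                  # MX MY MZ
  wf(d * voxel)                          # CELLA
  wf(c(90, 90, 90))                      # CELLB
  wi(1:3)                                # MAPC MAPR MAPS
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(1)                                  # ISPG
  wi(0)                                  # NSYMBT
  wi(rep(0L, 25))                        # EXTRA (words 25-49)
  wf(map$origin)                         # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.numeric(map$data)))    # RMS
  wi(1)                                  # NLABL
  lab <- sprintf("%-80s", "emval")
  writeChar(lab, con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, nchars = 720, eos = NULL)
  writeBin(as.vector(map$data), con, size = 4, endian = "little")
  invisible(path)
}
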