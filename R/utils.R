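#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed torsion angle of four points
#'
#' Dihedral about the b-c axis, in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# angle at p2 (degrees)
bond_angle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2)
  v <- unitv(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# NeRF atom placement: position D given A-B-C, bond length C-D, angle
# B-C-D (deg), torsion A-B-C-D (deg).
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# FFT sample frequencies in cycles per sample (numpy fftfreq convention)
fft_freq <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  k / n
}

# |s| array (1/Angstrom) for the FFT of a grid with given voxel sizes
freq_magnitude_grid <- function(dims, voxel_size) {
  fx <- fft_freq(dims[1]) / voxel_size[1]
  fy <- fft_freq(dims[2]) / voxel_size[2]
  fz <- fft_freq(dims[3]) / voxel_size[3]
  sq <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  sqrt(sq)
}

# smallest angular difference in degrees (wrapped to [0, 180])
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}
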