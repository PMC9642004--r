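ATOMIC_NUMBER <- c(H = 1, D = 1, C = 6, N = 7, O = 8, F = 9, NA_ = 11, MG = 12,
                   P = 15, S = 16, CL = 17, K = 19, CA_ = 20, MN = 25, FE = 26,
                   CO = 27, NI = 28, CU = 29, ZN = 30, SE = 34, BR = 35, I = 53,
                   MO = 42, W = 74)

atomic_number <- function(element) {
  z <- ATOMIC_NUMBER[element]
  # metals sharing symbols with common model elements are keyed with "_"
  z[is.na(z)] <- ATOMIC_NUMBER[paste0(element[is.na(z)], "_")]
  z[is.na(z)] <- 6
  unname(z)
}

# raised-cosine low-pass at spatial frequency s_c (1/A); ramp over
# [0.9 s_c, 1.1 s_c]
lowpass_filter <- function(smag, s_c) {
  s1 <- 0.9 * s_c
  s2 <- 1.1 * s_c
  f <- array(0, dim = dim(smag))
  f[smag <= s1] <- 1
  mid <- smag > s1 & smag < s2
  f[mid] <- 0.5 * (1 + cos(pi * (smag[mid] - s1) / (s2 - s1)))
  f
}

#' Simulate a theoretical density map from an atomic model
#'
#' Each atom contributes an isotropic 3-D Gaussian centred on its
#' coordinates with weight occupancy x atomic number and variance from
#' \code{B_eff = B_atom + 4 d^2} (d = nominal resolution in Angstrom;
#' the resolution-dependent broadening term is a stated, reproducible
#' stand-in for production blurring kernels), using the crystallographic
#' convention \code{sigma^2 = B_eff / (8 pi^2)}. Gaussians are truncated
#' at 3 sigma + 1 voxel. The rasterised map is then low-pass filtered
#' with a raised-cosine edge at 1/d.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param template a \code{\link{density_map}} supplying the output grid
#'   geometry (its data values are ignored).
#' @param resolution nominal resolution d in Angstrom; must satisfy
#'   d >= 2 max(voxel_size) (Nyquist).
#' @param lowpass apply the raised-cosine low-pass (default TRUE).
#' @return a \code{\link{density_map}} on the template grid.
#' @export
simulate_map <- function(model, template, resolution, lowpass = TRUE) {
  stopifnot(inherits(model, "atomic_model"), inherits(template, "density_map"))
  voxel <- template$voxel_size
  if (resolution < 2 * max(voxel))
    stop("resolution must be >= 2 x max(voxel_size) (Nyquist): got ",
         resolution, " vs voxel ", max(voxel))
  a <- select_conformer(model)$atoms
  d3 <- dim(template$data)
  out <- array(0, dim = d3)
  ax <- grid_axes(template)
  b_res <- 4 * resolution^2
  z <- atomic_number(a$element)
  skipped <- 0L
  for (i in seq_len(nrow(a))) {
    if (a$occ[i] <= 0) next
    sigma2 <- (a$b[i] + b_res) / (8 * pi^2)
    sigma <- sqrt(sigma2)
    pos <- c(a$x[i], a$y[i], a$z[i])
    idx0 <- (pos - template$origin) / voxel + 1      # fractional 1-based index
    if (any(idx0 < 1 - 5) || any(idx0 > d3 + 5)) { skipped <- skipped + 1L; next }
    rad <- 3 * sigma + voxel                         # truncation per axis
    w <- a$occ[i] * z[i] / (2 * pi * sigma2)^1.5
    rng <- lapply(1:3, function(k) {
      lo <- max(1L, ceiling(idx0[k] - rad[k] / voxel[k]))
      hi <- min(d3[k], floor(idx0[k] + rad[k] / voxel[k]))
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(rng) == 0)) next
    gx <- exp(-(ax[[1]][rng[[1]]] - pos[1])^2 / (2 * sigma2))
    gy <- exp(-(ax[[2]][rng[[2]]] - pos[2])^2 / (2 * sigma2))
    gz <- exp(-(ax[[3]][rng[[3]]] - pos[3])^2 / (2 * sigma2))
    out[rng[[1]], rng[[2]], rng[[3]]] <-
      out[rng[[1]], rng[[2]], rng[[3]]] + w * outer(outer(gx, gy), gz)
  }
  if (skipped > 0)
    warning(skipped, " atom(s) outside grid (beyond 5-voxel pad) skipped")
  if (lowpass) {
    smag <- freq_magnitude_grid(d3, voxel)
    filt <- lowpass_filter(smag, 1 / resolution)
    out <- Re(fft(fft(out) * filt, inverse = TRUE)) / prod(d3)
  }
  density_map(out, voxel, template$origin)
}

# equal-width frequency shells up to a limit; returns per-voxel shell
# index (NA beyond limit) and shell centres
shell_index <- function(dims, voxel, n_shells, s_max = NULL) {
  smag <- freq_magnitude_grid(dims, voxel)
  if (is.null(s_max)) s_max <- min(1 / (2 * voxel))
  ds <- s_max / n_shells
  idx <- floor(smag / ds) + 1
  idx[idx > n_shells | smag > s_max] <- NA
  list(idx = idx, centres = (seq_len(n_shells) - 0.5) * ds, ds = ds, smag = smag)
}

#' Radial (Wilson-style) amplitude curve of a map
#'
#' FFT amplitudes averaged in equal-width spherical frequency shells up
#' to Nyquist; the curve records shell centres as squared spatial
#' frequency (1/A^2) and the log of the shell-mean amplitude.
#'
#' @param map a \code{\link{density_map}}.
#' @param n_shells number of shells (>= 4); default smallest grid
#'   dimension / 2.
#' @return a \code{wilson_curve}: data.frame with columns \code{s2}
#'   (1/A^2), \code{log_amp}, \code{n}.
#' @export
wilson_curve <- function(map, n_shells = min(dim(map$data)) %/% 2) {
  stopifnot(n_shells >= 4)
  if (all(map$data == 0)) stop("all-zero map: log amplitude undefined")
  amp <- Mod(fft(map$data))
  sh <- shell_index(dim(map$data), map$voxel_size, n_shells)
  ok <- !is.na(sh$idx)
  mean_amp <- tapply(amp[ok], sh$idx[ok], mean)
  cnt <- tapply(amp[ok], sh$idx[ok], length)
  ishell <- as.integer(names(mean_amp))
  out <- data.frame(s2 = sh$centres[ishell]^2,
                    log_amp = log(mean_amp), n = as.integer(cnt))
  out <- out[is.finite(out$log_amp) & out$n >= 1, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("wilson_curve", "data.frame")
  out
}

#' Detect over-sharpening from a Wilson curve
#'
#' Least-squares slope of log shell-mean amplitude versus squared
#' frequency over the highest-resolution fraction of shells. A positive
#' slope (amplitudes rising toward Nyquist) flags over-sharpening. Under
#' the B-factor convention, applying exp(+B s^2/4) shifts this slope by
#' +B/4.
#'
#' @param curve a \code{\link{wilson_curve}}.
#' @param high_res_fraction fraction of shells (highest frequencies)
#'   inspected; default 0.25.
#' @return list with \code{flag} (logical) and \code{slope} (A^2, d
#'   log-amplitude / d s^2).
#' @export
detect_oversharpening <- function(curve, high_res_fraction = 0.25) {
  n <- nrow(curve)
  k <- max(4, ceiling(high_res_fraction * n))
  if (k > n) stop("fewer than 4 shells in the inspected band")
  band <- curve[(n - k + 1):n, , drop = FALSE]
  fit <- stats::lm.fit(cbind(1, band$s2), band$log_amp)
  slope <- unname(fit$coefficients[2])
  list(flag = slope > 0, slope = slope)
}

# shell-mean Fourier amplitude scale factors, clamped
shell_scale_factors <- function(f_map, f_ref, sh, clamp = c(1e-3, 1e3)) {
  ok <- !is.na(sh$idx)
  m_map <- tapply(Mod(f_map)[ok], sh$idx[ok], mean)
  m_ref <- tapply(Mod(f_ref)[ok], sh$idx[ok], mean)
  sc <- m_ref / m_map
  capped <- !is.finite(sc) | sc < clamp[1] | sc > clamp[2]
  if (any(capped)) {
    warning(sum(capped), " shell scale factor(s) clamped to [",
            clamp[1], ", ", clamp[2], "]")
    sc[!is.finite(sc)] <- clamp[2]
    sc <- pmin(pmax(sc, clamp[1]), clamp[2])
  }
  sc
}

#' Scale a map's Fourier amplitudes to a reference, shell by shell
#'
#' Multiplies the map's Fourier coefficients per equal-width frequency
#' shell by (reference shell-mean amplitude / map shell-mean amplitude);
#' phases are untouched. Scale factors are clamped to [1e-3, 1e3].
#'
#' @param map,reference \code{\link{density_map}}s on identical grids.
#' @param n_shells shell count; default smallest grid dimension / 2.
#' @return the amplitude-scaled \code{\link{density_map}}.
#' @export
scale_amplitudes_global <- function(map, reference,
                                    n_shells = min(dim(map$data)) %/% 2) {
  if (!same_grid(map, reference)) stop("maps must share an identical grid")
  d3 <- dim(map$data)
  f_map <- fft(map$data)
  f_ref <- fft(reference$data)
  # bins follow the package-wide Nyquist-limited shell convention;
  # corner voxels beyond the Nyquist sphere take the last shell's factor
  sh <- shell_index(d3, map$voxel_size, n_shells)
  sc <- shell_scale_factors(f_map, f_ref, sh)
  full <- rep(NA_real_, n_shells)
  full[as.integer(names(sc))] <- sc
  last <- max(which(!is.na(full)))
  full[is.na(full)] <- full[last]
  ds <- sh$ds
  idx_all <- pmin(floor(sh$smag / ds) + 1, n_shells)
  scale_vox <- array(full[idx_all], dim = d3)
  out <- Re(fft(f_map * scale_vox, inverse = TRUE)) / prod(d3)
  density_map(out, map$voxel_size, map$origin)
}

#' Difference maps between an experimental and a model-derived map
#'
#' The model map is first amplitude-scaled (per shell) to the
#' experimental map, then subtracted voxelwise in both directions.
#'
#' @param experimental,model_map \code{\link{density_map}}s, same grid.
#' @param n_shells shell count for the amplitude scaling.
#' @return list with \code{exp_minus_model} and \code{model_minus_exp}.
#' @export
difference_map <- function(experimental, model_map,
                           n_shells = min(dim(experimental$data)) %/% 2) {
  scaled <- scale_amplitudes_global(model_map, experimental, n_shells)
  d1 <- density_map(experimental$data - scaled$data,
                    experimental$voxel_size, experimental$origin)
  d2 <- density_map(-d1$data, experimental$voxel_size, experimental$origin)
  list(exp_minus_model = d1, model_minus_exp = d2)
}

# boolean mask of voxels within `radius` Angstrom of any (heavy) model atom
model_mask <- function(model, template, radius = 3, heavy_only = TRUE) {
  a <- select_conformer(model)$atoms
  if (heavy_only) a <- a[!a$hydrogen, , drop = FALSE]
  d3 <- dim(template$data)
  voxel <- template$voxel_size
  ax <- grid_axes(template)
  mask <- array(FALSE, dim = d3)
  for (i in seq_len(nrow(a))) {
    pos <- c(a$x[i], a$y[i], a$z[i])
    rng <- lapply(1:3, function(k) {
      lo <- max(1L, floor((pos[k] - radius - template$origin[k]) / voxel[k]) + 1)
      hi <- min(d3[k], ceiling((pos[k] + radius - template$origin[k]) / voxel[k]) + 1)
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(rng) == 0)) next
    dx2 <- (ax[[1]][rng[[1]]] - pos[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - pos[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - pos[3])^2
    within <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
    mask[rng[[1]], rng[[2]], rng[[3]]] <-
      mask[rng[[1]], rng[[2]], rng[[3]]] | within
  }
  mask
}

#' Model-based local amplitude scaling (local sharpening)
#'
#' Rolling-window amplitude scaling of the experimental map against a
#' model-derived reference map: for every voxel inside a 3 Angstrom
#' dilated model mask, a cubic window centred on the voxel is
#' amplitude-scaled per shell to the corresponding reference window and
#' the centre voxel of the scaled window is written to the output.
#' Voxels outside the mask are 0.
#'
#' @param experimental experimental \code{\link{density_map}}.
#' @param reference_model_map model-derived reference map, same grid.
#' @param window window edge length in Angstrom (>= 5 x voxel size).
#' @param model optional \code{\link{atomic_model}} defining the
#'   model-occupied region; when absent the mask is derived from the
#'   reference map (voxels above 1% of its maximum, dilated 3 A).
#' @param mask_radius dilation radius for the model mask (A).
#' @return the locally scaled \code{\link{density_map}}.
#' @export
local_scale <- function(experimental, reference_model_map, window,
                        model = NULL, mask_radius = 3) {
  if (!same_grid(experimental, reference_model_map))
    stop("maps must share an identical grid")
  voxel <- experimental$voxel_size
  if (window < 5 * max(voxel)) stop("window must be >= 5 x voxel size")
  d3 <- dim(experimental$data)
  w <- floor(window / min(voxel))
  if (w %% 2 == 0) w <- w + 1
  if (w > min(d3)) stop("window larger than grid")
  if (!is.null(model)) {
    mask <- model_mask(model, experimental, radius = mask_radius)
  } else {
    core <- reference_model_map$data > 0.01 * max(reference_model_map$data)
    mask <- dilate_mask(core, voxel, mask_radius)
  }
  h <- (w - 1) %/% 2
  sh <- shell_index(c(w, w, w), voxel, max(2L, w %/% 2),
                    s_max = max(freq_magnitude_grid(c(w, w, w), voxel)) + 1e-12)
  shl <- sh$idx
  out <- array(0, dim = d3)
  idxs <- which(mask, arr.ind = TRUE)
  centre <- h + 1L
  for (r in seq_len(nrow(idxs))) {
    ctr <- idxs[r, ]
    lo <- ctr - h; hi <- ctr + h
    clo <- pmax(lo, 1L); chi <- pmin(hi, d3)
    we <- array(0, dim = c(w, w, w)); wr <- we
    sl <- lapply(1:3, function(k) (clo[k] - lo[k] + 1):(w - (hi[k] - chi[k])))
    we[sl[[1]], sl[[2]], sl[[3]]] <-
      experimental$data[clo[1]:chi[1], clo[2]:chi[2], clo[3]:chi[3]]
    wr[sl[[1]], sl[[2]], sl[[3]]] <-
      reference_model_map$data[clo[1]:chi[1], clo[2]:chi[2], clo[3]:chi[3]]
    fe <- fft(we)
    fr <- fft(wr)
    sc <- suppressWarnings(shell_scale_factors(fe, fr, list(idx = shl)))
    scv <- array(1, dim = c(w, w, w))
    ok <- !is.na(shl)
    scv[ok] <- sc[as.character(shl[ok])]
    scaled <- Re(fft(fe * scv, inverse = TRUE)) / w^3
    out[ctr[1], ctr[2], ctr[3]] <- scaled[centre, centre, centre]
  }
  density_map(out, voxel, experimental$origin)
}

# binary dilation by a spherical structuring element (FFT convolution)
dilate_mask <- function(mask, voxel, radius) {
  d3 <- dim(mask)
  ax <- lapply(1:3, function(k) {
    i <- fft_freq(d3[k]) * d3[k]          # 0,1,...,-1 wrapped offsets
    (i * voxel[k])^2
  })
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  kern <- array(as.numeric(r2 <= radius^2), dim = d3)
  conv <- Re(fft(fft(array(as.numeric(mask), dim = d3)) * fft(kern),
                 inverse = TRUE)) / prod(d3)
  conv > 0.5
}
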