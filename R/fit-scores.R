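#' Fourier shell correlation between two maps
#'
#' Per equal-width frequency shell,
#' FSC = Re sum(F1 conj(F2)) / sqrt(sum|F1|^2 sum|F2|^2) over the Fourier
#' voxels of the shell, up to Nyquist.
#'
#' @param map1,map2 \code{\link{density_map}}s on identical grids.
#' @param n_shells shell count; default smallest grid dimension / 2.
#' @return an \code{fsc_curve}: data.frame with columns \code{freq}
#'   (shell centre, 1/A), \code{fsc}, \code{n} (Fourier voxels).
#' @export
fsc_curve <- function(map1, map2, n_shells = min(dim(map1$data)) %/% 2) {
  if (!same_grid(map1, map2)) stop("maps must share an identical grid")
  f1 <- fft(map1$data)
  f2 <- fft(map2$data)
  sh <- shell_index(dim(map1$data), map1$voxel_size, n_shells)
  ok <- !is.na(sh$idx)
  idx <- sh$idx[ok]
  num <- tapply(Re(f1[ok] * Conj(f2[ok])), idx, sum)
  d1 <- tapply(Mod(f1[ok])^2, idx, sum)
  d2 <- tapply(Mod(f2[ok])^2, idx, sum)
  cnt <- tapply(rep(1L, sum(ok)), idx, sum)
  fsc <- as.numeric(num / sqrt(d1 * d2))
  ishell <- as.integer(names(num))
  out <- data.frame(freq = sh$centres[ishell], fsc = fsc, n = as.integer(cnt))
  bad <- !is.finite(out$fsc)
  if (any(bad)) {
    warning(sum(bad), " empty/degenerate shell(s) dropped")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) < n_shells && !any(bad))
    warning(n_shells - nrow(out), " empty shell(s) dropped")
  rownames(out) <- NULL
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' FSCavg: voxel-count-weighted average FSC up to a resolution cutoff
#'
#' @param curve an \code{\link{fsc_curve}}.
#' @param cutoff resolution cutoff in Angstrom; shells with frequency
#'   <= 1/cutoff contribute, weighted by their Fourier-voxel counts.
#' @return scalar fsc_avg in [-1, 1].
#' @export
fsc_average <- function(curve, cutoff) {
  keep <- curve$freq <= 1 / cutoff
  if (!any(keep)) stop("no shells at frequencies below 1/", cutoff, " 1/A")
  sum(curve$fsc[keep] * curve$n[keep]) / sum(curve$n[keep])
}

# soft mask: 1 within `radius` of any heavy atom, cosine falloff to 0
# over `falloff` Angstrom beyond
soft_mask <- function(model, template, radius = 3, falloff = 3) {
  inner <- model_mask(model, template, radius = radius)
  outer_m <- model_mask(model, template, radius = radius + falloff)
  m <- array(0, dim = dim(template$data))
  m[outer_m] <- 0.5     # provisional; refined below by distance band
  m[inner] <- 1
  # cosine ramp needs a distance estimate in the band; use successive
  # dilation rings at one-voxel resolution
  nring <- max(2L, ceiling(falloff / min(template$voxel_size)))
  prev <- inner
  for (r in seq_len(nring)) {
    cur <- model_mask(model, template, radius = radius + r * falloff / nring)
    ring <- cur & !prev
    m[ring] <- 0.5 * (1 + cos(pi * (r - 0.5) / nring))
    prev <- cur
  }
  m[!outer_m] <- 0
  m
}

#' Global model-to-map fit: FSC curve and FSCavg
#'
#' Simulates a theoretical map from the model, applies a soft mask
#' (atoms dilated by \code{mask_radius} with a 3 Angstrom cosine
#' falloff) to both maps, computes the FSC curve and the FSCavg at the
#' stated resolution, plus the masked real-space correlation.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param map experimental \code{\link{density_map}}.
#' @param resolution stated nominal resolution (A); also the FSCavg
#'   cutoff.
#' @param mask_radius atom dilation radius for the soft mask (A).
#' @param n_shells FSC shell count.
#' @return list with \code{curve} (\code{\link{fsc_curve}}) and
#'   \code{global_fit} (fields \code{fsc_avg}, \code{real_space_cc},
#'   \code{resolution_cutoff}, \code{mask}).
#' @export
model_map_fsc <- function(model, map, resolution, mask_radius = 3,
                          n_shells = min(dim(map$data)) %/% 2) {
  sim <- simulate_map(model, map, resolution)
  msk <- soft_mask(model, map, radius = mask_radius)
  m1 <- density_map(map$data * msk, map$voxel_size, map$origin)
  m2 <- density_map(sim$data * msk, map$voxel_size, map$origin)
  curve <- fsc_curve(m1, m2, n_shells)
  favg <- fsc_average(curve, resolution)
  hard <- msk >= 0.5
  cc <- real_space_cc(map, sim, hard)
  list(curve = curve,
       global_fit = list(fsc_avg = favg, real_space_cc = cc,
                         resolution_cutoff = resolution,
                         mask = sprintf("atoms + %.1f A, cosine falloff 3.0 A",
                                        mask_radius)))
}

#' Masked real-space correlation of two maps
#'
#' Pearson correlation of voxel values inside a boolean mask.
#'
#' @param map,model_map \code{\link{density_map}}s, same grid.
#' @param mask boolean array matching the grid; must be nonempty.
#' @return correlation coefficient in [-1, 1].
#' @export
real_space_cc <- function(map, model_map, mask) {
  if (!same_grid(map, model_map)) stop("maps must share an identical grid")
  if (!any(mask)) stop("mask is empty")
  v1 <- map$data[mask]
  v2 <- model_map$data[mask]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("constant values inside mask: correlation undefined")
  stats::cor(v1, v2)
}

# per-atom voxel neighbourhoods: linear indices within `radius` A
atom_voxel_indices <- function(atoms, template, radius) {
  d3 <- dim(template$data)
  voxel <- template$voxel_size
  ax <- grid_axes(template)
  lapply(seq_len(nrow(atoms)), function(i) {
    pos <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    rng <- lapply(1:3, function(k) {
      lo <- max(1L, floor((pos[k] - radius - template$origin[k]) / voxel[k]) + 1)
      hi <- min(d3[k], ceiling((pos[k] + radius - template$origin[k]) / voxel[k]) + 1)
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(rng) == 0)) return(integer(0))
    dx2 <- (ax[[1]][rng[[1]]] - pos[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - pos[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - pos[3])^2
    within <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
    ii <- which(within, arr.ind = TRUE)
    if (!nrow(ii)) return(integer(0))
    (rng[[1]][ii[, 1]]) +
      d3[1] * (rng[[2]][ii[, 2]] - 1L) +
      d3[1] * d3[2] * (rng[[3]][ii[, 3]] - 1L)
  })
}

#' Per-residue SMOC local fit scores
#'
#' Segment-based Manders' overlap coefficient: for each residue i, the
#' voxels within \code{radius} Angstrom of the heavy atoms of residues
#' [i - w, i + w] along the chain (window truncated at termini) are
#' collected, and SMOC = sum(E M) / sqrt(sum E^2 sum M^2) between the
#' experimental (E) and simulated model (M) values over those voxels.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param map experimental \code{\link{density_map}}.
#' @param resolution nominal resolution (A) for the simulated map.
#' @param half_window residues either side of i (default 2: a 5-residue
#'   window).
#' @param radius contour distance from window atoms (A, default 2.5).
#' @param sim optional precomputed simulated map (same grid).
#' @return a \code{residue_score_table} data.frame with columns
#'   \code{chain}, \code{resno}, \code{ins}, \code{resname}, \code{smoc}
#'   (in [-1, 1]; NA for residues with no heavy atoms).
#' @export
smoc <- function(model, map, resolution, half_window = 2, radius = 2.5,
                 sim = NULL) {
  res <- model_residues(model)
  if (nrow(res) == 0) stop("no polymer residues present")
  if (is.null(sim)) sim <- simulate_map(model, map, resolution)
  a <- select_conformer(model)$atoms
  a <- a[!a$het & !a$hydrogen, , drop = FALSE]
  rkey <- paste(a$chain, a$resno, a$ins, sep = "\r")
  key <- paste(res$chain, res$resno, res$ins, sep = "\r")
  vox <- atom_voxel_indices(a, map, radius)
  res_vox <- lapply(key, function(k) {
    w <- which(rkey == k)
    if (!length(w)) integer(0) else unique(unlist(vox[w], use.names = FALSE))
  })
  e <- as.vector(map$data)
  m <- as.vector(sim$data)
  scores <- rep(NA_real_, nrow(res))
  for (i in seq_len(nrow(res))) {
    same <- which(res$chain == res$chain[i])
    win <- same[res$resno[same] >= res$resno[i] - half_window &
                res$resno[same] <= res$resno[i] + half_window]
    vv <- unique(unlist(res_vox[win], use.names = FALSE))
    if (!length(res_vox[[i]]) || !length(vv)) next   # no heavy atoms -> NA
    ev <- e[vv]; mv <- m[vv]
    den <- sqrt(sum(ev^2) * sum(mv^2))
    if (den > 0) scores[i] <- sum(ev * mv) / den
  }
  out <- cbind(res, smoc = scores)
  class(out) <- c("residue_score_table", "data.frame")
  out
}
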