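# Packaged reference probability grids for backbone/side-chain
# classification. The grids are coarse, smoothed, analytic mixtures of
# wrapped 2-D Gaussians placed on the well-established basins of
# high-resolution structure statistics (alpha, beta, polyproline-II,
# left-handed alpha for phi/psi; gauche/trans wells for chi; helix and
# sheet basins for the CA-trace virtual dihedrals). They make the
# package self-contained; absolute percentages can differ from
# MolProbity's empirically contoured tables by small margins.
#
# Classification thresholds (declared constants): favored = inside the
# 98% highest-density region, outlier = outside the 99.95% region for
# phi/psi; rotamer outlier = outside the 99.7% region; CA-trace outlier
# = outside the 99% region.

.grid_cache <- new.env(parent = emptyenv())

RAMA_FAVORED_MASS <- 0.98
RAMA_ALLOWED_MASS <- 0.9995
ROTAMER_OUTLIER_MASS <- 0.997
CABLAM_OUTLIER_MASS <- 0.99

# wrapped 1-D Gaussian kernel evaluated on angle grid (degrees)
wrapped_gauss <- function(theta, mu, sigma) {
  out <- 0
  for (k in -1:1) out <- out + exp(-0.5 * ((theta - mu + 360 * k) / sigma)^2)
  out
}

# mixture density on an n x n grid over [-180, 180)^2;
# modes: matrix cols mu1, sigma1, mu2, sigma2, weight
angle_grid_2d <- function(modes, n = 180) {
  centres <- -180 + (seq_len(n) - 0.5) * (360 / n)
  dens <- matrix(0, n, n)
  for (r in seq_len(nrow(modes))) {
    g1 <- wrapped_gauss(centres, modes[r, 1], modes[r, 2])
    g2 <- wrapped_gauss(centres, modes[r, 3], modes[r, 4])
    dens <- dens + modes[r, 5] * outer(g1, g2)
  }
  dens / sum(dens)
}

angle_grid_1d <- function(modes, n = 180) {
  centres <- -180 + (seq_len(n) - 0.5) * (360 / n)
  dens <- 0
  for (r in seq_len(nrow(modes)))
    dens <- dens + modes[r, 3] * wrapped_gauss(centres, modes[r, 1], modes[r, 2])
  dens / sum(dens)
}

# density level such that cells with density >= level hold `mass` of the
# probability
density_level <- function(dens, mass) {
  v <- sort(as.numeric(dens), decreasing = TRUE)
  cs <- cumsum(v)
  i <- which(cs >= mass * cs[length(cs)])[1]
  v[i]
}

grid_lookup_2d <- function(grid, a1, a2) {
  n <- nrow(grid)
  i <- pmin(n, pmax(1, floor((a1 + 180) / (360 / n)) + 1))
  j <- pmin(n, pmax(1, floor((a2 + 180) / (360 / n)) + 1))
  grid[cbind(i, j)]
}

grid_lookup_1d <- function(grid, a1) {
  n <- length(grid)
  i <- pmin(n, pmax(1, floor((a1 + 180) / (360 / n)) + 1))
  grid[i]
}

# ---- Ramachandran reference --------------------------------------------

rama_modes <- function(type) {
  # cols: mu_phi, sigma_phi, mu_psi, sigma_psi, weight
  switch(type,
    general = rbind(
      c(-63, 14, -43, 13, 0.42),          # alpha
      c(-118, 25, 132, 22, 0.28),         # beta
      c(-68, 15, 147, 16, 0.22),          # polyproline II
      c(57, 12, 42, 12, 0.08)),           # left-handed alpha
    gly = rbind(
      c(-70, 18, -35, 18, 0.22), c(70, 18, 35, 18, 0.22),
      c(-95, 25, 150, 25, 0.18), c(95, 25, -150, 25, 0.18),
      c(-170, 25, 175, 25, 0.10), c(170, 25, -175, 25, 0.10)),
    pro = rbind(
      c(-62, 11, -35, 13, 0.45), c(-62, 11, 148, 14, 0.45),
      c(-62, 11, 70, 18, 0.10)),
    prepro = rbind(
      c(-63, 14, -43, 14, 0.30), c(-120, 25, 130, 22, 0.40),
      c(-68, 15, 147, 16, 0.25), c(57, 12, 42, 12, 0.05)))
}

rama_grid <- function(type) {
  key <- paste0("rama_", type)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  dens <- angle_grid_2d(rama_modes(type))
  g <- list(dens = dens,
            favored_level = density_level(dens, RAMA_FAVORED_MASS),
            allowed_level = density_level(dens, RAMA_ALLOWED_MASS))
  # reference moments of log density under the favored-region
  # conditional distribution, for the Z-score
  fav <- dens >= g$favored_level
  w <- dens[fav] / sum(dens[fav])
  lp <- log(dens[fav])
  g$logp_mean <- sum(w * lp)
  g$logp_sd <- sqrt(sum(w * (lp - g$logp_mean)^2))
  .grid_cache[[key]] <- g
  g
}

rama_type <- function(resname, next_resname) {
  ifelse(resname == "GLY", "gly",
         ifelse(resname == "PRO", "pro",
                ifelse(!is.na(next_resname) & next_resname == "PRO",
                       "prepro", "general")))
}

# ---- Rotamer reference --------------------------------------------------

rotamer_grid <- function(resname) {
  key <- paste0("rota_", resname)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  modes <- ROTAMER_MODES[[resname]]
  if (is.null(modes)) return(NULL)
  has_chi2 <- !is.na(modes[1, 2])
  s1 <- 14
  s2 <- if (resname %in% CHI2_SP2) 35 else 16
  if (has_chi2) {
    m <- cbind(modes[, 1], s1, modes[, 2], s2, modes[, 3])
    dens <- angle_grid_2d(m)
  } else {
    m <- cbind(modes[, 1], s1, modes[, 3])
    dens <- angle_grid_1d(m)
  }
  g <- list(dens = dens, has_chi2 = has_chi2,
            outlier_level = density_level(dens, ROTAMER_OUTLIER_MASS))
  .grid_cache[[key]] <- g
  g
}

# ---- CA-trace (CaBLAM-style) reference ---------------------------------

cablam_grid <- function() {
  key <- "cablam"
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  # (mu_in, mu_out) basins: alpha helix ~ (50, 50); beta/extended near
  # +/-180; a broad loop basin
  modes <- rbind(
    c(50, 16, 50, 16, 0.45),
    c(-178, 28, -178, 28, 0.30),
    c(-80, 32, 60, 32, 0.15),
    c(80, 32, -60, 32, 0.10))
  dens <- angle_grid_2d(modes)
  g <- list(dens = dens,
            outlier_level = density_level(dens, CABLAM_OUTLIER_MASS))
  .grid_cache[[key]] <- g
  g
}
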