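# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, full matrices) and never share code
# paths with the package implementation they check.

# all atom pairs within cutoff, O(n^2)
brute_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff)
      out <- rbind(out, c(i, j))
  }
  out
}

# naive Benjamini-Yekutieli step-up adjusted q-values
naive_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q <- p[o] * m * cm / seq_len(m)
  # enforce monotonicity from the largest down
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# naive BH for the switchable method
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# connected components by repeated sweeps over the full distance matrix
naive_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  adj <- as.matrix(dist(xyz)) <= cutoff
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  comp
}

# torsion angle via an independent construction (projection onto the
# plane perpendicular to the central bond)
brute_torsion <- function(p1, p2, p3, p4) {
  b <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * b) * b
  v2 <- (p4 - p3) - sum((p4 - p3) * b) * b
  x <- sum(v1 * v2)
  y <- sum(c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1]) * b)
  -atan2(y, x) * 180 / pi
}

# Manders coefficient of one residue by a naive full-grid voxel loop
naive_manders <- function(map, sim, atoms_xyz, radius) {
  d3 <- dim(map$data)
  se <- 0; sm <- 0; sem <- 0
  for (i in seq_len(d3[1])) for (j in seq_len(d3[2])) for (k in seq_len(d3[3])) {
    pos <- map$origin + (c(i, j, k) - 1) * map$voxel_size
    dmin <- min(sqrt(colSums((t(atoms_xyz) - pos)^2)))
    if (dmin <= radius) {
      e <- map$data[i, j, k]; m <- sim$data[i, j, k]
      sem <- sem + e * m; se <- se + e^2; sm <- sm + m^2
    }
  }
  sem / sqrt(se * sm)
}

# random "protein-like" atom cloud for clash oracle tests
random_model <- function(n_atoms, seed, box = 20) {
  set.seed(seed)
  elems <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                  prob = c(0.6, 0.2, 0.15, 0.05))
  atomic_model(data.frame(
    chain = sample(c("A", "B"), n_atoms, TRUE),
    resno = sample(1:40, n_atoms, TRUE), ins = "",
    resname = "ALA", atom = paste0("X", seq_len(n_atoms)), element = elems,
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box), b = 30, occ = 1, altloc = "",
    het = FALSE, hydrogen = FALSE, stringsAsFactors = FALSE))
}

# brute-force clash finder: O(n^2) pairs, igraph::distances for the
# bonded-path exclusion (a different igraph route than ego())
brute_clashes <- function(model, threshold = 0.4) {
  a <- emval:::select_conformer(model)$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- emval:::vdw_radius(a$element)
  g <- emval:::bond_graph(a)
  gd <- igraph::distances(g)
  polar_h <- rep(FALSE, nrow(a))
  if (any(a$hydrogen)) for (i in which(a$hydrogen)) {
    nb <- which(gd[i, ] == 1)
    polar_h[i] <- any(a$element[nb] %in% c("N", "O", "S"))
  }
  acceptor <- a$element %in% c("N", "O", "S")
  n <- nrow(a)
  hits <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ov <- r[i] + r[j] - d
    if ((polar_h[i] && acceptor[j]) || (polar_h[j] && acceptor[i]))
      ov <- ov - 0.8
    if (ov >= threshold && gd[i, j] > 3)
      hits[[length(hits) + 1]] <- c(i, j, ov)
  }
  if (!length(hits)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, hits)
}

# shell-mean amplitudes by direct complex sums (independent of
# shell_index/tapply machinery)
brute_shell_means <- function(map, n_shells) {
  f <- fft(map$data)
  d3 <- dim(map$data)
  fx <- emval:::fft_freq(d3[1]) / map$voxel_size[1]
  fy <- emval:::fft_freq(d3[2]) / map$voxel_size[2]
  fz <- emval:::fft_freq(d3[3]) / map$voxel_size[3]
  s_max <- min(1 / (2 * map$voxel_size))
  ds <- s_max / n_shells
  sums <- numeric(n_shells); cnts <- integer(n_shells)
  for (i in seq_len(d3[1])) for (j in seq_len(d3[2])) for (k in seq_len(d3[3])) {
    s <- sqrt(fx[i]^2 + fy[j]^2 + fz[k]^2)
    b <- floor(s / ds) + 1
    if (b <= n_shells && s <= s_max) {
      sums[b] <- sums[b] + Mod(f[i, j, k]); cnts[b] <- cnts[b] + 1L
    }
  }
  list(mean = sums / cnts, n = cnts)
}
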