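# candidate atom pairs (i < j) within cutoff, via spatial hashing
# (cell lists); equivalent to the brute-force double loop by
# construction, which the test suite asserts
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  lo <- apply(xyz, 2, min)
  cell <- floor((xyz - matrix(lo, n, 3, byrow = TRUE)) / cutoff)
  key <- cell[, 1] + 100000 * cell[, 2] + 1e10 * cell[, 3]
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0)
  for (b in buckets) {
    c0 <- cell[b[1], ]
    cand <- integer(0)
    for (r in seq_len(nrow(offs))) {
      k <- (c0[1] + offs[r, 1]) + 100000 * (c0[2] + offs[r, 2]) +
        1e10 * (c0[3] + offs[r, 3])
      hit <- buckets[[as.character(k)]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    for (i in b) {
      j <- cand[cand > i]
      if (!length(j)) next
      d2 <- (xyz[j, 1] - xyz[i, 1])^2 + (xyz[j, 2] - xyz[i, 2])^2 +
        (xyz[j, 3] - xyz[i, 3])^2
      j <- j[d2 <= cutoff^2]
      if (length(j)) { out_i <- c(out_i, rep(i, length(j))); out_j <- c(out_j, j) }
    }
  }
  cbind(out_i, out_j)
}

# distance-based covalent bond graph over all atoms
bond_graph <- function(atoms) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  pairs <- neighbor_pairs(xyz, 2.6)
  if (nrow(pairs) == 0) return(g)
  r <- cov_radius(atoms$element)
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                     xyz[pairs[, 2], , drop = FALSE])^2))
  bonded <- d > 0.3 & d <= r[pairs[, 1]] + r[pairs[, 2]] + 0.45
  bp <- pairs[bonded, , drop = FALSE]
  if (nrow(bp)) g <- igraph::add_edges(g, as.vector(t(bp)))
  g
}

atom_label <- function(atoms, i) {
  sprintf("%s/%d%s/%s", atoms$chain[i], atoms$resno[i], atoms$ins[i],
          atoms$atom[i])
}

#' Find steric clashes and compute the clashscore
#'
#' All non-bonded atom pairs (excluding 1-2, 1-3 and 1-4 bonded paths)
#' whose van der Waals overlap (r1 + r2 - distance) is at least
#' \code{threshold}. Hydrogen-bond pairs (a polar hydrogen, i.e. one
#' riding on N/O/S, against an N/O/S acceptor) receive a 0.8 Angstrom
#' overlap allowance, so that ordinary secondary-structure hydrogen
#' bonds are not reported as clashes. Clashscore =
#' 1000 x n_clashes / n_atoms, hydrogens included when present.
#'
#' @param model an \code{\link{atomic_model}} (ideally after
#'   \code{\link{add_hydrogens}}).
#' @param threshold overlap threshold in Angstrom (default 0.4).
#' @return list with \code{clashes} (data.frame: atom labels, overlap,
#'   midpoint coordinates, residue keys) and \code{clashscore}.
#' @export
find_clashes <- function(model, threshold = 0.4) {
  a <- select_conformer(model)$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- vdw_radius(a$element)
  g <- bond_graph(a)
  near <- igraph::ego(g, order = 3, nodes = seq_len(nrow(a)))
  # polar hydrogens: H whose bonded parent is N/O/S
  polar_h <- rep(FALSE, nrow(a))
  if (any(a$hydrogen)) {
    nb1 <- igraph::ego(g, order = 1, nodes = which(a$hydrogen))
    polar_h[which(a$hydrogen)] <- vapply(nb1, function(v)
      any(a$element[setdiff(as.integer(v), 0)] %in% c("N", "O", "S")), TRUE)
  }
  acceptor <- a$element %in% c("N", "O", "S")
  pairs <- neighbor_pairs(xyz, 2 * max(r) - threshold)
  rec <- list()
  if (nrow(pairs)) {
    d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
    ov <- r[pairs[, 1]] + r[pairs[, 2]] - d
    hbond <- (polar_h[pairs[, 1]] & acceptor[pairs[, 2]]) |
      (polar_h[pairs[, 2]] & acceptor[pairs[, 1]])
    ov[hbond] <- ov[hbond] - 0.8
    keep <- ov >= threshold
    for (k in which(keep)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (j %in% as.integer(near[[i]])) next          # 1-2/1-3/1-4 related
      rec[[length(rec) + 1]] <- data.frame(
        atom1 = atom_label(a, i), atom2 = atom_label(a, j),
        chain1 = a$chain[i], resno1 = a$resno[i], ins1 = a$ins[i],
        chain2 = a$chain[j], resno2 = a$resno[j], ins2 = a$ins[j],
        overlap = ov[k],
        mx = (xyz[i, 1] + xyz[j, 1]) / 2, my = (xyz[i, 2] + xyz[j, 2]) / 2,
        mz = (xyz[i, 3] + xyz[j, 3]) / 2, stringsAsFactors = FALSE)
    }
  }
  clashes <- if (length(rec)) do.call(rbind, rec) else
    data.frame(atom1 = character(), atom2 = character(), chain1 = character(),
               resno1 = integer(), ins1 = character(), chain2 = character(),
               resno2 = integer(), ins2 = character(), overlap = numeric(),
               mx = numeric(), my = numeric(), mz = numeric())
  list(clashes = clashes, clashscore = 1000 * nrow(clashes) / nrow(a))
}

# coordinates of a named atom in a residue-atom data.frame, or NULL
get_xyz <- function(ra, name) {
  i <- which(ra$atom == name)[1]
  if (is.na(i)) NULL else c(ra$x[i], ra$y[i], ra$z[i])
}

# per-chain residue list with backbone coordinates; peptide-bonded
# connectivity decided by C(i)-N(i+1) distance <= 2.0 A
backbone_frames <- function(model) {
  res <- model_residues(model)
  a <- select_conformer(model)$atoms
  a <- a[!a$het, , drop = FALSE]
  frames <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    ra <- a[a$chain == res$chain[i] & a$resno == res$resno[i] &
            a$ins == res$ins[i], , drop = FALSE]
    frames[[i]] <- list(N = get_xyz(ra, "N"), CA = get_xyz(ra, "CA"),
                        C = get_xyz(ra, "C"), O = get_xyz(ra, "O"))
  }
  linked_next <- logical(nrow(res))
  for (i in seq_len(nrow(res) - 1)) {
    same <- res$chain[i] == res$chain[i + 1]
    ci <- frames[[i]]$C; ni <- frames[[i + 1]]$N
    linked_next[i] <- same && !is.null(ci) && !is.null(ni) &&
      vnorm(ci - ni) <= 2.0
  }
  list(res = res, frames = frames, linked_next = linked_next)
}

#' Ramachandran classification and Z-score
#'
#' phi/psi dihedrals are computed for residues with peptide-bonded
#' neighbours on both sides and classified (favored / allowed / outlier)
#' against packaged smoothed reference grids (general / Gly / Pro /
#' pre-Pro; 2 degree bins). The Z-score compares per-residue
#' log-probabilities with reference moments derived from the grids
#' themselves under the favored-region distribution:
#' z = mean_i((logp_i - mu_type)/sd_type) x sqrt(n).
#'
#' @param model an \code{\link{atomic_model}}.
#' @return list with \code{table} (chain, resno, ins, resname, phi, psi,
#'   rama_class), \code{rama_favored_pct}, \code{rama_outlier_pct},
#'   \code{rama_z}.
#' @export
ramachandran <- function(model) {
  bf <- backbone_frames(model)
  res <- bf$res
  n <- nrow(res)
  if (n < 3) {
    warning("chain(s) too short for phi/psi (need >= 3 consecutive residues)")
    return(list(table = data.frame(), rama_favored_pct = NA_real_,
                rama_outlier_pct = NA_real_, rama_z = NA_real_))
  }
  rows <- list()
  zs <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(bf$linked_next[i - 1] && bf$linked_next[i])) next
    p <- bf$frames[[i - 1]]; q <- bf$frames[[i]]; r <- bf$frames[[i + 1]]
    if (is.null(p$C) || is.null(q$N) || is.null(q$CA) || is.null(q$C) ||
        is.null(r$N)) next
    phi <- torsion_angle(p$C, q$N, q$CA, q$C)
    psi <- torsion_angle(q$N, q$CA, q$C, r$N)
    type <- rama_type(res$resname[i], res$resname[i + 1])
    g <- rama_grid(type)
    dens <- grid_lookup_2d(g$dens, phi, psi)
    cls <- if (dens >= g$favored_level) "favored"
           else if (dens >= g$allowed_level) "allowed" else "outlier"
    zs <- c(zs, (log(pmax(dens, 1e-300)) - g$logp_mean) / g$logp_sd)
    rows[[length(rows) + 1]] <- data.frame(
      chain = res$chain[i], resno = res$resno[i], ins = res$ins[i],
      resname = res$resname[i], phi = phi, psi = psi, rama_class = cls,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!nrow(tab)) {
    warning("no residues with computable phi/psi")
    return(list(table = tab, rama_favored_pct = NA_real_,
                rama_outlier_pct = NA_real_, rama_z = NA_real_))
  }
  list(table = tab,
       rama_favored_pct = 100 * mean(tab$rama_class == "favored"),
       rama_outlier_pct = 100 * mean(tab$rama_class == "outlier"),
       rama_z = mean(zs) * sqrt(length(zs)))
}

#' Rotamer outlier detection
#'
#' chi1 (and chi2 where defined) angles are scored against packaged
#' coarse per-residue-type probability grids; a residue is flagged when
#' its chi vector falls outside the 99.7% highest-density region.
#' Ala/Gly and residues with missing side-chain atoms are unscorable and
#' excluded from the denominator.
#'
#' @param model an \code{\link{atomic_model}}.
#' @return list with \code{table} (chain, resno, ins, resname, chi1,
#'   chi2, rotamer_outlier), \code{rotamer_outlier_pct},
#'   \code{n_unscorable}.
#' @export
rotamer_outliers <- function(model) {
  res <- model_residues(model)
  a <- select_conformer(model)$atoms
  a <- a[!a$het & !a$hydrogen, , drop = FALSE]
  rows <- list()
  unscorable <- 0L
  for (i in seq_len(nrow(res))) {
    rn <- res$resname[i]
    quad <- CHI1_ATOMS[[rn]]
    if (is.null(quad)) { unscorable <- unscorable + 1L; next }
    ra <- a[a$chain == res$chain[i] & a$resno == res$resno[i] &
            a$ins == res$ins[i], , drop = FALSE]
    pts <- lapply(quad, get_xyz, ra = ra)
    if (any(vapply(pts, is.null, TRUE))) { unscorable <- unscorable + 1L; next }
    chi1 <- torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    g <- rotamer_grid(rn)
    chi2 <- NA_real_
    if (g$has_chi2) {
      quad2 <- CHI2_ATOMS[[rn]]
      pts2 <- lapply(quad2, get_xyz, ra = ra)
      if (any(vapply(pts2, is.null, TRUE))) { unscorable <- unscorable + 1L; next }
      chi2 <- torsion_angle(pts2[[1]], pts2[[2]], pts2[[3]], pts2[[4]])
      dens <- grid_lookup_2d(g$dens, chi1, chi2)
    } else {
      dens <- grid_lookup_1d(g$dens, chi1)
    }
    rows[[length(rows) + 1]] <- data.frame(
      chain = res$chain[i], resno = res$resno[i], ins = res$ins[i],
      resname = rn, chi1 = chi1, chi2 = chi2,
      rotamer_outlier = dens < g$outlier_level, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), ins = character(),
               resname = character(), chi1 = numeric(), chi2 = numeric(),
               rotamer_outlier = logical())
  pct <- if (nrow(tab)) 100 * mean(tab$rotamer_outlier) else 0
  list(table = tab, rotamer_outlier_pct = pct, n_unscorable = unscorable)
}

#' CA-trace backbone geometry flags (CaBLAM-style)
#'
#' Per residue i, the CA virtual dihedrals mu_in (CA i-2..i+1) and
#' mu_out (CA i-1..i+2) and the CA virtual angle are computed; the
#' residue is flagged when (mu_in, mu_out) falls outside the packaged
#' 99% highest-density region. Chain breaks (CA-CA > 4.5 A) split the
#' trace; flanking residues are unscorable.
#'
#' @param model an \code{\link{atomic_model}}.
#' @return list with \code{table} (chain, resno, ins, resname, mu_in,
#'   mu_out, nu, cablam_outlier) and \code{cablam_outlier_pct}.
#' @export
cablam_flags <- function(model) {
  bf <- backbone_frames(model)
  res <- bf$res
  ca <- lapply(bf$frames, `[[`, "CA")
  n <- nrow(res)
  # split chains into segments of consecutive CA with CA-CA <= 4.5
  seg_id <- integer(n); cur <- 1L
  for (i in seq_len(n)) {
    if (i > 1) {
      brk <- res$chain[i] != res$chain[i - 1] || is.null(ca[[i]]) ||
        is.null(ca[[i - 1]]) || vnorm(ca[[i]] - ca[[i - 1]]) > 4.5
      if (brk) cur <- cur + 1L
    }
    seg_id[i] <- cur
  }
  g <- cablam_grid()
  rows <- list()
  for (i in seq_len(n)) {
    idx <- (i - 2):(i + 2)
    if (any(idx < 1 | idx > n)) next
    if (length(unique(seg_id[idx])) != 1) next
    if (any(vapply(ca[idx], is.null, TRUE))) next
    mu_in <- torsion_angle(ca[[i - 2]], ca[[i - 1]], ca[[i]], ca[[i + 1]])
    mu_out <- torsion_angle(ca[[i - 1]], ca[[i]], ca[[i + 1]], ca[[i + 2]])
    nu <- bond_angle(ca[[i - 1]], ca[[i]], ca[[i + 1]])
    dens <- grid_lookup_2d(g$dens, mu_in, mu_out)
    rows[[length(rows) + 1]] <- data.frame(
      chain = res$chain[i], resno = res$resno[i], ins = res$ins[i],
      resname = res$resname[i], mu_in = mu_in, mu_out = mu_out, nu = nu,
      cablam_outlier = dens < g$outlier_level, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), ins = character(),
               resname = character(), mu_in = numeric(), mu_out = numeric(),
               nu = numeric(), cablam_outlier = logical())
  pct <- if (nrow(tab)) 100 * mean(tab$cablam_outlier) else 0
  list(table = tab, cablam_outlier_pct = pct)
}

#' MolProbity-style composite score
#'
#' score = 0.426 ln(1 + clashscore)
#'       + 0.33 ln(1 + max(0, rotamer_outlier_pct - 1))
#'       + 0.25 ln(1 + max(0, (100 - rama_favored_pct) - 2)) + 0.5,
#' the published composite calibrated to crystallographic resolution.
#'
#' @param clashscore clashes per 1000 atoms.
#' @param rotamer_outlier_pct rotamer outlier percentage.
#' @param rama_favored_pct Ramachandran favored percentage.
#' @return composite score (>= 0.5).
#' @export
molprobity_score <- function(clashscore, rotamer_outlier_pct,
                             rama_favored_pct) {
  stopifnot(is.finite(clashscore), clashscore >= 0,
            rotamer_outlier_pct >= 0, rotamer_outlier_pct <= 100,
            rama_favored_pct >= 0, rama_favored_pct <= 100)
  0.426 * log(1 + clashscore) +
    0.33 * log(1 + max(0, rotamer_outlier_pct - 1)) +
    0.25 * log(1 + max(0, (100 - rama_favored_pct) - 2)) + 0.5
}

#' Full stereochemical summary of a model
#'
#' Runs clash detection (after riding-hydrogen placement unless
#' \code{add_h = FALSE}), Ramachandran, rotamer and CA-trace checks and
#' assembles the composite score plus a per-residue outlier table.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param add_h place riding hydrogens before clash detection
#'   (default TRUE); FALSE is recorded in the output.
#' @param clash_threshold vdW overlap threshold (A).
#' @return list with \code{summary} (clashscore, rotamer_outlier_pct,
#'   rama_favored_pct, rama_outlier_pct, rama_z, cablam_outlier_pct,
#'   molprobity_score, h_mode), \code{residue_table} (per-residue
#'   outlier flags), \code{clashes}.
#' @export
geometry_summary <- function(model, add_h = TRUE, clash_threshold = 0.4) {
  mh <- if (add_h) add_hydrogens(model) else model
  cl <- find_clashes(mh, threshold = clash_threshold)
  rama <- ramachandran(model)
  rota <- rotamer_outliers(model)
  cab <- cablam_flags(model)
  res <- model_residues(model)
  key <- function(d) paste(d$chain, d$resno, d$ins, sep = "\r")
  rk <- key(res)
  tab <- res
  tab$rama_class <- NA_character_
  if (nrow(rama$table))
    tab$rama_class[match(key(rama$table), rk)] <- rama$table$rama_class
  tab$rama_outlier <- !is.na(tab$rama_class) & tab$rama_class == "outlier"
  tab$rotamer_outlier <- FALSE
  if (nrow(rota$table))
    tab$rotamer_outlier[match(key(rota$table), rk)] <- rota$table$rotamer_outlier
  tab$cablam_outlier <- FALSE
  if (nrow(cab$table))
    tab$cablam_outlier[match(key(cab$table), rk)] <- cab$table$cablam_outlier
  tab$clash <- FALSE
  if (nrow(cl$clashes)) {
    ck <- unique(c(paste(cl$clashes$chain1, cl$clashes$resno1, cl$clashes$ins1,
                         sep = "\r"),
                   paste(cl$clashes$chain2, cl$clashes$resno2, cl$clashes$ins2,
                         sep = "\r")))
    tab$clash[rk %in% ck] <- TRUE
  }
  fav <- if (is.na(rama$rama_favored_pct)) 100 else rama$rama_favored_pct
  list(summary = list(
         clashscore = cl$clashscore,
         rotamer_outlier_pct = rota$rotamer_outlier_pct,
         rama_favored_pct = rama$rama_favored_pct,
         rama_outlier_pct = rama$rama_outlier_pct,
         rama_z = rama$rama_z,
         cablam_outlier_pct = cab$cablam_outlier_pct,
         molprobity_score = molprobity_score(cl$clashscore,
                                             rota$rotamer_outlier_pct, fav),
         h_mode = if (add_h) "riding hydrogens added" else "no-h (heavy atoms only)"),
       residue_table = tab, clashes = cl$clashes)
}
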