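# tetrahedral half-angle: H-C-H 109.47 deg -> 54.735 from the bisector
TET_HALF <- 54.735

h_name_set <- function(parent, n) {
  base <- substring(parent, 2)
  if (n == 1) paste0("H", base)
  else if (n == 2) paste0("H", base, 2:3)
  else paste0("H", base, 1:3)
}

# place n hydrogens on `parent` given unit vectors to its known heavy
# neighbours; returns 3-column matrix of positions (possibly 0 rows)
place_h_on <- function(parent_pos, nbr_pos, n, type, blen, ref_pos = NULL) {
  k <- length(nbr_pos)
  us <- lapply(nbr_pos, function(p) unitv(p - parent_pos))
  if (k == 3 && n == 1) {                      # sp3 CH
    d <- -unitv(us[[1]] + us[[2]] + us[[3]])
    return(matrix(parent_pos + blen * d, 1))
  }
  if (k == 2 && n == 2) {                      # sp3 CH2 / Gly CA
    b <- -unitv(us[[1]] + us[[2]])
    p <- unitv(cross3(us[[1]], us[[2]]))
    a <- deg2rad(TET_HALF)
    return(rbind(parent_pos + blen * (cos(a) * b + sin(a) * p),
                 parent_pos + blen * (cos(a) * b - sin(a) * p)))
  }
  if (k == 2 && n == 1) {                      # sp2 CH / ring NH
    d <- -unitv(us[[1]] + us[[2]])
    return(matrix(parent_pos + blen * d, 1))
  }
  if (k == 1 && !is.null(ref_pos)) {
    if (type == "methyl" && n >= 2) {          # methyl / NH3 staggered
    tors <- c(180, 60, -60)[seq_len(n)]
      pos <- t(vapply(tors, function(tt)
        place_atom(ref_pos, nbr_pos[[1]], parent_pos, blen, 109.47, tt),
        numeric(3)))
      return(pos)
    }
    if (type == "sp2" && n == 2) {             # amide NH2, in plane
      return(rbind(
        place_atom(ref_pos, nbr_pos[[1]], parent_pos, blen, 120, 0),
        place_atom(ref_pos, nbr_pos[[1]], parent_pos, blen, 120, 180)))
    }
    if (n == 1) {                              # hydroxyl/thiol, anti
      return(matrix(place_atom(ref_pos, nbr_pos[[1]], parent_pos, blen,
                               109.5, 180), 1))
    }
  }
  matrix(numeric(0), 0, 3)
}

#' Place riding hydrogens on standard amino-acid residues
#'
#' Hydrogens are added from ideal internal coordinates (bond length by
#' element, ideal tetrahedral/trigonal directions completed from the
#' known heavy-atom neighbours; methyls staggered). Existing hydrogens
#' are kept and their parents skipped, making the operation idempotent.
#' Non-standard residues are skipped with a warning. N-terminal amides
#' and prolines get no N-H.
#'
#' @param model an \code{\link{atomic_model}}.
#' @return a new \code{\link{atomic_model}} including the hydrogens.
#' @export
add_hydrogens <- function(model) {
  a <- select_conformer(model)$atoms
  heavy <- a[!a$hydrogen, , drop = FALSE]
  hyd <- a[a$hydrogen, , drop = FALSE]
  res <- model_residues(model, polymer_only = FALSE)
  skipped <- 0L
  new_rows <- list()
  hxyz <- as.matrix(hyd[, c("x", "y", "z")])

  has_h_on <- function(pos) {
    if (!nrow(hxyz)) return(FALSE)
    any(rowSums((hxyz - matrix(pos, nrow(hxyz), 3, byrow = TRUE))^2) < 1.3^2)
  }
  res_atoms <- function(ch, no, ic)
    heavy[heavy$chain == ch & heavy$resno == no & heavy$ins == ic, , drop = FALSE]

  for (i in seq_len(nrow(res))) {
    rn <- res$resname[i]
    if (!(rn %in% STANDARD_AA)) { skipped <- skipped + 1L; next }
    ra <- res_atoms(res$chain[i], res$resno[i], res$ins[i])
    if (!nrow(ra)) next
    side <- H_TABLE[[rn]]
    ca <- get_xyz(ra, "CA"); n_at <- get_xyz(ra, "N"); c_at <- get_xyz(ra, "C")
    cb <- get_xyz(ra, "CB")
    # previous residue C for the amide H
    prev_c <- NULL
    if (i > 1 && res$chain[i - 1] == res$chain[i]) {
      pa <- res_atoms(res$chain[i - 1], res$resno[i - 1], res$ins[i - 1])
      pc <- get_xyz(pa, "C")
      if (!is.null(pc) && !is.null(n_at) && vnorm(pc - n_at) <= 2.0) prev_c <- pc
    }
    add <- function(names, pos) {
      for (k in seq_along(names)) {
        new_rows[[length(new_rows) + 1]] <<- data.frame(
          chain = res$chain[i], resno = res$resno[i], ins = res$ins[i],
          resname = rn, atom = names[k], element = "H",
          x = pos[k, 1], y = pos[k, 2], z = pos[k, 3],
          b = ra$b[1], occ = 1, altloc = "", het = FALSE, hydrogen = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    # amide H (not Pro, not N-terminal)
    if (rn != "PRO" && !is.null(prev_c) && !is.null(n_at) && !is.null(ca) &&
        !has_h_on(n_at)) {
      d <- -unitv(unitv(ca - n_at) + unitv(prev_c - n_at))
      add("H", matrix(n_at + H_BOND_LENGTH["N"] * d, 1))
    }
    # alpha hydrogens
    if (!is.null(ca) && !has_h_on(ca) && !is.null(n_at) && !is.null(c_at)) {
      if (rn == "GLY") {
        add(c("HA2", "HA3"),
            place_h_on(ca, list(n_at, c_at), 2, "sp3", H_BOND_LENGTH["C"]))
      } else if (!is.null(cb)) {
        add("HA", place_h_on(ca, list(n_at, c_at, cb), 1, "sp3",
                             H_BOND_LENGTH["C"]))
      }
    }
    # side chain per table
    for (parent in names(side)) {
      spec <- side[[parent]]
      nH <- as.integer(spec[1]); type <- spec[2]
      pp <- get_xyz(ra, parent)
      if (is.null(pp) || has_h_on(pp)) next
      elem <- substr(parent, 1, 1)
      blen <- H_BOND_LENGTH[elem]
      if (is.na(blen)) blen <- 1.09
      # known heavy neighbours of the parent within this residue (plus
      # backbone); distance-based
      cand <- ra[ra$atom != parent, , drop = FALSE]
      dd <- sqrt((cand$x - pp[1])^2 + (cand$y - pp[2])^2 + (cand$z - pp[3])^2)
      nb <- cand[dd <= cov_radius(elem) + cov_radius(cand$element) + 0.45, ,
                 drop = FALSE]
      if (!nrow(nb)) next
      nbr_pos <- lapply(seq_len(nrow(nb)), function(r)
        c(nb$x[r], nb$y[r], nb$z[r]))
      ref_pos <- NULL
      if (nrow(nb) == 1) {
        # reference: a neighbour of the neighbour, for torsion placement
        np <- nbr_pos[[1]]
        cand2 <- ra[!(ra$atom %in% c(parent, nb$atom[1])), , drop = FALSE]
        d2 <- sqrt((cand2$x - np[1])^2 + (cand2$y - np[2])^2 +
                   (cand2$z - np[3])^2)
        j <- which(d2 <= cov_radius(nb$element[1]) +
                     cov_radius(cand2$element) + 0.45)
        if (length(j)) ref_pos <- c(cand2$x[j[1]], cand2$y[j[1]], cand2$z[j[1]])
      }
      pos <- place_h_on(pp, nbr_pos, nH, type, blen, ref_pos)
      if (nrow(pos)) add(h_name_set(parent, nrow(pos)), pos)
    }
  }
  if (skipped > 0)
    warning(skipped, " non-standard residue(s) skipped by add_hydrogens")
  if (!length(new_rows)) return(atomic_model(a))
  atomic_model(rbind(a, do.call(rbind, new_rows)))
}
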