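#' Build an ideal alpha-helix model
#'
#' Poly-Ala (or poly-Gly) helix from ideal internal coordinates:
#' phi = -57, psi = -47, omega = 180 degrees, Engh-Huber-like bond
#' lengths and angles. B = 30 A^2, occupancy 1, chain "A".
#'
#' @param n_res number of residues (>= 5).
#' @param residue_type "ALA" (default) or "GLY".
#' @param b_factor atomic B-factor (A^2).
#' @return an \code{\link{atomic_model}}.
#' @export
make_helix <- function(n_res, residue_type = "ALA", b_factor = 30) {
  stopifnot(n_res >= 5)
  if (!(residue_type %in% c("ALA", "GLY")))
    stop("unsupported residue type: ", residue_type,
         " (the generator builds ALA or GLY)")
  g <- IDEAL_BB
  phi <- -57; psi <- -47; omega <- 180
  rows <- list()
  # seed residue 1 backbone
  n1 <- c(0, 0, 0)
  ca1 <- n1 + c(g$n_ca, 0, 0)
  c1 <- place_atom(c(-1, 1, 0), n1, ca1, g$ca_c, g$ang_n_ca_c, 60)
  pos <- list(N = n1, CA = ca1, C = c1)
  prev <- NULL
  for (i in seq_len(n_res)) {
    if (i > 1) {
      n_i <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi)
      ca_i <- place_atom(prev$CA, prev$C, n_i, g$n_ca, g$ang_c_n_ca, omega)
      c_i <- place_atom(prev$C, n_i, ca_i, g$ca_c, g$ang_n_ca_c, phi)
      pos <- list(N = n_i, CA = ca_i, C = c_i)
    }
    prev <- pos
    rows[[length(rows) + 1]] <- pos
  }
  atoms <- list()
  addrow <- function(i, name, elem, p) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      chain = "A", resno = i, ins = "", resname = residue_type, atom = name,
      element = elem, x = p[1], y = p[2], z = p[3], b = b_factor, occ = 1,
      altloc = "", het = FALSE, hydrogen = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    p <- rows[[i]]
    addrow(i, "N", "N", p$N)
    addrow(i, "CA", "C", p$CA)
    addrow(i, "C", "C", p$C)
    # carbonyl O: trans to the next N (or to psi continuation at C-term)
    nn <- if (i < n_res) rows[[i + 1]]$N else
      place_atom(p$N, p$CA, p$C, IDEAL_BB$c_n, IDEAL_BB$ang_ca_c_n, psi)
    o <- place_atom(nn, p$CA, p$C, g$c_o, g$ang_ca_c_o, 180)
    addrow(i, "O", "O", o)
    if (residue_type == "ALA") {
      # CB with L-chirality: tetrahedral completion out of the N-CA-C plane
      u1 <- unitv(p$N - p$CA); u2 <- unitv(p$C - p$CA)
      bis <- -unitv(u1 + u2)
      perp <- unitv(cross3(u2, u1))
      a <- deg2rad(TET_HALF)
      cb <- p$CA + g$ca_cb * (cos(a) * bis + sin(a) * perp)
      addrow(i, "CB", "C", cb)
    }
  }
  atomic_model(do.call(rbind, atoms))
}

#' Perturbation specification for synthetic defects
#'
#' @param kind one of \code{segment_shift}, \code{register_shift},
#'   \code{rotamer_scramble}, \code{clash_inject}, \code{delete_segment}.
#' @param from,to residue-number range (inclusive).
#' @param magnitude displacement in Angstrom (shift/clash) or residue
#'   steps (register shift); must be > 0.
#' @param seed random seed, recorded with the spec.
#' @param chain chain id (default "A").
#' @return a \code{perturbation_spec}.
#' @export
perturbation_spec <- function(kind, from, to, magnitude = 1, seed = 1,
                              chain = "A") {
  kind <- match.arg(kind, c("segment_shift", "register_shift",
                            "rotamer_scramble", "clash_inject",
                            "delete_segment"))
  stopifnot(magnitude > 0, from <= to)
  structure(list(kind = kind, from = from, to = to, magnitude = magnitude,
                 seed = as.integer(seed), chain = chain),
            class = "perturbation_spec")
}

# seeded random unit vector
runit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    if (vnorm(v) > 1e-6) return(unitv(v))
  }
}

#' Apply a controlled defect to a model
#'
#' Only the atoms named by the spec change; every other atom is
#' bit-identical. All randomness is seeded from the spec.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param spec a \code{\link{perturbation_spec}}.
#' @return the perturbed \code{\link{atomic_model}}.
#' @export
perturb <- function(model, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  a <- model$atoms
  inrange <- a$chain == spec$chain & a$resno >= spec$from & a$resno <= spec$to
  if (!any(inrange)) stop("perturbation range has no atoms in the model")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  bb_names <- c("N", "CA", "C", "O")
  switch(spec$kind,
    segment_shift = {
      dir <- runit3()
      a$x[inrange] <- a$x[inrange] + spec$magnitude * dir[1]
      a$y[inrange] <- a$y[inrange] + spec$magnitude * dir[2]
      a$z[inrange] <- a$z[inrange] + spec$magnitude * dir[3]
    },
    register_shift = {
      k <- round(spec$magnitude)
      res <- model_residues(model)
      res <- res[res$chain == spec$chain & res$resno >= spec$from &
                   res$resno <= spec$to, , drop = FALSE]
      new_names <- a$resname
      moved <- list()
      keep <- rep(TRUE, nrow(a))
      for (i in seq_len(nrow(res))) {
        donor <- res$resno[i] + k
        di <- which(a$chain == spec$chain & a$resno == donor &
                      !(a$atom %in% bb_names) & !a$het)
        ti <- which(a$chain == spec$chain & a$resno == res$resno[i] & !a$het)
        if (!length(ti)) next
        donor_name <- if (length(di)) a$resname[di[1]] else {
          dr <- which(a$chain == spec$chain & a$resno == donor & !a$het)
          if (length(dr)) a$resname[dr[1]] else NA_character_
        }
        if (!is.na(donor_name)) new_names[ti] <- donor_name
        # drop the residue's own side chain; import the donor's,
        # translated by the CA-CA offset so it rides the new backbone
        own_side <- which(a$chain == spec$chain & a$resno == res$resno[i] &
                            !(a$atom %in% bb_names) & !a$het)
        keep[own_side] <- FALSE
        if (length(di)) {
          ca_t <- which(a$chain == spec$chain & a$resno == res$resno[i] &
                          a$atom == "CA")
          ca_d <- which(a$chain == spec$chain & a$resno == donor &
                          a$atom == "CA")
          if (length(ca_t) && length(ca_d)) {
            off <- c(a$x[ca_t] - a$x[ca_d], a$y[ca_t] - a$y[ca_d],
                     a$z[ca_t] - a$z[ca_d])
            sc <- a[di, , drop = FALSE]
            sc$resno <- res$resno[i]
            sc$resname <- if (!is.na(donor_name)) donor_name else sc$resname
            sc$x <- sc$x + off[1]; sc$y <- sc$y + off[2]; sc$z <- sc$z + off[3]
            moved[[length(moved) + 1]] <- sc
          }
        }
      }
      a$resname <- new_names
      a <- a[keep, , drop = FALSE]
      if (length(moved)) a <- rbind(a, do.call(rbind, moved))
      a <- a[order(a$chain, a$resno, a$ins), , drop = FALSE]
    },
    rotamer_scramble = {
      res <- model_residues(model)
      res <- res[res$chain == spec$chain & res$resno >= spec$from &
                   res$resno <= spec$to, , drop = FALSE]
      for (i in seq_len(nrow(res))) {
        sel <- a$chain == spec$chain & a$resno == res$resno[i]
        ca <- which(sel & a$atom == "CA"); cb <- which(sel & a$atom == "CB")
        rot <- which(sel & !(a$atom %in% c(bb_names, "CB")) & !a$hydrogen)
        if (!length(ca) || !length(cb) || !length(rot)) next
        axis <- unitv(c(a$x[cb] - a$x[ca], a$y[cb] - a$y[ca], a$z[cb] - a$z[ca]))
        ang <- stats::runif(1, 30, 330)   # guaranteed change of chi1
        th <- deg2rad(ang)
        K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                      axis[2], -axis[1], 0), 3, 3)
        R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
        origin <- c(a$x[cb], a$y[cb], a$z[cb])
        for (j in rot) {
          v <- c(a$x[j], a$y[j], a$z[j]) - origin
          w <- origin + as.vector(R %*% v)
          a$x[j] <- w[1]; a$y[j] <- w[2]; a$z[j] <- w[3]
        }
      }
    },
    clash_inject = {
      # pull the side chain (or CB) of the first range residue toward a
      # sequence-distant atom until the vdW overlap equals `magnitude`
      sel <- which(a$chain == spec$chain & a$resno == spec$from)
      mover <- sel[!(a$atom[sel] %in% bb_names)]
      if (!length(mover)) mover <- sel[a$atom[sel] == "CA"]
      far <- which(!(a$chain == spec$chain &
                       abs(a$resno - spec$from) <= 2) & !a$hydrogen)
      if (!length(far)) stop("no sequence-distant target atom for clash_inject")
      m1 <- mover[1]
      d <- sqrt((a$x[far] - a$x[m1])^2 + (a$y[far] - a$y[m1])^2 +
                  (a$z[far] - a$z[m1])^2)
      t <- far[which.min(d)]
      dir <- unitv(c(a$x[t] - a$x[m1], a$y[t] - a$y[m1], a$z[t] - a$z[m1]))
      target_d <- vdw_radius(a$element[m1]) + vdw_radius(a$element[t]) -
        spec$magnitude
      shift <- (min(d) - target_d) * dir
      a$x[mover] <- a$x[mover] + shift[1]
      a$y[mover] <- a$y[mover] + shift[2]
      a$z[mover] <- a$z[mover] + shift[3]
    },
    delete_segment = {
      a <- a[!inrange, , drop = FALSE]
    })
  atomic_model(a)
}

#' Simulated map / model test pair
#'
#' Builds a grid covering the model extent plus \code{box_pad}
#' Angstrom at voxel = resolution/3, simulates the model's map and adds
#' white Gaussian noise with sd = \code{noise_sigma} x RMS of the
#' signal inside the model region (3 A mask).
#'
#' @param model an \code{\link{atomic_model}}.
#' @param resolution nominal resolution (A).
#' @param noise_sigma noise sd as a fraction of the model-region signal
#'   RMS (0 = noiseless).
#' @param box_pad padding around the model extent (A, default 8).
#' @param seed random seed for the noise.
#' @param min_dim minimum grid dimension (voxels) per axis.
#' @return list with \code{map} (\code{\link{density_map}}),
#'   \code{model} (untouched), \code{signal_rms}, \code{noise_sd}.
#' @export
make_test_pair <- function(model, resolution, noise_sigma = 0, box_pad = 8,
                           seed = 1, min_dim = 8) {
  a <- model$atoms
  voxel <- rep(resolution / 3, 3)
  lo <- c(min(a$x), min(a$y), min(a$z)) - box_pad
  hi <- c(max(a$x), max(a$y), max(a$z)) + box_pad
  dims <- pmax(as.integer(ceiling((hi - lo) / voxel)) + 1L, as.integer(min_dim))
  template <- density_map(array(0, dim = dims), voxel, lo)
  sim <- simulate_map(model, template, resolution)
  msk <- model_mask(model, template, radius = 3)
  rms <- sqrt(mean(sim$data[msk]^2))
  noise_sd <- noise_sigma * rms
  data <- sim$data
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    data <- data + array(stats::rnorm(prod(dims), sd = noise_sd), dim = dims)
  }
  list(map = density_map(data, voxel, lo), model = model,
       signal_rms = rms, noise_sd = noise_sd)
}
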