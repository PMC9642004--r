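#' Estimate background noise statistics of a map
#'
#' \code{corners}: mean and sd of the voxel values in eight corner cubes
#' of edge length dim/8 (requires a grid of at least 32^3).
#' \code{mask}: statistics over a user-supplied solvent mask of at least
#' 1000 voxels. Skewness and excess kurtosis of the background sample
#' are returned as a normality diagnostic.
#'
#' @param map a \code{\link{density_map}}.
#' @param method \code{"corners"} or \code{"mask"}.
#' @param mask boolean array (for \code{method = "mask"}).
#' @return list with \code{mean}, \code{sd}, \code{skew}, \code{kurt},
#'   \code{n}, \code{method}.
#' @export
estimate_noise <- function(map, method = c("corners", "mask"), mask = NULL) {
  method <- match.arg(method)
  d3 <- dim(map$data)
  if (method == "corners") {
    if (min(d3) < 32) stop("corners method needs a grid of at least 32^3")
    e <- pmax(1L, d3 %/% 8L)
    v <- numeric(0)
    for (cx in list(1:e[1], (d3[1] - e[1] + 1):d3[1]))
      for (cy in list(1:e[2], (d3[2] - e[2] + 1):d3[2]))
        for (cz in list(1:e[3], (d3[3] - e[3] + 1):d3[3]))
          v <- c(v, as.numeric(map$data[cx, cy, cz]))
  } else {
    if (is.null(mask) || sum(mask) < 1000)
      stop("mask method needs a solvent mask with >= 1000 voxels")
    v <- map$data[mask]
  }
  s <- stats::sd(v)
  if (s == 0) stop("degenerate background: sd = 0")
  m <- mean(v)
  zc <- (v - m) / s
  list(mean = m, sd = s, skew = mean(zc^3), kurt = mean(zc^4) - 3,
       n = length(v), method = method)
}

#' FDR confidence map
#'
#' One-sided right-tail p-values per voxel under the Gaussian background
#' model, adjusted for multiple testing over all voxels with the
#' Benjamini-Yekutieli procedure (dependency-robust; spatially
#' correlated voxels violate the independence assumption of
#' Benjamini-Hochberg, which remains available via \code{method}).
#' Confidence = 1 - q.
#'
#' @param map a \code{\link{density_map}}.
#' @param noise background model from \code{\link{estimate_noise}} (or a
#'   list with \code{mean} and \code{sd}).
#' @param fdr default binarisation level in (0, 1) (default 0.01).
#' @param method \code{"BY"} (default) or \code{"BH"}.
#' @return a \code{confidence_map}: list with \code{q} and
#'   \code{confidence} arrays on the source grid, \code{noise},
#'   \code{fdr}, \code{method}, \code{voxel_size}, \code{origin}.
#' @export
confidence_map <- function(map, noise, fdr = 0.01, method = c("BY", "BH")) {
  method <- match.arg(method)
  stopifnot(fdr > 0, fdr < 1)
  if (!is.null(noise$skew) &&
      (abs(noise$skew) > 1 || (!is.null(noise$kurt) && abs(noise$kurt) > 2)))
    warning("background sample looks non-Gaussian (|skew| > 1 or |excess kurtosis| > 2); confidence values may be miscalibrated")
  p <- stats::pnorm(as.vector(map$data), mean = noise$mean, sd = noise$sd,
                    lower.tail = FALSE)
  q <- stats::p.adjust(p, method = method)
  structure(list(q = array(q, dim = dim(map$data)),
                 confidence = array(1 - q, dim = dim(map$data)),
                 noise = noise, fdr = fdr, method = method,
                 voxel_size = map$voxel_size, origin = map$origin),
            class = "confidence_map")
}

#' Binary signal mask of a confidence map at a given FDR level
#'
#' @param conf a \code{confidence_map}.
#' @param fdr level; defaults to the level stored in \code{conf}.
#' @return boolean array of flagged (confident) voxels.
#' @export
flagged_voxels <- function(conf, fdr = conf$fdr) {
  conf$q <= fdr
}

#' Per-residue FDR-backbone scores
#'
#' For each residue i, the fraction of backbone atoms (N, CA, C, O) of
#' residues [i - w, i + w] whose nearest voxel is flagged confident at
#' the given FDR level. The "nearest voxel" of an atom is the
#' maximum-confidence voxel among the 2x2x2 grid neighbours of its
#' fractional grid position (robust to half-voxel origin offsets). Low
#' scores indicate backbone mis-tracing.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param conf a \code{\link{confidence_map}}.
#' @param fdr FDR level (default: the map's stored level).
#' @param half_window residues either side of i (default 2).
#' @return a \code{residue_score_table} data.frame with column
#'   \code{fdr_backbone} in [0, 1] (NA when no backbone atoms).
#' @export
fdr_backbone_score <- function(model, conf, fdr = conf$fdr, half_window = 2) {
  res <- model_residues(model)
  if (nrow(res) == 0) stop("no polymer residues present")
  a <- select_conformer(model)$atoms
  a <- a[!a$het & a$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
  d3 <- dim(conf$q)
  # per-atom: is its nearest voxel flagged?
  flag <- conf$q <= fdr
  atom_ok <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    g0 <- (c(a$x[i], a$y[i], a$z[i]) - conf$origin) / conf$voxel_size + 1
    lo <- pmin(pmax(floor(g0), 1), d3)
    hi <- pmin(lo + 1, d3)
    best <- -Inf
    for (ix in unique(c(lo[1], hi[1]))) for (iy in unique(c(lo[2], hi[2])))
      for (iz in unique(c(lo[3], hi[3]))) {
        v <- conf$confidence[ix, iy, iz]
        if (v > best) { best <- v; atom_ok[i] <- flag[ix, iy, iz] }
      }
  }
  rkey <- paste(a$chain, a$resno, a$ins, sep = "\r")
  key <- paste(res$chain, res$resno, res$ins, sep = "\r")
  scores <- rep(NA_real_, nrow(res))
  for (i in seq_len(nrow(res))) {
    same <- which(res$chain == res$chain[i])
    win <- same[res$resno[same] >= res$resno[i] - half_window &
                res$resno[same] <= res$resno[i] + half_window]
    sel <- rkey %in% key[win]
    own <- rkey == key[i]
    if (!any(own)) next                       # residue missing all backbone
    if (any(sel)) scores[i] <- mean(atom_ok[sel])
  }
  out <- cbind(res, fdr_backbone = scores)
  class(out) <- c("residue_score_table", "data.frame")
  out
}
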