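#' Default per-metric flag thresholds
#'
#' SMOC < 0.5 and fdr_backbone < 0.5 (the half-scale convention applied
#' per residue); geometry outlier flags are taken directly.
#'
#' @export
default_thresholds <- function() list(smoc = 0.5, fdr_backbone = 0.5)

res_key <- function(d) paste(d$chain, d$resno, d$ins, sep = "\r")

#' Flag low-scoring residues across all metrics
#'
#' Outer-joins the per-residue score tables and the geometry outlier
#' table on the residue key, flags each metric by its threshold rule
#' (score below threshold; geometry outliers directly) and counts
#' issues per residue. Missing (NA) scores are never flagged.
#'
#' @param score_tables named list of \code{residue_score_table}s; names
#'   are metric column names (e.g. \code{smoc}, \code{fdr_backbone}).
#' @param geometry_table per-residue geometry flags from
#'   \code{\link{geometry_summary}} (\code{$residue_table}); optional.
#' @param thresholds named list of per-metric thresholds.
#' @return an \code{issue_table} data.frame: residue keys, score
#'   columns, \code{flag_<metric>} booleans, \code{issue_count}.
#' @export
flag_residues <- function(score_tables, geometry_table = NULL,
                          thresholds = default_thresholds()) {
  base <- NULL
  for (nm in names(score_tables)) {
    t <- score_tables[[nm]]
    if (anyDuplicated(res_key(t))) {
      d <- t[duplicated(res_key(t)), ]
      stop("conflicting duplicate residue key in '", nm, "': ",
           d$chain[1], "/", d$resno[1], d$ins[1])
    }
    cols <- t[, c("chain", "resno", "ins", "resname", nm)]
    base <- if (is.null(base)) cols else
      merge(base, cols, by = c("chain", "resno", "ins", "resname"),
            all = TRUE)
  }
  geom_flags <- c("rama_outlier", "rotamer_outlier", "cablam_outlier", "clash")
  if (!is.null(geometry_table)) {
    gcols <- geometry_table[, c("chain", "resno", "ins", "resname",
                                intersect(geom_flags, names(geometry_table)))]
    base <- if (is.null(base)) gcols else
      merge(base, gcols, by = c("chain", "resno", "ins", "resname"), all = TRUE)
  }
  if (is.null(base)) stop("no score tables supplied")
  base <- base[order(base$chain, base$resno, base$ins), , drop = FALSE]
  rownames(base) <- NULL
  flag_cols <- character(0)
  for (nm in names(score_tables)) {
    th <- thresholds[[nm]]
    fc <- paste0("flag_", nm)
    base[[fc]] <- !is.na(base[[nm]]) & !is.null(th) & base[[nm]] < (th %||% -Inf)
    flag_cols <- c(flag_cols, fc)
  }
  for (gf in intersect(geom_flags, names(base))) {
    fc <- paste0("flag_", gf)
    base[[fc]] <- !is.na(base[[gf]]) & base[[gf]]
    flag_cols <- c(flag_cols, fc)
  }
  base$issue_count <- rowSums(base[, flag_cols, drop = FALSE])
  attr(base, "flag_cols") <- flag_cols
  class(base) <- c("issue_table", "data.frame")
  base
}

# union-find single-linkage components from an edge list
single_linkage <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster flagged residues by spatial proximity
#'
#' Single-linkage clustering of flagged residues with CA-CA distance
#' <= \code{cutoff}; clusters are ranked by (severity = sum of member
#' issue counts, descending), then distinct-metric count (descending),
#' then first member's (chain, residue number) ascending.
#'
#' @param issues an \code{issue_table} from \code{\link{flag_residues}}.
#' @param model the \code{\link{atomic_model}} (for CA coordinates).
#' @param cutoff CA-CA linkage distance in Angstrom (default 8).
#' @return list of \code{issue_cluster}s: each with \code{members}
#'   (data.frame), \code{centroid}, \code{severity},
#'   \code{n_metrics}, ranked; empty list when nothing is flagged.
#' @export
cluster_issues <- function(issues, model, cutoff = 8) {
  fl <- issues[issues$issue_count > 0, , drop = FALSE]
  if (!nrow(fl)) return(list())
  a <- select_conformer(model)$atoms
  ca <- a[a$atom == "CA" & !a$het, , drop = FALSE]
  m <- match(res_key(fl), res_key(ca))
  if (anyNA(m)) stop("flagged residue(s) without CA atoms: ",
                     paste(fl$resno[is.na(m)], collapse = ", "))
  xyz <- as.matrix(ca[m, c("x", "y", "z")])
  n <- nrow(fl)
  edges <- neighbor_pairs(xyz, cutoff)
  comp <- single_linkage(n, edges)
  flag_cols <- attr(issues, "flag_cols") %||%
    grep("^flag_", names(issues), value = TRUE)
  clusters <- lapply(split(seq_len(n), comp), function(ii) {
    mem <- fl[ii, , drop = FALSE]
    mem <- mem[order(mem$chain, mem$resno, mem$ins), , drop = FALSE]
    nmet <- sum(vapply(flag_cols, function(fc) any(mem[[fc]]), TRUE))
    list(members = mem,
         centroid = colMeans(xyz[ii, , drop = FALSE]),
         severity = sum(mem$issue_count),
         n_metrics = nmet)
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "severity"),
               -vapply(clusters, `[[`, numeric(1), "n_metrics"),
               vapply(clusters, function(cl) cl$members$chain[1], character(1)),
               vapply(clusters, function(cl) cl$members$resno[1], integer(1)))
  unname(clusters[ord])
}

#' Compare two scored models (before vs after)
#'
#' dFSC = FSCavg(after) - FSCavg(before); dMolProbity =
#' MolProbity(after) - MolProbity(before). Positive dFSC means better
#' fit; positive dMolProbity means worse geometry.
#'
#' @param before,after lists each containing \code{fsc_avg} and
#'   \code{molprobity_score}.
#' @return list with \code{dFSC} and \code{dMolProbity}.
#' @export
compare_models <- function(before, after) {
  list(dFSC = after$fsc_avg - before$fsc_avg,
       dMolProbity = after$molprobity_score - before$molprobity_score)
}

#' List contacts at a residue site
#'
#' Partner residues with any heavy-atom distance <= \code{cutoff} to the
#' site residue, typed \code{polar} when both atoms are N/O,
#' \code{clash} when the vdW overlap is >= 0.4 A, else \code{nonpolar}.
#' Sequence neighbours (i +/- 1 in the same chain) are excluded.
#'
#' @param model an \code{\link{atomic_model}}.
#' @param chain,resnum,ins site residue key.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return a \code{contact_list} data.frame: partner residue key,
#'   minimum atom-atom distance, contact type.
#' @export
contacts_at_site <- function(model, chain, resnum, ins = "", cutoff = 4.0) {
  a <- select_conformer(model)$atoms
  a <- a[!a$hydrogen, , drop = FALSE]
  site <- a$chain == chain & a$resno == resnum & a$ins == ins
  if (!any(site)) {
    near <- unique(a[a$chain == chain &
                       abs(a$resno - resnum) <= 2, c("chain", "resno", "ins")])
    stop("site ", chain, "/", resnum, ins, " not found; near misses: ",
         if (nrow(near)) paste(near$chain, near$resno, sep = "/", collapse = ", ")
         else "(none)")
  }
  sa <- a[site, , drop = FALSE]
  oa <- a[!site, , drop = FALSE]
  # drop bonded sequence neighbours
  oa <- oa[!(oa$chain == chain & abs(oa$resno - resnum) <= 1), , drop = FALSE]
  if (!nrow(oa)) return(empty_contacts())
  rows <- list()
  okey <- paste(oa$chain, oa$resno, oa$ins, sep = "\r")
  for (k in unique(okey)) {
    pa <- oa[okey == k, , drop = FALSE]
    dmin <- Inf; best <- NULL
    for (i in seq_len(nrow(sa))) {
      d <- sqrt((pa$x - sa$x[i])^2 + (pa$y - sa$y[i])^2 + (pa$z - sa$z[i])^2)
      j <- which.min(d)
      if (d[j] < dmin) {
        dmin <- d[j]
        best <- list(site_atom = sa$atom[i], partner_atom = pa$atom[j],
                     e1 = sa$element[i], e2 = pa$element[j])
      }
    }
    if (dmin > cutoff) next
    ov <- vdw_radius(best$e1) + vdw_radius(best$e2) - dmin
    type <- if (ov >= 0.4) "clash"
            else if (best$e1 %in% c("N", "O") && best$e2 %in% c("N", "O")) "polar"
            else "nonpolar"
    rows[[length(rows) + 1]] <- data.frame(
      site_chain = chain, site_resno = resnum, site_ins = ins,
      partner_chain = pa$chain[1], partner_resno = pa$resno[1],
      partner_ins = pa$ins[1], partner_resname = pa$resname[1],
      site_atom = best$site_atom, partner_atom = best$partner_atom,
      min_dist = dmin, type = type, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_contacts()
  out <- out[order(out$min_dist), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_list", "data.frame")
  out
}

empty_contacts <- function() {
  out <- data.frame(site_chain = character(), site_resno = integer(),
                    site_ins = character(), partner_chain = character(),
                    partner_resno = integer(), partner_ins = character(),
                    partner_resname = character(), site_atom = character(),
                    partner_atom = character(), min_dist = numeric(),
                    type = character())
  class(out) <- c("contact_list", "data.frame")
  out
}

#' Assemble and write the validation report
#'
#' Writes \code{report.json} (machine-readable: inputs, parameters,
#' global scores, per-residue table, ranked clusters),
#' \code{residue_scores.csv}, \code{clashes.csv} and a plain-text
#' \code{summary.txt} whose first section lists the issue clusters in
#' rank order. The JSON is deterministic for identical inputs and
#' parameters; the timestamp is isolated in its own field so it can be
#' excluded from determinism hashes.
#'
#' @param results list with any of: \code{global_fit}, \code{geometry},
#'   \code{issues} (issue_table), \code{clusters}, \code{clashes}.
#' @param metadata named list echoed verbatim into the report
#'   (input paths, resolution, every tunable parameter used).
#' @param out_dir output directory (created if absent).
#' @return invisibly, the report list.
#' @export
build_report <- function(results, metadata, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  clusters_json <- lapply(results$clusters %||% list(), function(cl) {
    list(severity = cl$severity, n_metrics = cl$n_metrics,
         centroid = round(unname(cl$centroid), 3),
         members = sprintf("%s/%d%s", cl$members$chain, cl$members$resno,
                           cl$members$ins))
  })
  report <- list(
    schema_version = "1.0",
    parameters = metadata,
    global_fit = results$global_fit %||% NULL,
    geometry = results$geometry %||% NULL,
    clusters = clusters_json,
    residue_scores = results$issues %||% NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  json_path <- file.path(out_dir, "report.json")
  tmp <- paste0(json_path, ".tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", null = "null", pretty = TRUE)
  file.rename(tmp, json_path)
  if (!is.null(results$issues))
    utils::write.csv(results$issues, file.path(out_dir, "residue_scores.csv"),
                     row.names = FALSE)
  if (!is.null(results$clashes))
    utils::write.csv(results$clashes, file.path(out_dir, "clashes.csv"),
                     row.names = FALSE)
  lines <- c("validation summary", "==================", "",
             "issue clusters (ranked):")
  if (length(clusters_json)) {
    for (i in seq_along(clusters_json)) {
      cl <- clusters_json[[i]]
      lines <- c(lines, sprintf(
        "  %d. severity %s, %s metric(s), residues: %s", i, cl$severity,
        cl$n_metrics, paste(cl$members, collapse = " ")))
    }
  } else lines <- c(lines, "  (none)")
  if (!is.null(results$global_fit))
    lines <- c(lines, "", sprintf("FSCavg = %.4f at %.2f A cutoff",
                                  results$global_fit$fsc_avg,
                                  results$global_fit$resolution_cutoff))
  if (!is.null(results$geometry))
    lines <- c(lines, sprintf("MolProbity-style score = %.3f",
                              results$geometry$molprobity_score))
  lines <- c(lines, "", "parameters:",
             paste0("  ", names(metadata), " = ",
                    vapply(metadata, function(x) paste(format(x), collapse = " "),
                           character(1))))
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(report)
}
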