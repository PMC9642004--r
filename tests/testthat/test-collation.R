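fake_table <- function(resno, col, vals) {
  out <- data.frame(chain = "A", resno = resno, ins = "", resname = "ALA")
  out[[col]] <- vals
  class(out) <- c("residue_score_table", "data.frame")
  out
}

test_that("flagging joins tables, applies thresholds, never flags NA", {
  sm <- fake_table(1:10, "smoc", c(rep(0.9, 4), 0.3, rep(0.9, 4), NA))
  fb <- fake_table(1:10, "fdr_backbone", c(rep(1, 5), rep(1, 5)))
  it <- flag_residues(list(smoc = sm, fdr_backbone = fb))
  expect_equal(sum(it$flag_smoc), 1)
  expect_equal(it$resno[it$flag_smoc], 5)
  expect_equal(it$issue_count[it$resno == 5], 1)
  expect_equal(sum(it$issue_count), 1)
  expect_false(it$flag_smoc[it$resno == 10])          # NA never flagged
  dup <- rbind(sm, sm[1, ])
  expect_error(flag_residues(list(smoc = dup)), "duplicate")
})

test_that("all-green helix produces zero flags and zero clusters", {
  tp <- fix_pair()
  st <- smoc(tp$model, tp$map, 3)
  gs <- geometry_summary(tp$model)
  it <- flag_residues(list(smoc = st), geometry_table = gs$residue_table)
  expect_equal(sum(it$issue_count), 0)
  expect_length(cluster_issues(it, tp$model), 0)
})

test_that("smoc and fdr_backbone flags co-occur on a shifted segment", {
  tp <- fix_noisy_pair()
  hp <- perturb(fix_helix(), perturbation_spec("segment_shift", 10, 14,
                                               magnitude = 4, seed = 5))
  st <- smoc(hp, tp$map, 3)
  cm <- confidence_map(tp$map, estimate_noise(tp$map, "corners"), fdr = 0.01)
  fb <- fdr_backbone_score(hp, cm)
  it <- flag_residues(list(smoc = st, fdr_backbone = fb))
  both <- it$flag_smoc & it$flag_fdr_backbone
  expect_true(any(both))
  expect_true(all(it$resno[both] >= 8 & it$resno[both] <= 16))
})

test_that("single-linkage clustering matches the naive component oracle", {
  h <- fix_helix()
  # consecutive helix residues 10-12: one cluster of three
  it <- fake_table(1:30, "smoc", ifelse(1:30 %in% 10:12, 0.1, 0.9))
  it <- flag_residues(list(smoc = it))
  cl <- cluster_issues(it, h, cutoff = 8)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members$resno, 10:12)
  expect_equal(cl[[1]]$severity, 3)
  # two flagged residues far apart: two singletons
  it2 <- flag_residues(list(smoc = fake_table(1:30, "smoc",
                                              ifelse(1:30 %in% c(2, 28), 0.1, 0.9))))
  cl2 <- cluster_issues(it2, h, cutoff = 8)
  expect_length(cl2, 2)
  # randomized flag sets vs naive union-find over the full matrix
  ca <- h$atoms[h$atoms$atom == "CA", c("x", "y", "z")]
  set.seed(81)
  for (rep in 1:30) {
    flagged <- sort(sample(1:30, sample(2:12, 1)))
    itr <- flag_residues(list(smoc = fake_table(1:30, "smoc",
                                                ifelse(1:30 %in% flagged, 0.1, 0.9))))
    clr <- cluster_issues(itr, h, cutoff = 8)
    comp <- naive_components(as.matrix(ca[flagged, ]), 8)
    want_sizes <- sort(as.integer(table(comp)))
    got_sizes <- sort(vapply(clr, function(cl) nrow(cl$members), integer(1)))
    expect_equal(got_sizes, want_sizes)
    # membership partition identical
    want_groups <- lapply(split(flagged, comp), sort)
    got_groups <- lapply(clr, function(cl) sort(cl$members$resno))
    expect_setequal(lapply(want_groups, paste, collapse = ","),
                    lapply(got_groups, paste, collapse = ","))
    # every flagged residue in exactly one cluster
    expect_equal(sort(unlist(lapply(clr, function(cl) cl$members$resno))),
                 flagged)
  }
})

test_that("cluster ranking is a severity-ordered total order", {
  h <- fix_helix()
  sm <- fake_table(1:30, "smoc", ifelse(1:30 %in% c(3, 20, 21, 22), 0.1, 0.9))
  fb <- fake_table(1:30, "fdr_backbone", ifelse(1:30 %in% c(20, 21), 0.1, 1))
  it <- flag_residues(list(smoc = sm, fdr_backbone = fb))
  cl <- cluster_issues(it, h, cutoff = 8)
  sev <- vapply(cl, `[[`, numeric(1), "severity")
  expect_equal(sev, sort(sev, decreasing = TRUE))
  expect_equal(cl[[1]]$members$resno, 20:22)           # severity 5
  expect_equal(cl[[1]]$n_metrics, 2)
})

test_that("model comparison: self-zero, antisymmetry, the 5% bin boundary", {
  a <- list(fsc_avg = 0.50, molprobity_score = 1.2)
  b <- list(fsc_avg = 0.55, molprobity_score = 1.0)
  expect_equal(compare_models(a, a), list(dFSC = 0, dMolProbity = 0))
  ab <- compare_models(a, b); ba <- compare_models(b, a)
  expect_equal(ab$dFSC, -ba$dFSC)
  expect_equal(ab$dMolProbity, -ba$dMolProbity)
  expect_equal(ab$dFSC, 0.05)
})

test_that("contacts: empty far case, polar O..N pair, brute-force equivalence", {
  h <- fix_helix()
  # an isolated residue far away
  iso <- h$atoms[h$atoms$resno == 1, ]
  iso$x <- iso$x + 100; iso$resno <- 99L; iso$chain <- "B"
  m <- atomic_model(rbind(h$atoms, iso))
  expect_equal(nrow(contacts_at_site(m, "B", 99)), 0)
  # constructed O..N pair at 2.9 A between two isolated chains
  mkatom <- function(chain, resno, atom, elem, x) data.frame(
    chain = chain, resno = resno, ins = "", resname = "ALA", atom = atom,
    element = elem, x = x, y = 500, z = 500, b = 30, occ = 1, altloc = "",
    het = FALSE, hydrogen = FALSE, stringsAsFactors = FALSE)
  m2 <- atomic_model(rbind(h$atoms, mkatom("B", 1, "O", "O", 0),
                           mkatom("C", 1, "N", "N", 2.9)))
  cc <- contacts_at_site(m2, "C", 1)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$type, "polar")
  expect_equal(cc$min_dist, 2.9, tolerance = 1e-9)
  # brute-force oracle on random two-chain models
  set.seed(82)
  for (rep in 1:5) {
    mdl <- random_model(80, seed = 900 + rep, box = 15)
    site <- mdl$atoms[1, ]
    got <- contacts_at_site(mdl, site$chain, site$resno, cutoff = 4)
    a <- mdl$atoms
    sel <- a$chain == site$chain & a$resno == site$resno
    want <- character(0)
    for (k in which(!sel)) {
      if (a$chain[k] == site$chain && abs(a$resno[k] - site$resno) <= 1) next
      dmin <- min(sqrt((a$x[sel] - a$x[k])^2 + (a$y[sel] - a$y[k])^2 +
                         (a$z[sel] - a$z[k])^2))
      if (dmin <= 4) want <- c(want, paste(a$chain[k], a$resno[k]))
    }
    expect_setequal(paste(got$partner_chain, got$partner_resno), unique(want))
  }
  expect_error(contacts_at_site(h, "A", 999), "near miss")
})

test_that("reports round-trip, echo parameters, and are deterministic", {
  tp <- fix_pair()
  st <- smoc(tp$model, tp$map, 3)
  gs <- geometry_summary(tp$model)
  it <- flag_residues(list(smoc = st), geometry_table = gs$residue_table)
  cl <- cluster_issues(it, tp$model)
  meta <- list(command = "validate", resolution = 3, fsc_avg_cutoff = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_report(list(geometry = gs$summary, issues = it, clusters = cl,
                    clashes = gs$clashes), meta, d1)
  build_report(list(geometry = gs$summary, issues = it, clusters = cl,
                    clashes = gs$clashes), meta, d2)
  r1 <- jsonlite::read_json(file.path(d1, "report.json"))
  r2 <- jsonlite::read_json(file.path(d2, "report.json"))
  expect_equal(r1$parameters$fsc_avg_cutoff, 3)
  expect_length(r1$clusters, 0)
  r1$timestamp <- NULL; r2$timestamp <- NULL
  expect_identical(r1, r2)            # byte-identical minus timestamp field
  expect_equal(r1$geometry$molprobity_score, gs$summary$molprobity_score,
               tolerance = 1e-9)
  expect_true(file.exists(file.path(d1, "residue_scores.csv")))
  expect_true(file.exists(file.path(d1, "summary.txt")))
})
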