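test_that("torsion computation matches an independent oracle and is rigid-invariant", {
  set.seed(51)
  for (rep in 1:20) {
    pts <- lapply(1:4, function(i) rnorm(3) * 3)
    t1 <- torsion_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    t2 <- brute_torsion(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    expect_equal(t1, t2, tolerance = 1e-9)
    # random rigid transform
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]),
                   cos(th[1])), 3, 3)
    Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                   0, 0, 1), 3, 3)
    R <- Rx %*% Rz
    tr <- rnorm(3) * 10
    q <- lapply(pts, function(p) as.vector(R %*% p) + tr)
    expect_equal(torsion_angle(q[[1]], q[[2]], q[[3]], q[[4]]), t1,
                 tolerance = 1e-9)
  }
})

test_that("alanine gains its 5 riding hydrogens at ideal bond lengths, idempotently", {
  h <- fix_helix(10)
  hh <- add_hydrogens(h)
  a <- hh$atoms
  # central residue: H, HA, HB1-3
  r5 <- a[a$resno == 5 & a$hydrogen, ]
  expect_setequal(r5$atom, c("H", "HA", "HB1", "HB2", "HB3"))
  # N-terminal residue gets no amide H
  expect_false("H" %in% a$atom[a$resno == 1 & a$hydrogen])
  # bond lengths match the packaged ideals
  parent <- c(H = "N", HA = "CA", HB1 = "CB", HB2 = "CB", HB3 = "CB")
  ideal <- c(H = 1.01, HA = 1.09, HB1 = 1.09, HB2 = 1.09, HB3 = 1.09)
  heavy5 <- a[a$resno == 5 & !a$hydrogen, ]
  for (hn in r5$atom) {
    hp <- unlist(r5[r5$atom == hn, c("x", "y", "z")])
    pp <- unlist(heavy5[heavy5$atom == parent[hn], c("x", "y", "z")])
    expect_equal(sqrt(sum((hp - pp)^2)), unname(ideal[hn]), tolerance = 1e-3)
  }
  hh2 <- add_hydrogens(hh)
  expect_equal(nrow(hh2$atoms), nrow(hh$atoms))
})

test_that("clash arithmetic on constructed probes", {
  probe <- function(i, x, d_apart = 50) atomic_model(data.frame(
    chain = "A", resno = i, ins = "", resname = "ALA", atom = "CA",
    element = "C", x = x, y = i * d_apart, z = 0, b = 30, occ = 1,
    altloc = "", het = FALSE, hydrogen = FALSE))
  # two C atoms 5 A apart: no clash
  two <- atomic_model(rbind(probe(1, 0)$atoms,
                            within(probe(5, 5)$atoms, y <- 0)))
  expect_equal(find_clashes(two)$clashscore, 0)
  # 10 atoms, one pair at 2.6 A: overlap 1.70 + 1.70 - 2.6 = 0.8 -> 1 clash
  rows <- do.call(rbind, lapply(1:9, function(i) probe(i * 3, 0)$atoms))
  rows$resno <- seq(10, 90, 10)
  extra <- probe(95, 2.6)$atoms; extra$y <- 10 * 50
  rows2 <- rbind(rows, extra)
  rows2$y[nrow(rows2)] <- rows2$y[1]      # same y as atom 1, x = 2.6
  rows2$y[1] <- rows2$y[nrow(rows2)]
  m10 <- atomic_model(rows2)
  cl <- find_clashes(m10)
  expect_equal(nrow(cl$clashes), 1)
  expect_equal(cl$clashes$overlap, 0.8, tolerance = 1e-9)
  expect_equal(cl$clashscore, 100)        # 1000 * 1/10
})

test_that("spatial-grid clash detection equals the brute-force pair loop", {
  for (seed in 1:15) {
    mdl <- random_model(100, seed = 600 + seed)
    got <- find_clashes(mdl)
    want <- brute_clashes(mdl)
    expect_equal(nrow(got$clashes), nrow(want),
                 info = paste("seed", seed))
    if (nrow(want)) {
      o1 <- sort(got$clashes$overlap)
      o2 <- sort(want[, 3])
      expect_equal(o1, o2, tolerance = 1e-12)
    }
  }
})

test_that("neighbour-pair hashing equals brute force", {
  set.seed(52)
  for (rep in 1:5) {
    xyz <- matrix(runif(3 * 60, 0, 15), ncol = 3)
    got <- emval:::neighbor_pairs(xyz, 3.0)
    want <- brute_pairs(xyz, 3.0)
    key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    expect_identical(key(got), key(want))
  }
})

test_that("Ramachandran classification: helix favored, constructed outlier, z dual-route", {
  h <- fix_helix()
  r <- ramachandran(h)
  expect_equal(r$rama_favored_pct, 100)
  expect_equal(r$rama_outlier_pct, 0)
  # (+60, -120) for a non-Gly residue is empty reference space
  g <- emval:::rama_grid("general")
  dens <- emval:::grid_lookup_2d(g$dens, 60, -120)
  expect_lt(dens, g$allowed_level)
  # z-score agrees with a direct re-derivation from the table
  zs <- vapply(seq_len(nrow(r$table)), function(i) {
    gi <- emval:::rama_grid(emval:::rama_type(
      r$table$resname[i],
      if (i < nrow(r$table)) r$table$resname[i + 1] else NA))
    (log(emval:::grid_lookup_2d(gi$dens, r$table$phi[i], r$table$psi[i])) -
       gi$logp_mean) / gi$logp_sd
  }, numeric(1))
  expect_equal(r$rama_z, mean(zs) * sqrt(length(zs)), tolerance = 1e-9)
  # too-short chain warns and returns no rows
  expect_warning(r2 <- ramachandran(make_helix(5)), NA)
})

test_that("rotamer scoring: canonical leucine passes, eclipsed chi1 is an outlier", {
  good <- make_leu(-60, 180)
  ro <- rotamer_outliers(good)
  leu <- ro$table[ro$table$resname == "LEU", ]
  expect_false(leu$rotamer_outlier)
  expect_equal(leu$chi1, -60, tolerance = 1e-6)
  bad <- make_leu(120, 180)
  rb <- rotamer_outliers(bad)
  expect_true(rb$table$rotamer_outlier[rb$table$resname == "LEU"])
  # Ala residues are unscorable and excluded from the denominator
  expect_equal(nrow(ro$table), 1)
  expect_equal(ro$n_unscorable, 6)
})

test_that("CA-trace flags: clean helix, displaced segment, torsion oracle", {
  h <- fix_helix()
  cb <- cablam_flags(h)
  expect_equal(cb$cablam_outlier_pct, 0)
  # seed 4's shift direction keeps both junction CA-CA distances below
  # the 4.5 A chain-break rule, so the broken helical mu pattern is
  # scored (and flagged) rather than split into unscorable segments
  hp <- perturb(h, perturbation_spec("segment_shift", 10, 14, 3, seed = 4))
  cbp <- cablam_flags(hp)
  flagged <- cbp$table$resno[cbp$table$cablam_outlier]
  expect_true(any(flagged >= 8 & flagged <= 16))
  # a rupturing direction instead splits the trace: junction residues
  # become unscorable
  hp2 <- perturb(h, perturbation_spec("segment_shift", 10, 14, 3, seed = 1))
  cb2 <- cablam_flags(hp2)
  expect_lt(nrow(cb2$table), nrow(cbp$table))
  # mu_in matches the brute-force torsion oracle
  ca <- h$atoms[h$atoms$atom == "CA", c("x", "y", "z")]
  i <- 10
  mu_in_oracle <- brute_torsion(unlist(ca[i - 2, ]), unlist(ca[i - 1, ]),
                                unlist(ca[i, ]), unlist(ca[i + 1, ]))
  expect_equal(cb$table$mu_in[cb$table$resno == i], mu_in_oracle,
               tolerance = 1e-9)
})

test_that("composite geometry score: closed forms and monotonicity", {
  expect_equal(molprobity_score(0, 0, 100), 0.5)
  direct <- 0.426 * log(11) + 0.33 * log(5) + 0.25 * log(9) + 0.5
  expect_equal(molprobity_score(10, 5, 90), direct, tolerance = 1e-12)
  expect_gt(molprobity_score(11, 5, 90), molprobity_score(10, 5, 90))
  expect_gt(molprobity_score(10, 6, 90), molprobity_score(10, 5, 90))
  expect_gt(molprobity_score(10, 5, 89), molprobity_score(10, 5, 90))
})

test_that("ideal helix is the all-green baseline", {
  gs <- geometry_summary(fix_helix())
  expect_equal(gs$summary$clashscore, 0)
  expect_equal(gs$summary$rotamer_outlier_pct, 0)
  expect_equal(gs$summary$rama_favored_pct, 100)
  expect_equal(gs$summary$cablam_outlier_pct, 0)
  expect_equal(gs$summary$molprobity_score, 0.5)
  expect_false(any(gs$residue_table$clash))
})

test_that("injected clash is detected and raises the composite score", {
  h <- fix_helix()
  hp <- perturb(h, perturbation_spec("clash_inject", 10, 10, magnitude = 0.9))
  gs <- geometry_summary(hp)
  expect_gt(gs$summary$clashscore, 0)
  expect_gt(gs$summary$molprobity_score, 0.5)
  expect_true(any(gs$residue_table$clash))
})
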