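# Shared fixtures, built once per test run. Seeds are fixed and listed
# here; tests never reseed these objects.

FIXTURE_SEEDS <- list(helix_pair = 11L, noisy_pair = 12L)

.fix <- new.env()

fix_helix <- function(n = 30) {
  key <- paste0("helix", n)
  if (is.null(.fix[[key]])) .fix[[key]] <- make_helix(n)
  .fix[[key]]
}

# noiseless 3 A map of the 30-residue helix
fix_pair <- function() {
  if (is.null(.fix$pair))
    .fix$pair <- make_test_pair(fix_helix(), resolution = 3, noise_sigma = 0,
                                seed = FIXTURE_SEEDS$helix_pair)
  .fix$pair
}

# moderately noisy pair on a grid big enough for corner noise estimation
fix_noisy_pair <- function() {
  if (is.null(.fix$noisy))
    .fix$noisy <- make_test_pair(fix_helix(), resolution = 3,
                                 noise_sigma = 0.5, box_pad = 12,
                                 seed = FIXTURE_SEEDS$noisy_pair,
                                 min_dim = 32)
  .fix$noisy
}

# white-noise map fixture
noise_map <- function(seed, n = 64, voxel = 1) {
  set.seed(seed)
  density_map(array(rnorm(n^3), dim = c(n, n, n)), rep(voxel, 3))
}

# leucine residue grafted onto a helix backbone with chosen chi angles
make_leu <- function(chi1, chi2) {
  h <- make_helix(7)
  a <- h$atoms
  i <- 4                                    # central residue becomes LEU
  sel <- a$resno == i
  n <- unlist(a[sel & a$atom == "N", c("x", "y", "z")])
  ca <- unlist(a[sel & a$atom == "CA", c("x", "y", "z")])
  cb <- unlist(a[sel & a$atom == "CB", c("x", "y", "z")])
  cg <- emval:::place_atom(n, ca, cb, 1.53, 116, chi1)
  cd1 <- emval:::place_atom(ca, cb, cg, 1.53, 111, chi2)
  cd2 <- emval:::place_atom(ca, cb, cg, 1.53, 111, chi2 + 120)
  add <- function(name, p) data.frame(
    chain = "A", resno = i, ins = "", resname = "LEU", atom = name,
    element = "C", x = p[1], y = p[2], z = p[3], b = 30, occ = 1,
    altloc = "", het = FALSE, hydrogen = FALSE, stringsAsFactors = FALSE)
  a$resname[sel] <- "LEU"
  atomic_model(rbind(a, add("CG", cg), add("CD1", cd1), add("CD2", cd2)))
}
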