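single_atom_model <- function(x, y, z, b = 0, occ = 1, elem = "C") {
  atomic_model(data.frame(
    chain = "A", resno = 1L, ins = "", resname = "ALA", atom = "CA",
    element = elem, x = x, y = y, z = z, b = b, occ = occ, altloc = "",
    het = FALSE, hydrogen = FALSE, stringsAsFactors = FALSE))
}

blank_map <- function(n = 24, voxel = 1) {
  density_map(array(0, dim = rep(n, 3)), rep(voxel, 3), origin = c(0, 0, 0))
}

test_that("single-atom density peaks at the atom and is isotropic", {
  tpl <- blank_map(24)
  m <- single_atom_model(11, 11, 11, b = 0)           # exactly a voxel centre
  sim <- simulate_map(m, tpl, resolution = 3)
  pk <- which(sim$data == max(sim$data), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(12, 12, 12))
  v <- sim$data
  expect_equal(v[13, 12, 12], v[12, 13, 12], tolerance = 1e-6)
  expect_equal(v[13, 12, 12], v[12, 12, 13], tolerance = 1e-6)
  expect_equal(v[11, 12, 12], v[13, 12, 12], tolerance = 1e-6)
})

test_that("integrated density matches total weight (direct integral oracle)", {
  tpl <- blank_map(32)
  set.seed(7)
  rows <- do.call(rbind, lapply(1:5, function(i)
    single_atom_model(runif(1, 12, 20), runif(1, 12, 20), runif(1, 12, 20),
                      b = runif(1, 10, 40),
                      elem = sample(c("C", "N", "O"), 1))$atoms))
  rows$occ <- runif(5, 0.5, 1)
  rows$atom <- paste0("X", 1:5)
  mdl <- atomic_model(rows)
  sim <- simulate_map(mdl, tpl, resolution = 3)
  total_weight <- sum(rows$occ * emval:::atomic_number(rows$element))
  integral <- sum(sim$data) * prod(tpl$voxel_size)
  expect_equal(integral, total_weight, tolerance = 0.01)
})

test_that("doubling B-factors lowers every atom-centre peak; occupancy is linear", {
  tpl <- blank_map(24)
  h <- make_helix(6)
  ctr <- colMeans(h$atoms[, c("x", "y", "z")])
  h$atoms$x <- h$atoms$x - ctr[1] + 12
  h$atoms$y <- h$atoms$y - ctr[2] + 12
  h$atoms$z <- h$atoms$z - ctr[3] + 12
  s1 <- simulate_map(h, tpl, 3)
  h2 <- h; h2$atoms$b <- h$atoms$b * 2
  s2 <- simulate_map(h2, tpl, 3)
  for (i in seq_len(nrow(h$atoms))) {
    idx <- round((c(h$atoms$x[i], h$atoms$y[i], h$atoms$z[i]) - tpl$origin) /
                   tpl$voxel_size) + 1
    expect_lt(s2$data[idx[1], idx[2], idx[3]], s1$data[idx[1], idx[2], idx[3]])
  }
  h3 <- h; h3$atoms$occ <- 0.5
  s3 <- simulate_map(h3, tpl, 3)
  expect_equal(s3$data, 0.5 * s1$data, tolerance = 1e-6)
})

test_that("wilson curve of white noise is flat (direct shell-sum oracle)", {
  # 16 shells on a 64^3 grid: >= 100 independent Fourier voxels per
  # inner shell, so the null curve is flat well within 0.2
  m <- noise_map(21, n = 64)
  wc <- wilson_curve(m, n_shells = 16)
  ref <- brute_shell_means(m, 16)
  expect_equal(exp(wc$log_amp), ref$mean[ref$n > 0], tolerance = 1e-10)
  inner <- wc$log_amp[2:(nrow(wc) - 1)]
  expect_lt(max(inner) - min(inner), 0.2)
})

test_that("applied exp(+B s^2/4) sharpening shows up as slope +B/4", {
  m <- noise_map(22, n = 64)
  B <- 100
  smag <- emval:::freq_magnitude_grid(dim(m$data), m$voxel_size)
  sharp <- Re(fft(fft(m$data) * exp(B * smag^2 / 4), inverse = TRUE)) / 64^3
  ms <- density_map(sharp, m$voxel_size)
  wc <- wilson_curve(ms, n_shells = 32)
  fit <- lm(log_amp ~ s2, data = as.data.frame(wc)[2:(nrow(wc) - 1), ])
  expect_equal(unname(coef(fit)[2]), B / 4, tolerance = 0.1)
})

test_that("over-sharpening detector flags constructed pathology and recovers slope", {
  tp <- fix_pair()
  sim <- simulate_map(tp$model, tp$map, 3, lowpass = FALSE)
  wc0 <- wilson_curve(sim)
  det0 <- detect_oversharpening(wc0)
  expect_false(det0$flag)
  B_applied <- 150
  B_intrinsic <- 30 + 4 * 3^2             # atomic B + resolution broadening
  smag <- emval:::freq_magnitude_grid(dim(sim$data), sim$voxel_size)
  sharp <- Re(fft(fft(sim$data) * exp(B_applied * smag^2 / 4),
                  inverse = TRUE)) / prod(dim(sim$data))
  det1 <- detect_oversharpening(wilson_curve(density_map(sharp, sim$voxel_size)))
  expect_true(det1$flag)
  expect_equal(det1$slope, (B_applied - B_intrinsic) / 4, tolerance = 0.15)
})

test_that("amplitude scaling: identity, shell match, phase preservation", {
  tp <- fix_pair()
  m <- tp$map
  out <- scale_amplitudes_global(m, m)
  expect_lt(sqrt(mean((out$data - m$data)^2)) / sqrt(mean(m$data^2)), 1e-6)
  # reference with non-vanishing shell amplitudes (no low-pass), so the
  # zero-shell clamp never engages
  m <- simulate_map(tp$model, tp$map, 3, lowpass = FALSE)
  set.seed(23)
  m2 <- density_map(array(rnorm(prod(dim(m$data))), dim(m$data)), m$voxel_size,
                    m$origin)
  sc <- scale_amplitudes_global(m2, m)
  n_sh <- min(dim(m$data)) %/% 2
  a_out <- brute_shell_means(sc, n_sh)
  a_ref <- brute_shell_means(m, n_sh)
  ok <- a_out$n > 0 & a_ref$mean > 1e-8
  expect_lt(max(abs(a_out$mean[ok] / a_ref$mean[ok] - 1)), 1e-3)
  ph_in <- Arg(fft(m2$data)); ph_out <- Arg(fft(sc$data))
  amp <- Mod(fft(m2$data))
  big <- amp > stats::quantile(amp, 0.5)
  expect_lt(max(abs(Arg(exp(1i * (ph_in[big] - ph_out[big]))))), 1e-6)
})

test_that("difference map: self-consistency, deleted-residue peak, antisymmetry", {
  tp <- fix_pair()
  sim <- simulate_map(tp$model, tp$map, 3)
  dm <- difference_map(tp$map, sim)
  rms_map <- sqrt(mean(tp$map$data^2))
  expect_lt(sqrt(mean(dm$exp_minus_model$data^2)), 0.05 * rms_map)
  expect_equal(dm$model_minus_exp$data, -dm$exp_minus_model$data)
  # delete residue 15: positive blob where it was
  del <- perturb(tp$model, perturbation_spec("delete_segment", 15, 15))
  sim_d <- simulate_map(del, tp$map, 3)
  dm2 <- difference_map(tp$map, sim_d)
  deleted <- tp$model$atoms[tp$model$atoms$resno == 15, ]
  near <- emval:::model_mask(atomic_model(deleted), tp$map, radius = 2)
  diff <- dm2$exp_minus_model$data
  bg_rms <- sqrt(mean(diff[!near]^2))
  expect_gt(mean(diff[near]), 3 * bg_rms)
})

test_that("local scaling is an identity on matched input and deterministic", {
  tp <- fix_pair()
  sim <- simulate_map(tp$model, tp$map, 3)
  sub_model <- atomic_model(tp$model$atoms[tp$model$atoms$resno %in% 14:16, ])
  out1 <- local_scale(sim, sim, window = 8, model = sub_model)
  msk <- emval:::model_mask(sub_model, sim, radius = 3)
  rel <- sqrt(mean((out1$data[msk] - sim$data[msk])^2)) /
    sqrt(mean(sim$data[msk]^2))
  expect_lt(rel, 0.02)
  expect_equal(sum(out1$data[!msk] != 0), 0)
  out2 <- local_scale(sim, sim, window = 8, model = sub_model)
  expect_identical(out1$data, out2$data)
})

test_that("local scaling pushes the local amplitude falloff toward the reference", {
  # two separated atoms, one sharp (B=20) one blurred (B=120); the
  # "experimental" map swaps their B-factors; after local scaling each
  # site's local curve should move toward the reference's
  tpl <- blank_map(40)
  two <- function(b1, b2) {
    r <- rbind(single_atom_model(12, 20, 20, b = b1)$atoms,
               single_atom_model(28, 20, 20, b = b2)$atoms)
    r$resno <- 1:2; r$atom <- c("X1", "X2")
    atomic_model(r)
  }
  ref <- simulate_map(two(20, 120), tpl, 3, lowpass = FALSE)
  ex <- simulate_map(two(120, 20), tpl, 3, lowpass = FALSE)
  out <- local_scale(ex, ref, window = 10, model = two(20, 120))
  box <- function(map, ctr, h = 5) {
    density_map(map$data[(ctr[1] - h):(ctr[1] + h), (ctr[2] - h):(ctr[2] + h),
                         (ctr[3] - h):(ctr[3] + h)], map$voxel_size)
  }
  slope <- function(map, ctr) {
    wc <- wilson_curve(box(map, ctr), n_shells = 4)
    coef(lm(log_amp ~ s2, data = as.data.frame(wc)))[2]
  }
  c1 <- c(13, 21, 21); c2 <- c(29, 21, 21)
  # site 1: reference sharper than experimental -> scaled slope shallower
  expect_gt(slope(out, c1), slope(ex, c1))
  # site 2: reference more blurred -> scaled slope steeper
  expect_lt(slope(out, c2), slope(ex, c2))
})
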