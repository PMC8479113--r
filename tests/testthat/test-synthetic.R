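test_that("rigid mode with zero noise yields identical frames", {
  tr <- generate_hexamer_trajectory(
    synthetic_spec(mode = "rigid", noise_sd = 0, n_frames = 5L))
  expect_lt(max(conventional_rmsd(tr)), 1e-12)
})

test_that("same seed reproduces coordinates bitwise; seeds differ", {
  sp <- hexamer_state_spec("deoxy", n_frames = 6L, seed = 3L)
  t1 <- generate_hexamer_trajectory(sp)
  t2 <- generate_hexamer_trajectory(sp)
  expect_identical(t1$coords, t2$coords)
  sp$seed <- 4L
  t3 <- generate_hexamer_trajectory(sp)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("ring counter-rotation angle is recovered by Kabsch fit", {
  nf <- 16L
  tr <- generate_hexamer_trajectory(
    synthetic_spec(mode = "ring_counter_rotation", mode_amplitude = 5,
                   noise_sd = 0, n_frames = nf))
  top_atoms <- atom_select(tr, ring = "top")
  bot_atoms <- atom_select(tr, ring = "bottom")
  for (t in c(3L, 5L, 7L)) {
    fit <- kabsch_superpose(frame_coords(tr, t)[top_atoms, ],
                            frame_coords(tr, 1L)[top_atoms, ])
    ang <- acos(pmin(1, (sum(diag(fit$rotation)) - 1) / 2)) * 180 / pi
    expect_equal(ang, abs(5 * sin(2 * pi * (t - 1) / nf)), tolerance = 1e-6)
    # bottom ring rotates by the opposite angle
    fitb <- kabsch_superpose(frame_coords(tr, t)[bot_atoms, ],
                             frame_coords(tr, 1L)[bot_atoms, ])
    angb <- acos(pmin(1, (sum(diag(fitb$rotation)) - 1) / 2)) * 180 / pi
    expect_equal(angb, ang, tolerance = 1e-6)
  }
})

test_that("unknown modes and bad parameters are rejected", {
  expect_error(synthetic_spec(mode = "wobble"))
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
  expect_error(synthetic_spec(n_frames = 1L), "n_frames")
  sp <- synthetic_spec(mode = "custom", noise_sd = 0, n_frames = 4L)
  expect_error(generate_hexamer_trajectory(sp), "custom_mode")
  expect_error(generate_toy_geometry("sphere", radius = -1), "positive")
})

test_that("toy geometries store their analytic ground truths", {
  g <- generate_toy_geometry("sphere", radius = 1.7, probe = 1.4)
  expect_equal(g$truth$asa, 4 * pi * 3.1^2, tolerance = 1e-12)
  h <- generate_toy_geometry("hourglass", constriction = 1.5)
  expect_equal(h$truth$bottleneck, 1.5)
  s <- generate_toy_geometry("hollow_shell", cavity_side = 6)
  expect_equal(s$truth$cavity_volume, 216)
  ch <- generate_toy_geometry("channel", radius = 2, length = 10)
  expect_equal(ch$truth$cost, 2.5)
  expect_equal(ch$truth$throughput, exp(-2.5))
})

test_that("site distance matrices satisfy metric invariants", {
  ds <- generate_site_distance_dataset(
    hexamer_state_spec("deoxy", seed = 1L),
    hexamer_state_spec("oxy", seed = 2L),
    frames_per_state = 8L, seed = 1L)
  expect_equal(dim(ds$matrices)[2:3], c(36L, 36L))
  for (t in seq_len(dim(ds$matrices)[1])) {
    m <- ds$matrices[t, , ]
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(0, 36))
    expect_true(all(m >= 0))
  }
  # triangle inequality on a spot-checked frame
  m <- ds$matrices[1, , ]
  for (i in 1:6) for (j in 7:12) for (k in 13:18)
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-9)
  # split is disjoint and 80:20
  expect_length(intersect(ds$split$train, ds$split$val), 0L)
  expect_equal(length(ds$split$train), round(0.8 * 16))
})

test_that("between-state site differences dominate within-state noise", {
  ds0 <- generate_site_distance_dataset(
    hexamer_state_spec("deoxy", noise_sd = 0, seed = 1L),
    hexamer_state_spec("oxy", noise_sd = 0, seed = 2L),
    frames_per_state = 4L, seed = 1L)
  a <- which(ds0$labels == "a"); b <- which(ds0$labels == "b")
  # zero noise: mode amplitude is the only within-state variation
  within <- norm(ds0$matrices[a[1], , ] - ds0$matrices[a[2], , ], "F")
  between <- norm(ds0$matrices[a[1], , ] - ds0$matrices[b[1], , ], "F")
  expect_gt(between, within)
  expect_gt(between, 0)
  # empty dataset contract
  dse <- generate_site_distance_dataset(
    hexamer_state_spec("deoxy"), hexamer_state_spec("oxy"),
    frames_per_state = 0L)
  expect_equal(dim(dse$matrices)[1], 0L)
})

test_that("larger mode amplitude concentrates more variance in mode 1", {
  v1share <- function(amp) {
    tr <- generate_hexamer_trajectory(
      synthetic_spec(mode = "ring_counter_rotation", mode_amplitude = amp,
                     noise_sd = 0.05, n_frames = 30L, seed = 5L))
    p <- fit_pca(tr, n_modes = 2L)
    p$values[1] / sum(p$values)
  }
  expect_gt(v1share(6), v1share(1.5))
})
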