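test_that("Kabsch recovers exact rigid motions", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  self <- kabsch_superpose(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  y <- x %*% t(R) + rep(c(1, 2, 3), each = 10)
  fit <- kabsch_superpose(y, x)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches a dense rotation-grid search oracle", {
  set.seed(2)
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(a, b)
  # oracle: centered RMSD minimised over a dense grid of rotations
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  gr <- seq(0, 2 * pi, length.out = 25L)
  gb <- seq(0, pi, length.out = 13L)
  best <- Inf
  for (al in gr) for (be in gb) for (ga in gr) {
    Rz1 <- matrix(c(cos(al), sin(al), 0, -sin(al), cos(al), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(be), 0, -sin(be), 0, 1, 0, sin(be), 0, cos(be)), 3, 3)
    Rz2 <- matrix(c(cos(ga), sin(ga), 0, -sin(ga), cos(ga), 0, 0, 0, 1), 3, 3)
    r <- sqrt(mean(rowSums((ac %*% t(Rz2 %*% Ry %*% Rz1) - bc)^2)))
    if (r < best) best <- r
  }
  expect_lte(fit$rmsd, best)          # Kabsch is the true minimum
  expect_lt(best - fit$rmsd, 0.05)    # grid resolution gap
  expect_error(kabsch_superpose(a[1:2, ], b[1:2, ]), "3 atoms")
  coll <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(coll, coll), "collinear")
})

test_that("conventional RMSD removes rigid motion and matches expectation", {
  tr <- generate_hexamer_trajectory(
    synthetic_spec(mode = "rigid", noise_sd = 0, n_frames = 4L))
  expect_lt(max(conventional_rmsd(tr)), 1e-12)
  # pure translation of one frame gives zero
  co <- tr$coords
  co[2, , ] <- co[2, , ] + rep(c(5, -3, 2), each = n_atoms(tr))
  expect_lt(max(conventional_rmsd(trajectory(co, tr$topology))), 1e-10)
  # Monte-Carlo expectation: noisy rigid trajectory, both frames noisy
  trn <- generate_hexamer_trajectory(
    synthetic_spec(mode = "rigid", noise_sd = 0.5, n_frames = 300L,
                   seed = 9L))
  r <- conventional_rmsd(trn)
  expect_equal(mean(r[-1]), sqrt(6) * 0.5, tolerance = 0.05)
})

test_that("RMSD is invariant under a global rigid motion of all frames", {
  tr <- fx_deoxy()
  r0 <- conventional_rmsd(tr)
  th <- 0.7
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  co <- tr$coords
  for (t in seq_len(n_frames(tr)))
    co[t, , ] <- co[t, , ] %*% t(R) + rep(c(10, -4, 6), each = n_atoms(tr))
  expect_equal(conventional_rmsd(trajectory(co, tr$topology)), r0,
               tolerance = 1e-8)
})

test_that("core alignment recovers a planted rigid core", {
  pl <- fx_planted_core()
  ca <- core_align(pl$traj, fraction = 0.7)
  expect_equal(length(ca$core), round(0.7 * n_atoms(pl$traj)))
  expect_gte(mean(ca$core %in% pl$rigid), 0.95)
  # core rmsd at the planted noise scale, far below the mobile noise
  expect_lt(mean(ca$core_rmsd), 3 * 0.1)
  expect_gt(mean(ca$noncore_rmsd), mean(ca$core_rmsd))
})

test_that("core alignment degenerates to conventional RMSD at fraction 1", {
  pl <- fx_planted_core()
  c1 <- core_align(pl$traj, fraction = 1)
  expect_equal(c1$core_rmsd, conventional_rmsd(pl$traj), tolerance = 1e-12)
  expect_error(core_align(pl$traj, fraction = 0), "fraction")
})

test_that("core RMSD is non-increasing in the core fraction", {
  pl <- fx_planted_core()
  m <- vapply(c(0.5, 0.7, 1), function(f)
    mean(core_align(pl$traj, fraction = f)$core_rmsd), numeric(1))
  expect_true(all(diff(m) >= -1e-12))
})

test_that("rigid trajectories converge immediately with zero core RMSD", {
  tr <- generate_hexamer_trajectory(
    synthetic_spec(mode = "rigid", noise_sd = 0, n_frames = 4L))
  ca <- core_align(tr, fraction = 0.6)
  expect_lt(max(ca$core_rmsd), 1e-12)
  expect_equal(ca$iterations, 1L)
  expect_true(ca$converged)
})

test_that("RMSF matches its analytic expectation and construction", {
  tr <- generate_hexamer_trajectory(
    synthetic_spec(mode = "rigid", noise_sd = 0, n_frames = 4L))
  expect_lt(max(rmsf(tr)), 1e-12)
  # isotropic noise sd 0.5: RMSF ~ sigma * sqrt(3)
  trn <- generate_hexamer_trajectory(
    synthetic_spec(mode = "rigid", noise_sd = 0.5, n_frames = 500L,
                   seed = 9L))
  expect_equal(mean(rmsf(trn)), 0.5 * sqrt(3), tolerance = 0.05)
  # planted mobile atoms fluctuate strictly more than the rigid core
  pl <- fx_planted_core()
  f <- rmsf(pl$traj)
  expect_gt(min(f[pl$mobile]), max(f[pl$rigid]))
  expect_error(rmsf(traj_select(pl$traj, frames = 1L)), "single frame")
})

test_that("RMSF sum rule ties into the PCA eigenvalue trace", {
  tr <- fx_deoxy()
  atoms <- seq_len(n_atoms(tr))
  f <- rmsf(tr, atoms = atoms)
  p <- fit_pca(tr, atoms = atoms, n_modes = 2L)
  expect_equal(sum(f^2), sum(p$values), tolerance = 1e-10)
})

test_that("radius of gyration reproduces closed forms", {
  top2 <- topology(rep("CA", 2), 0:1, rep("ALA", 2), rep("A", 2))
  tr2 <- trajectory(matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE), top2)
  expect_equal(radius_of_gyration(tr2), 2)                 # d/2
  top1 <- topology("CA", 0L, "ALA", "A")
  tr1 <- trajectory(matrix(c(5, 5, 5), 1, 3), top1)
  expect_equal(radius_of_gyration(tr1), 0)                 # single atom
  # uniform solid sphere: Rg -> R sqrt(3/5)
  with_seed(3L, {
    n <- 1e5
    u <- matrix(rnorm(n * 3), n, 3)
    u <- u / sqrt(rowSums(u^2)) * stats::runif(n)^(1 / 3) * 10
    trs <- trajectory(array(u, c(1, n, 3)),
                      topology(rep("CA", n), seq_len(n) - 1L,
                               rep("ALA", n), rep("A", n)))
    expect_equal(radius_of_gyration(trs), 10 * sqrt(3 / 5), tolerance = 0.02)
  })
})
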