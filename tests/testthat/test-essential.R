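test_that("a single planted mode is recovered exactly", {
  sp <- synthetic_spec(mode = "custom", mode_amplitude = 1, noise_sd = 0,
                       n_frames = 24L)
  nat <- 6L * 68L
  u <- with_seed(2L, matrix(rnorm(nat * 3), nat, 3))
  u <- u / sqrt(sum(u^2))
  sp$custom_mode <- u
  tr <- generate_hexamer_trajectory(sp)
  p <- fit_pca(tr, atoms = seq_len(nat), align_first = FALSE)
  expect_gte(p$values[1] / sum(p$values), 0.999)
  v1 <- matrix(p$vectors[, 1], ncol = 3, byrow = TRUE)
  expect_gt(abs(sum(v1 * u)), 0.999)
})

test_that("rigid trajectories have an all-zero spectrum", {
  tr <- generate_hexamer_trajectory(
    synthetic_spec(mode = "rigid", noise_sd = 0, n_frames = 4L))
  p <- fit_pca(tr, n_modes = 2L)
  expect_lt(max(p$values), 1e-12)
})

test_that("the decomposition matches a brute-force covariance oracle", {
  set.seed(3)
  nf <- 60L; n <- 8L
  co <- array(rnorm(nf * n * 3), c(nf, n, 3))
  p <- fit_pca(bare_traj(co), atoms = 1:n, align_first = FALSE,
               n_modes = 3 * n)
  # naive covariance: explicit loops over coordinate pairs
  X <- matrix(NA_real_, nf, 3 * n)
  for (k in 1:3) X[, seq(k, 3 * n, by = 3)] <- co[, , k]
  mu <- colMeans(X)
  C <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(3 * n)) for (b in seq_len(3 * n))
    C[a, b] <- mean((X[, a] - mu[a]) * (X[, b] - mu[b]))
  ev <- eigen(C, symmetric = TRUE)$values
  expect_equal(p$values, pmax(ev, 0), tolerance = 1e-10)
  expect_equal(sum(p$values), sum(diag(C)), tolerance = 1e-10)
  # orthonormality and projection-variance identity
  G <- crossprod(p$vectors)
  expect_equal(G, diag(3 * n), tolerance = 1e-8)
  pv <- apply(p$projections, 2, function(x) mean((x - mean(x))^2))
  expect_equal(pv, p$values[seq_along(pv)], tolerance = 1e-8)
})

test_that("subspace comparison has the right fixed points", {
  tr <- fx_deoxy()
  p <- fit_pca(tr)
  self <- compare_subspaces(p, p, k = 6L)
  expect_equal(self$rmsip, 1, tolerance = 1e-10)
  expect_equal(self$dot_matrix, diag(6), tolerance = 1e-8)
  expect_equal(self$average_max_dot, 1, tolerance = 1e-8)
  # orthogonal planted subspaces give rmsip 0
  D <- 12L
  a <- p; b <- p
  a$vectors <- diag(D)[, 1:6]; a$values <- rep(1, 6)
  b$vectors <- diag(D)[, 7:12]; b$values <- rep(1, 6)
  expect_equal(compare_subspaces(a, b, k = 6L)$rmsip, 0)
})

test_that("rmsip is symmetric and random subspaces match sqrt(k/D)", {
  tr <- fx_deoxy(); to <- fx_oxy()
  pa <- fit_pca(tr); pb <- fit_pca(to)
  expect_equal(compare_subspaces(pa, pb, 10L)$rmsip,
               compare_subspaces(pb, pa, 10L)$rmsip, tolerance = 1e-12)
  D <- 180L; k <- 10L
  vals <- vapply(1:40, function(s) with_seed(s, {
    A <- qr.Q(qr(matrix(rnorm(D * k), D, k)))
    B <- qr.Q(qr(matrix(rnorm(D * k), D, k)))
    sqrt(sum(crossprod(A, B)^2) / k)
  }), numeric(1))
  expect_equal(mean(vals), sqrt(k / D), tolerance = 0.15)
})

test_that("different planted modes overlap less than same-mode replicas", {
  fit_state <- function(state, seed) fit_pca(generate_hexamer_trajectory(
    hexamer_state_spec(state, n_frames = 24L, seed = seed)))
  pd1 <- fit_state("deoxy", 21L)
  pd2 <- fit_state("deoxy", 22L)
  po <- fit_state("oxy", 23L)
  k <- 5L
  cross <- compare_subspaces(pd1, po, k)$rmsip
  replica <- compare_subspaces(pd1, pd2, k)$rmsip
  expect_gt(replica, cross)
})

test_that("porcupine vectors follow the planted rotation geometry", {
  tr <- generate_hexamer_trajectory(
    synthetic_spec(mode = "ring_counter_rotation", mode_amplitude = 4,
                   noise_sd = 0, n_frames = 24L))
  cas <- atom_select(tr, name = "CA")
  p <- fit_pca(tr, atoms = cas)
  expect_equal(porcupine(p, 1L, scale = 0),
               matrix(0, length(cas), 3))
  arrows <- porcupine(p, 1L, scale = 2)
  expect_equal(sum(arrows^2), 4 * p$values[1], tolerance = 1e-8)
  # tangential field: z-component of (r x arrow) has a consistent sign
  # within each ring and opposite signs across rings
  top <- which(cas %in% atom_select(tr, ring = "top", name = "CA"))
  bot <- which(cas %in% atom_select(tr, ring = "bottom", name = "CA"))
  cz <- function(idx) {
    r <- p$mean[idx, , drop = FALSE]; a <- arrows[idx, , drop = FALSE]
    r[, 1] * a[, 2] - r[, 2] * a[, 1]
  }
  expect_gt(mean(sign(cz(top)) == sign(cz(top))[1]), 0.97)
  expect_gt(mean(sign(cz(bot)) == -sign(cz(top))[1]), 0.97)
  expect_error(porcupine(p, 10^6), "no such mode")
})

test_that("combined fits share one subspace across both states", {
  comb <- fit_pca_combined(fx_deoxy(), fx_oxy())
  fr <- attr(comb, "frames")
  expect_equal(length(fr$a) + length(fr$b), nrow(comb$projections))
})
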