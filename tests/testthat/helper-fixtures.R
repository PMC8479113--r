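# Shared fixtures, built once per test run and memoised.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- maker()
  .fx_env[[name]]
}

fx_deoxy <- function() fx("deoxy", function()
  generate_hexamer_trajectory(hexamer_state_spec("deoxy", n_frames = 24L,
                                                 seed = 11L)))

fx_oxy <- function() fx("oxy", function()
  generate_hexamer_trajectory(hexamer_state_spec("oxy", n_frames = 24L,
                                                 seed = 12L)))

# a trajectory with a planted rigid core (fraction `frac`) and independently
# noisy mobile atoms, with the two sets interleaved by a seeded permutation
fx_planted_core <- function(n = 200L, nf = 40L, frac = 0.7,
                            sd_core = 0.1, sd_mobile = 3, seed = 7L) {
  with_seed(seed, {
    base <- matrix(stats::rnorm(n * 3), n, 3) * 8
    perm <- sample.int(n)
    rigid <- perm[seq_len(round(frac * n))]
    mobile <- setdiff(seq_len(n), rigid)
    co <- array(0, c(nf, n, 3))
    for (t in seq_len(nf)) {
      x <- base
      x[rigid, ] <- x[rigid, ] +
        matrix(stats::rnorm(length(rigid) * 3, sd = sd_core), ncol = 3)
      x[mobile, ] <- x[mobile, ] +
        matrix(stats::rnorm(length(mobile) * 3, sd = sd_mobile), ncol = 3)
      co[t, , ] <- x
    }
    tr <- trajectory(co, topology(rep("CA", n), seq_len(n) - 1L,
                                  rep("ALA", n), rep("A", n)))
    list(traj = tr, rigid = sort(rigid), mobile = sort(mobile))
  })
}

# small bare trajectory from an explicit coordinate array
bare_traj <- function(co) {
  n <- dim(co)[2]
  trajectory(co, topology(rep("CA", n), seq_len(n) - 1L,
                          rep("ALA", n), rep("A", n)))
}

# naive double-loop cross-correlation oracle (deliberately unvectorised)
naive_dccm <- function(co) {
  nf <- dim(co)[1]; n <- dim(co)[2]
  avg <- apply(co, c(2, 3), mean)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0
    for (t in seq_len(nf))
      num <- num + sum((co[t, i, ] - avg[i, ]) * (co[t, j, ] - avg[j, ]))
    di <- dj <- 0
    for (t in seq_len(nf)) {
      di <- di + sum((co[t, i, ] - avg[i, ])^2)
      dj <- dj + sum((co[t, j, ] - avg[j, ])^2)
    }
    M[i, j] <- (num / nf) / sqrt(di / nf * dj / nf)
  }
  M
}

# Bellman-Ford single-source shortest paths (edge-list relaxation oracle)
bellman_ford <- function(n_nodes, from, to, w, src) {
  d <- rep(Inf, n_nodes); d[src] <- 0
  ff <- c(from, to); tt <- c(to, from); ww <- c(w, w)
  for (it in seq_len(n_nodes)) {
    nd <- pmin(d, unname(tapply(d[ff] + ww, tt, min)[as.character(seq_len(n_nodes))]))
    nd[is.na(nd)] <- d[is.na(nd)]
    if (max(abs(nd - d), na.rm = TRUE) == 0) break
    d <- nd
  }
  d
}
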