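#' Essential dynamics: PCA of coordinate fluctuations
#'
#' Eigendecomposition of the 3n x 3n covariance of the (optionally
#' superposed) coordinates. The covariance uses the population divisor
#' (1/T), so the eigenvalue sum equals the trace of the displacement
#' covariance and hence the RMSF sum rule
#' `sum_i RMSF_i^2 = sum_m lambda_m` holds exactly.
#'
#' @param traj an `hxd_trajectory` with at least 2 frames.
#' @param atoms atom mask (default: `CA` atoms if present, else all).
#' @param align_first iteratively superpose frames on the mean structure
#'   (2 rounds) before the decomposition.
#' @param n_modes number of modes for which projections are stored
#'   (default `min(20, 3n)`); all eigenvectors are kept.
#' @return object of class `hxd_pca`: `mean` (n x 3), `vectors`
#'   (3n x 3n, orthonormal columns, descending eigenvalue order),
#'   `values` (Angstrom^2, non-negative), `projections` (T x n_modes),
#'   `atoms`.
#' @export
fit_pca <- function(traj, atoms = NULL, align_first = TRUE, n_modes = NULL) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  if (is.null(atoms)) {
    atoms <- atom_select(traj, name = "CA")
    if (length(atoms) == 0L) atoms <- seq_len(n_atoms(traj))
  }
  if (is.logical(atoms)) atoms <- which(atoms)
  sub <- traj_select(traj, atoms = atoms)
  if (align_first) sub <- align_trajectory(sub, "mean")
  nf <- n_frames(sub); n <- n_atoms(sub)
  # T x 3n matrix, coordinate-major per atom: (x1,y1,z1,x2,...)
  X <- matrix(NA_real_, nf, 3L * n)
  for (k in 1:3) X[, seq(k, 3L * n, by = 3L)] <- sub$coords[, , k]
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / nf
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  if (is.null(n_modes)) n_modes <- min(20L, 3L * n)
  n_modes <- min(n_modes, 3L * n)
  proj <- Xc %*% eg$vectors[, seq_len(n_modes), drop = FALSE]
  mean_structure <- matrix(mu, ncol = 3L, byrow = TRUE)
  structure(list(mean = mean_structure, vectors = eg$vectors,
                 values = vals, projections = proj, atoms = atoms,
                 n_frames = nf),
            class = "hxd_pca")
}

#' @export
print.hxd_pca <- function(x, ...) {
  tot <- sum(x$values)
  cat(sprintf("<hxd_pca> %d modes; top-3 variance share %.1f%% / %.1f%% / %.1f%%\n",
              length(x$values),
              100 * x$values[1] / tot, 100 * x$values[2] / tot,
              100 * x$values[3] / tot))
  invisible(x)
}

#' Compare two essential-dynamics subspaces
#'
#' Builds the k x k matrix of absolute eigenvector inner products
#' `|v_i . w_j|` and summarizes it as the root mean square inner product
#' \deqn{RMSIP = \sqrt{\frac{1}{k}\sum_{i=1}^k\sum_{j=1}^k (v_i\cdot w_j)^2}}
#' (in \[0, 1\]; 1 for identical subspaces, ~sqrt(k/3n) for random ones)
#' and the average maximum dot product (mean over rows of the row maximum).
#' The subspace overlap is reported as RMSIP x 100%.
#'
#' @param a,b `hxd_pca` objects fitted on the same atom mask and ordering.
#' @param k number of top modes to compare (default 10).
#' @return object of class `hxd_subspace`: `dot_matrix`, `rmsip`,
#'   `overlap_pct`, `average_max_dot`, `k`.
#' @export
compare_subspaces <- function(a, b, k = 10L) {
  if (nrow(a$vectors) != nrow(b$vectors))
    stop("subspace dimension mismatch between the two fits")
  k <- min(k, ncol(a$vectors), ncol(b$vectors))
  V <- a$vectors[, seq_len(k), drop = FALSE]
  W <- b$vectors[, seq_len(k), drop = FALSE]
  dots <- crossprod(V, W)
  rmsip <- sqrt(sum(dots^2) / k)
  structure(list(dot_matrix = abs(dots), rmsip = rmsip,
                 overlap_pct = 100 * rmsip,
                 average_max_dot = mean(apply(abs(dots), 1L, max)),
                 k = k),
            class = "hxd_subspace")
}

#' @export
print.hxd_subspace <- function(x, ...) {
  cat(sprintf(paste0("<hxd_subspace> k = %d; RMSIP %.3f ",
                     "(subspace overlap %.1f%%), average max dot %.2f\n"),
              x$k, x$rmsip, x$overlap_pct, x$average_max_dot))
  invisible(x)
}

#' Porcupine displacement field of one mode
#'
#' Per-atom 3-vectors of the chosen eigenvector scaled by
#' `scale * sqrt(eigenvalue)` — the arrows of a porcupine plot.
#'
#' @param modes an `hxd_pca`.
#' @param mode mode index (1 = dominant).
#' @param scale scalar multiplier.
#' @return `n x 3` matrix of displacement vectors; the squared norms sum
#'   to `scale^2 * eigenvalue`.
#' @export
porcupine <- function(modes, mode = 1L, scale = 1) {
  if (mode < 1L || mode > length(modes$values)) stop("no such mode")
  v <- modes$vectors[, mode]
  matrix(v, ncol = 3L, byrow = TRUE) * scale * sqrt(modes$values[mode])
}

#' Fit combined-trajectory essential dynamics
#'
#' Concatenates two trajectories (same atoms) so both share one subspace,
#' then fits the PCA; per-state projections can be recovered from the
#' returned frame ranges.
#'
#' @param a,b `hxd_trajectory`s with identical atom counts.
#' @param ... passed to [fit_pca()].
#' @return an `hxd_pca` with attribute `"frames"` (list of per-state frame
#'   index ranges).
#' @export
fit_pca_combined <- function(a, b, ...) {
  if (n_atoms(a) != n_atoms(b)) stop("atom count mismatch")
  coords <- array(NA_real_, dim = c(n_frames(a) + n_frames(b), n_atoms(a), 3L))
  coords[seq_len(n_frames(a)), , ] <- a$coords
  coords[n_frames(a) + seq_len(n_frames(b)), , ] <- b$coords
  comb <- trajectory(coords, a$topology)
  fit <- fit_pca(comb, ...)
  attr(fit, "frames") <- list(a = seq_len(n_frames(a)),
                              b = n_frames(a) + seq_len(n_frames(b)))
  fit
}
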