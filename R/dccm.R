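#' Dynamic cross-correlation matrix of displacement vectors
#'
#' For atoms i, j with displacements `dr_i(t) = r_i(t) - <r_i>` the
#' cross-correlation is the normalized scalar product
#' \deqn{\sigma_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle}},}
#' the ensemble average running over frames. Values lie in \[-1, 1\]:
#' +1 for perfectly parallel, -1 for antiparallel motions. The 3-vectors
#' are dotted (scalar-product correlation), not correlated per axis.
#'
#' Frames are superposed on the mean structure first by default; without
#' alignment any global rigid-body drift dominates the map.
#'
#' Atoms with zero fluctuation get their row/column set to 0 (diagonal 1)
#' with a warning, avoiding NaN propagation.
#'
#' @param traj an `hxd_trajectory` with at least 2 frames.
#' @param atoms atom mask (default: `CA` atoms if present, else all).
#' @param align_first superpose frames on the mean structure first.
#' @return object of class `hxd_dccm`: `values` (n x n, symmetric, unit
#'   diagonal), `atom_map` (matrix row -> atom index in `traj`).
#' @export
compute_dccm <- function(traj, atoms = NULL, align_first = TRUE) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  if (is.null(atoms)) {
    atoms <- atom_select(traj, name = "CA")
    if (length(atoms) == 0L) atoms <- seq_len(n_atoms(traj))
  }
  if (is.logical(atoms)) atoms <- which(atoms)
  sub <- traj_select(traj, atoms = atoms)
  if (align_first) sub <- align_trajectory(sub, "mean")
  nf <- n_frames(sub); n <- n_atoms(sub)
  avg <- colMeans(sub$coords, dims = 1L)
  num <- matrix(0, n, n)
  for (k in 1:3) {
    d <- sub$coords[, , k] - rep(avg[, k], each = nf)
    num <- num + crossprod(d) / nf
  }
  amp <- sqrt(diag(num))
  zero <- amp < 1e-12
  if (any(zero))
    warning(sum(zero), " atom(s) with zero fluctuation; ",
            "their correlations are set to 0")
  amp[zero] <- 1
  vals <- num / tcrossprod(amp)
  vals[zero, ] <- 0; vals[, zero] <- 0
  diag(vals) <- 1
  vals[vals > 1] <- 1; vals[vals < -1] <- -1
  structure(list(values = vals, atom_map = atoms),
            class = "hxd_dccm")
}

#' @export
print.hxd_dccm <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<hxd_dccm> %d x %d; off-diagonal range [%.3f, %.3f]\n",
              n, n, min(off), max(off)))
  invisible(x)
}

#' Mean cross-correlation per block pair
#'
#' Averages the matrix over blocks of rows/columns (e.g. domains or
#' subunits), excluding the matrix diagonal. `ranges` must partition the
#' rows without overlap.
#'
#' @param m an `hxd_dccm` or a plain symmetric matrix.
#' @param ranges named list of integer row index vectors, or a
#'   `data.frame` with columns `name`, `from`, `to` (1-based, inclusive).
#' @return matrix of block-pair mean correlations, blocks in rows/columns.
#' @export
dccm_block_summary <- function(m, ranges) {
  vals <- if (inherits(m, "hxd_dccm")) m$values else m
  if (is.data.frame(ranges)) {
    ranges <- stats::setNames(
      lapply(seq_len(nrow(ranges)), function(i) ranges$from[i]:ranges$to[i]),
      ranges$name)
  }
  all_idx <- unlist(ranges)
  if (anyDuplicated(all_idx)) stop("ranges overlap")
  if (any(all_idx < 1L | all_idx > nrow(vals))) stop("range out of bounds")
  nb <- length(ranges)
  out <- matrix(NA_real_, nb, nb,
                dimnames = list(names(ranges), names(ranges)))
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    block <- vals[ranges[[a]], ranges[[b]], drop = FALSE]
    if (a == b) {
      keep <- upper.tri(block) | lower.tri(block)
      out[a, b] <- if (any(keep)) mean(block[keep]) else 0
    } else out[a, b] <- mean(block)
  }
  out
}
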