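#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' of `mobile` onto `reference` over the masked atoms.
#'
#' @param mobile,reference `n x 3` coordinate matrices with atom
#'   correspondence.
#' @param mask integer or logical atom mask used for the fit (default all).
#' @return list with `rotation` (3x3), `translation` (length 3; the fitted
#'   transform is `x %*% t(R) + t`), and `rmsd` over the masked atoms.
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  if (is.null(mask)) mask <- seq_len(nrow(mobile))
  if (is.logical(mask)) mask <- which(mask)
  m <- mobile[mask, , drop = FALSE]
  r <- reference[mask, , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 atoms to superpose")
  mc <- colMeans(m); rc <- colMeans(r)
  m0 <- sweep(m, 2L, mc); r0 <- sweep(r, 2L, rc)
  sv <- svd(crossprod(m0, r0))
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2L)
    stop("masked atoms are collinear; superposition is degenerate")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- rc - as.vector(R %*% mc)
  fitted <- m %*% t(R) + rep(t_vec, each = nrow(m))
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

.apply_fit <- function(x, fit) {
  x %*% t(fit$rotation) + rep(fit$translation, each = nrow(x))
}

#' Superpose every frame of a trajectory
#'
#' Fits each frame onto a reference over `fit_atoms`; the transform is
#' applied to all atoms. `reference = "mean"` iterates fit-to-mean rounds
#' (default 2), the usual essential-dynamics pretreatment.
#'
#' @param traj an `hxd_trajectory`.
#' @param reference a frame index, an `n_atoms x 3` matrix, or `"mean"`.
#' @param fit_atoms atoms used in the fit (default all).
#' @param mean_rounds iterations of the fit-to-mean cycle.
#' @return an `hxd_trajectory` with superposed coordinates.
#' @export
align_trajectory <- function(traj, reference = "mean", fit_atoms = NULL,
                             mean_rounds = 2L) {
  nf <- n_frames(traj)
  coords <- traj$coords
  if (is.null(fit_atoms)) fit_atoms <- seq_len(n_atoms(traj))
  fit_all <- function(coords, ref) {
    for (t in seq_len(nf)) {
      f <- kabsch_superpose(coords[t, , ], ref, mask = fit_atoms)
      coords[t, , ] <- .apply_fit(coords[t, , ], f)
    }
    coords
  }
  if (identical(reference, "mean")) {
    ref <- frame_coords(traj, 1L)
    for (it in seq_len(mean_rounds)) {
      coords <- fit_all(coords, ref)
      ref <- colMeans(coords, dims = 1L)
      dim(ref) <- c(n_atoms(traj), 3L)
    }
  } else {
    ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
    coords <- fit_all(coords, ref)
  }
  out <- traj
  out$coords <- coords
  out
}

#' Conventional per-frame RMSD
#'
#' Each frame is superposed on the reference frame over `atoms` and the
#' RMSD is reported over the same atoms.
#'
#' @param traj an `hxd_trajectory`.
#' @param ref_frame reference frame index (default 1).
#' @param atoms atom mask (indices or logical; default all).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
conventional_rmsd <- function(traj, ref_frame = 1L, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(n_atoms(traj))
  if (is.logical(atoms)) atoms <- which(atoms)
  ref <- frame_coords(traj, ref_frame)
  vapply(seq_len(n_frames(traj)), function(t) {
    kabsch_superpose(frame_coords(traj, t), ref, mask = atoms)$rmsd
  }, numeric(1))
}

#' Robust fraction-based core alignment
#'
#' Iteratively aligns the trajectory on the fraction `fraction` of atoms
#' displaying the smallest displacements: align on the current core,
#' rank atoms by their mean displacement from the trajectory-average
#' structure, re-select the `fraction` with the smallest displacement,
#' and repeat until the core set is fixed, the core RMSD changes by less
#' than `tol`, or `max_iter` is reached. `fraction = 1` reduces exactly to
#' [conventional_rmsd()].
#'
#' @param traj an `hxd_trajectory`.
#' @param fraction core fraction in (0, 1].
#' @param ref_frame reference frame for the reported per-frame RMSD.
#' @param atoms atom mask restricting the analysis (default all).
#' @param max_iter,tol convergence controls.
#' @return object of class `hxd_core_align`: `core` (atom indices, within
#'   `atoms`), `core_rmsd` and `noncore_rmsd` per frame, `iterations`,
#'   `converged`, `fraction`.
#' @export
core_align <- function(traj, fraction = 0.7, ref_frame = 1L, atoms = NULL,
                       max_iter = 100L, tol = 1e-4) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(atoms)) atoms <- seq_len(n_atoms(traj))
  if (is.logical(atoms)) atoms <- which(atoms)
  sub <- traj_select(traj, atoms = atoms)
  n <- n_atoms(sub); nf <- n_frames(sub)
  n_core <- max(3L, round(fraction * n))
  core <- seq_len(n_core)  # deterministic initial core (lowest indices)
  prev_rmsd <- Inf; converged <- FALSE; iters <- 0L
  core_rmsd <- noncore_rmsd <- rep(NA_real_, nf)
  repeat {
    iters <- iters + 1L
    ref <- frame_coords(sub, ref_frame)
    fits <- lapply(seq_len(nf), function(t)
      kabsch_superpose(frame_coords(sub, t), ref, mask = core))
    aligned <- array(NA_real_, dim = dim(sub$coords))
    for (t in seq_len(nf))
      aligned[t, , ] <- .apply_fit(frame_coords(sub, t), fits[[t]])
    avg <- colMeans(aligned, dims = 1L); dim(avg) <- c(n, 3L)
    disp <- sapply(seq_len(nf), function(t)
      sqrt(rowSums((aligned[t, , ] - avg)^2)))
    mean_disp <- rowMeans(disp)
    # rank by mean displacement; deterministic tie-break by atom index
    new_core <- order(mean_disp, seq_len(n))[seq_len(n_core)]
    new_core <- sort(new_core)
    refm <- aligned[ref_frame, , ]
    core_rmsd <- vapply(seq_len(nf), function(t) {
      al <- aligned[t, , ]
      sqrt(mean(rowSums((al[new_core, , drop = FALSE] -
                           refm[new_core, , drop = FALSE])^2)))
    }, numeric(1))
    cur <- mean(core_rmsd)
    if (identical(new_core, core) || abs(prev_rmsd - cur) < tol) {
      core <- new_core; converged <- TRUE; break
    }
    if (iters >= max_iter) { core <- new_core; break }
    core <- new_core; prev_rmsd <- cur
  }
  # re-fit on the final core so the reported RMSD split matches the final mask
  refc <- frame_coords(sub, ref_frame)
  nc <- setdiff(seq_len(n), core)
  for (t in seq_len(nf)) {
    f <- kabsch_superpose(frame_coords(sub, t), refc, mask = core)
    core_rmsd[t] <- f$rmsd
    if (length(nc)) {
      fitted <- .apply_fit(frame_coords(sub, t), f)
      noncore_rmsd[t] <- sqrt(mean(rowSums(
        (fitted[nc, , drop = FALSE] - refc[nc, , drop = FALSE])^2)))
    }
  }
  if (!length(nc)) noncore_rmsd <- rep(NA_real_, nf)
  structure(list(core = core, core_rmsd = core_rmsd,
                 noncore_rmsd = noncore_rmsd, iterations = iters,
                 converged = converged, fraction = fraction,
                 atoms = atoms),
            class = "hxd_core_align")
}

#' @export
print.hxd_core_align <- function(x, ...) {
  cat(sprintf(paste0("<hxd_core_align> fraction %.2f (%d core atoms), ",
                     "%d iteration(s)%s\n  mean core RMSD %.3f A"),
              x$fraction, length(x$core), x$iterations,
              if (x$converged) "" else " [not converged]",
              mean(x$core_rmsd)))
  if (!all(is.na(x$noncore_rmsd)))
    cat(sprintf(", mean non-core RMSD %.3f A", mean(x$noncore_rmsd)))
  cat("\n")
  invisible(x)
}

#' Per-atom root mean square fluctuation
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` after superposition on the
#' mean structure.
#'
#' @param traj an `hxd_trajectory` with at least 2 frames.
#' @param atoms atom mask (default all).
#' @param align superpose on the mean structure first (default TRUE).
#' @return numeric vector of per-atom RMSF (Angstrom).
#' @export
rmsf <- function(traj, atoms = NULL, align = TRUE) {
  if (n_frames(traj) < 2L) stop("RMSF is undefined for a single frame")
  if (is.null(atoms)) atoms <- seq_len(n_atoms(traj))
  if (is.logical(atoms)) atoms <- which(atoms)
  sub <- traj_select(traj, atoms = atoms)
  if (align) sub <- align_trajectory(sub, "mean")
  avg <- colMeans(sub$coords, dims = 1L)
  d2 <- sweep(sub$coords, c(2, 3), avg)^2
  sqrt(colMeans(d2[, , 1] + d2[, , 2] + d2[, , 3]))
}

#' Per-frame radius of gyration
#'
#' `Rg(t) = sqrt(sum_i m_i |r_i - r_cm|^2 / sum_i m_i)`; mass weighting is
#' off by default (appropriate for C-alpha-only analyses, where masses are
#' equal).
#'
#' @param traj an `hxd_trajectory`.
#' @param atoms atom mask (default all).
#' @param mass_weighted use topology masses (default FALSE).
#' @return numeric vector, one Rg (Angstrom) per frame.
#' @export
radius_of_gyration <- function(traj, atoms = NULL, mass_weighted = FALSE) {
  if (is.null(atoms)) atoms <- seq_len(n_atoms(traj))
  if (is.logical(atoms)) atoms <- which(atoms)
  w <- if (mass_weighted) traj$topology$mass[atoms] else rep(1, length(atoms))
  w <- w / sum(w)
  vapply(seq_len(n_frames(traj)), function(t) {
    x <- frame_coords(traj, t)[atoms, , drop = FALSE]
    cm <- colSums(x * w)
    sqrt(sum(w * rowSums(sweep(x, 2L, cm)^2)))
  }, numeric(1))
}
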