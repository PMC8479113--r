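#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe ASA by quadrature: for each atom, the fraction of
#' quasi-uniform sphere points at radius `r_i + probe` not inside any
#' neighbour's expanded sphere, times `4*pi*(r_i+probe)^2`. The point set
#' is a deterministic golden-angle spiral lattice, so results are seed-free
#' and reproducible; hydrogens are excluded by default.
#'
#' @param x an `hxd_trajectory` (first frame used), an `hxd_toy_geometry`,
#'   or an `n x 3` coordinate matrix.
#' @param radii per-atom van der Waals radii; taken from the topology when
#'   `x` carries one.
#' @param atoms atom mask (default: all non-hydrogen atoms).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (>= 50; default 960).
#' @param frame frame to evaluate when `x` is a trajectory.
#' @param include_h include hydrogens (default FALSE).
#' @return object of class `hxd_surface`: `per_atom` ASA (Angstrom^2, zero
#'   for unselected atoms), `total`, `probe`, `n_points`.
#' @export
sasa <- function(x, radii = NULL, atoms = NULL, probe = 1.4, n_points = 960L,
                 frame = 1L, include_h = FALSE) {
  if (probe <= 0) stop("probe radius must be positive")
  if (n_points < 50L) stop("need at least 50 quadrature points")
  cr <- .coords_radii(x, radii, frame)
  coords <- cr$coords; radii <- cr$radii
  n <- nrow(coords)
  if (is.null(atoms)) {
    atoms <- seq_len(n)
    if (!include_h && !is.null(cr$element))
      atoms <- atoms[cr$element != "H"]
  }
  if (is.logical(atoms)) atoms <- which(atoms)
  dirs <- golden_spiral_points(n_points)
  per_atom <- numeric(n)
  sub <- coords[atoms, , drop = FALSE]
  subr <- radii[atoms]
  nn <- length(atoms)
  # neighbour lists from the pairwise distances of the selected set
  d2 <- as.matrix(stats::dist(sub))^2
  for (ii in seq_len(nn)) {
    ri <- subr[ii] + probe
    cutoff2 <- (ri + subr + probe)^2
    nb <- which(d2[ii, ] < cutoff2 & seq_len(nn) != ii)
    if (length(nb) == 0L) {
      per_atom[atoms[ii]] <- 4 * pi * ri^2
      next
    }
    pts <- dirs * ri
    pts <- sweep(pts, 2L, sub[ii, ], `+`)
    free <- rep(TRUE, n_points)
    for (jj in nb) {
      rj2 <- (subr[jj] + probe)^2
      dx <- pts[, 1] - sub[jj, 1]
      dy <- pts[, 2] - sub[jj, 2]
      dz <- pts[, 3] - sub[jj, 3]
      free <- free & (dx * dx + dy * dy + dz * dz > rj2)
      if (!any(free)) break
    }
    per_atom[atoms[ii]] <- 4 * pi * ri^2 * mean(free)
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe = probe, n_points = n_points),
            class = "hxd_surface")
}

#' @export
print.hxd_surface <- function(x, ...) {
  cat(sprintf("<hxd_surface> total ASA %.2f A^2 (probe %.2f A, %d points)\n",
              x$total, x$probe, x$n_points))
  invisible(x)
}

.coords_radii <- function(x, radii, frame = 1L) {
  if (inherits(x, "hxd_trajectory")) {
    list(coords = frame_coords(x, frame), radii = x$topology$vdw_radius,
         element = element_of(x$topology$atom_name))
  } else if (inherits(x, "hxd_toy_geometry")) {
    list(coords = x$coords, radii = x$topology$vdw_radius,
         element = element_of(x$topology$atom_name))
  } else {
    if (is.null(radii)) stop("radii required for a bare coordinate matrix")
    list(coords = x, radii = radii, element = NULL)
  }
}

#' Interface-buried accessible surface area
#'
#' The area buried when two groups form a complex:
#' `IASA = ASA(A alone) + ASA(B alone) - ASA(A union B)`.
#' Non-negative by construction (occlusion can only remove quadrature
#' points), and ~0 for groups out of probe reach of each other.
#'
#' @param x trajectory, toy geometry or coordinate matrix (see [sasa()]).
#' @param group_a,group_b disjoint atom index vectors, or chain-id
#'   character vectors when `x` carries a topology.
#' @param radii,probe,n_points as in [sasa()].
#' @param frames frames to evaluate (trajectory input; default all).
#' @return `data.frame` with one row per frame: `frame`, `asa_a`, `asa_b`,
#'   `asa_ab`, `iasa` (Angstrom^2).
#' @export
iasa <- function(x, group_a, group_b, radii = NULL, probe = 1.4,
                 n_points = 960L, frames = NULL) {
  has_top <- inherits(x, "hxd_trajectory") || inherits(x, "hxd_toy_geometry")
  if (is.character(group_a)) {
    if (!has_top) stop("chain-id groups need a topology")
    group_a <- which(x$topology$chain_id %in% group_a)
  }
  if (is.character(group_b)) {
    if (!has_top) stop("chain-id groups need a topology")
    group_b <- which(x$topology$chain_id %in% group_b)
  }
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (inherits(x, "hxd_trajectory")) {
    if (is.null(frames)) frames <- seq_len(n_frames(x))
  } else frames <- 1L
  rows <- lapply(frames, function(t) {
    cr <- .coords_radii(x, radii, t)
    one <- function(idx) {
      sasa(cr$coords[idx, , drop = FALSE], radii = cr$radii[idx],
           probe = probe, n_points = n_points)$total
    }
    aa <- one(group_a); bb <- one(group_b)
    ab <- one(sort(c(group_a, group_b)))
    data.frame(frame = t, asa_a = aa, asa_b = bb, asa_ab = ab,
               iasa = aa + bb - ab)
  })
  do.call(rbind, rows)
}

#' Per-frame SASA series with per-chain decomposition
#'
#' Totals per frame plus per-chain ASA and the per-subunit average (the
#' mean of the chain totals), for trajectory-level surface comparisons.
#'
#' @param traj an `hxd_trajectory`.
#' @param atoms atom mask (default all heavy atoms).
#' @param probe,n_points as in [sasa()].
#' @param frames frames to evaluate (default all).
#' @return `data.frame`: `frame`, `total`, one `asa_<chain>` column per
#'   chain, `subunit_mean`.
#' @export
sasa_series <- function(traj, atoms = NULL, probe = 1.4, n_points = 960L,
                        frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  chains <- unique(traj$topology$chain_id)
  rows <- lapply(frames, function(t) {
    s <- sasa(traj, atoms = atoms, probe = probe, n_points = n_points,
              frame = t)
    per_chain <- vapply(chains, function(ch)
      sum(s$per_atom[traj$topology$chain_id == ch]), numeric(1))
    out <- data.frame(frame = t, total = s$total)
    out[paste0("asa_", chains)] <- as.list(per_chain)
    out$subunit_mean <- mean(per_chain)
    out
  })
  do.call(rbind, rows)
}
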