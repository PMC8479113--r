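#' Grid-based solvent cavity detection over a trajectory
#'
#' A voxel is counted as pocket in a frame iff (a) its clearance — the
#' distance from the voxel center to the nearest atom surface — lies in
#' `[probe_min, probe_max]` (passable by a small molecule but excluded
#' from bulk solvent), and (b) it is buried: of 14 rays (6 axes and 8 cube
#' diagonals) at least `burial_min_rays` hit protein within
#' `burial_cutoff`. Connected components (6-connectivity) smaller than
#' `min_voxels` are discarded. Everything is deterministic: identical
#' inputs give identical grids.
#'
#' @param traj an `hxd_trajectory`.
#' @param atoms atoms considered protein (default all).
#' @param spacing grid spacing in Angstrom, in \[0.4, 1.5\] (default 0.8).
#' @param probe_min,probe_max clearance band (defaults 1.0 and 3.5 A,
#'   mirroring alpha-sphere bounds of pocket-detection practice).
#' @param burial_min_rays rays (of 14) that must be blocked (default 9).
#' @param burial_cutoff ray length in Angstrom (default 12).
#' @param min_voxels minimum connected-component size (default 5).
#' @param grid_bounds optional 3 x 2 matrix (rows x/y/z, columns min/max)
#'   restricting the candidate grid; default: bounding box of the masked
#'   atoms in frame 1 plus a 2 A margin. Burial rays always march through
#'   an occupancy grid covering all atoms, regardless of `grid_bounds`.
#' @param frames frames to analyze (default all).
#' @return object of class `hxd_pocket_grid`: `origin`, `spacing`, `dim`,
#'   `frequency` (3D array of per-voxel opening frequency across the
#'   analyzed frames), `volume` (per-frame pocket volume, Angstrom^3),
#'   `frames`, `cumulative_volume` (union over frames: voxels with
#'   frequency > 0 times spacing^3), `mean_volume`, and the parameters.
#' @export
detect_pockets <- function(traj, atoms = NULL, spacing = 0.8,
                           probe_min = 1.0, probe_max = 3.5,
                           burial_min_rays = 9L, burial_cutoff = 12,
                           min_voxels = 5L, grid_bounds = NULL,
                           frames = NULL) {
  if (spacing < 0.4 || spacing > 1.5) stop("spacing must be in [0.4, 1.5] A")
  if (probe_min >= probe_max) stop("probe_min must be < probe_max")
  if (is.null(atoms)) atoms <- seq_len(n_atoms(traj))
  if (is.logical(atoms)) atoms <- which(atoms)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  radii <- traj$topology$vdw_radius[atoms]
  if (is.null(grid_bounds)) {
    f1 <- frame_coords(traj, frames[1])[atoms, , drop = FALSE]
    grid_bounds <- cbind(apply(f1, 2, min) - 2, apply(f1, 2, max) + 2)
  }
  ax <- lapply(1:3, function(k)
    seq(grid_bounds[k, 1] + spacing / 2, grid_bounds[k, 2], by = spacing))
  nd <- vapply(ax, length, integer(1))
  if (any(nd < 1L)) stop("empty grid: mask or bounds too small")
  vox <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  nv <- nrow(vox)
  counts <- integer(nv)
  volumes <- numeric(length(frames))
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))))
  for (fi in seq_along(frames)) {
    coords <- frame_coords(traj, frames[fi])[atoms, , drop = FALSE]
    clearance <- nearest_clearance(vox, coords, radii)
    cand <- which(clearance >= probe_min & clearance <= probe_max)
    if (length(cand)) {
      occ <- .occupancy_grid(coords, radii, spacing)
      buried <- .burial_count(vox[cand, , drop = FALSE], occ, dirs,
                              burial_cutoff)
      open <- cand[buried >= burial_min_rays]
      open <- .prune_components(open, nd, min_voxels)
    } else open <- integer(0)
    volumes[fi] <- length(open) * spacing^3
    counts[open] <- counts[open] + 1L
  }
  freq <- array(counts / length(frames), dim = nd)
  structure(list(origin = grid_bounds[, 1], spacing = spacing, dim = nd,
                 frequency = freq, volume = volumes, frames = frames,
                 cumulative_volume = sum(counts > 0L) * spacing^3,
                 mean_volume = mean(volumes),
                 params = list(probe_min = probe_min, probe_max = probe_max,
                               burial_min_rays = burial_min_rays,
                               burial_cutoff = burial_cutoff,
                               min_voxels = min_voxels)),
            class = "hxd_pocket_grid")
}

#' @export
print.hxd_pocket_grid <- function(x, ...) {
  cat(sprintf(paste0("<hxd_pocket_grid> %d x %d x %d at %.2f A; ",
                     "mean volume %.1f A^3, cumulative %.1f A^3 over %d frames\n"),
              x$dim[1], x$dim[2], x$dim[3], x$spacing,
              x$mean_volume, x$cumulative_volume, length(x$frames)))
  invisible(x)
}

# occupancy grid over the atom bounding box: voxel centers within the vdW
# sphere of any atom
.occupancy_grid <- function(coords, radii, spacing) {
  lo <- apply(coords, 2, min) - max(radii) - spacing
  hi <- apply(coords, 2, max) + max(radii) + spacing
  ax <- lapply(1:3, function(k) seq(lo[k] + spacing / 2, hi[k], by = spacing))
  nd <- vapply(ax, length, integer(1))
  occ <- array(FALSE, dim = nd)
  maxoff <- ceiling(max(radii) / spacing)
  off <- as.matrix(expand.grid(-maxoff:maxoff, -maxoff:maxoff,
                               -maxoff:maxoff))
  offd2 <- rowSums((off * spacing)^2)
  base <- vapply(1:3, function(k)
    as.integer(round((coords[, k] - ax[[k]][1]) / spacing)) + 1L,
    integer(nrow(coords)))
  if (is.null(dim(base))) dim(base) <- c(nrow(coords), 3L)
  for (r in unique(radii)) {
    at <- which(radii == r)
    keep <- which(offd2 <= r^2 + spacing^2)  # slight inflation seals walls
    na <- length(at); nk <- length(keep)
    idx <- base[rep(at, each = nk), , drop = FALSE] +
      off[rep(keep, times = na), , drop = FALSE]
    ok <- idx[, 1] >= 1L & idx[, 1] <= nd[1] &
          idx[, 2] >= 1L & idx[, 2] <= nd[2] &
          idx[, 3] >= 1L & idx[, 3] <= nd[3]
    occ[idx[ok, , drop = FALSE]] <- TRUE
  }
  list(occ = occ, origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]),
       spacing = spacing, dim = nd)
}

# number of the 14 rays blocked within cutoff, for each query point
.burial_count <- function(pts, occ, dirs, cutoff) {
  nd <- occ$dim
  base <- vapply(1:3, function(k)
    as.integer(round((pts[, k] - occ$origin[k]) / occ$spacing)) + 1L,
    integer(nrow(pts)))
  if (is.null(dim(base))) dim(base) <- c(nrow(pts), 3L)
  nblocked <- integer(nrow(pts))
  for (d in seq_len(nrow(dirs))) {
    dd <- dirs[d, ]
    steplen <- occ$spacing * sqrt(sum(dd^2))
    ksteps <- max(1L, floor(cutoff / steplen))
    hit <- rep(FALSE, nrow(pts))
    for (k in seq_len(ksteps)) {
      ix <- base[, 1] + k * dd[1]
      iy <- base[, 2] + k * dd[2]
      iz <- base[, 3] + k * dd[3]
      inb <- ix >= 1L & ix <= nd[1] & iy >= 1L & iy <= nd[2] &
             iz >= 1L & iz <= nd[3]
      todo <- which(!hit & inb)
      if (!length(todo)) next
      lin <- ix[todo] + (iy[todo] - 1L) * nd[1] +
        (iz[todo] - 1L) * nd[1] * nd[2]
      hit[todo] <- occ$occ[lin]
    }
    nblocked <- nblocked + hit
  }
  nblocked
}

# drop 6-connected components smaller than min_voxels
.prune_components <- function(open, nd, min_voxels) {
  if (length(open) <= 1L) {
    return(if (length(open) < min_voxels) integer(0) else open)
  }
  pos <- arrayInd(open, nd)
  id <- stats::setNames(seq_along(open), open)
  edges <- NULL
  for (k in 1:3) {
    shift <- c(1L, nd[1], nd[1] * nd[2])[k]
    nb <- open + shift
    valid <- pos[, k] < nd[k] & nb %in% open
    if (any(valid))
      edges <- rbind(edges, cbind(id[as.character(open[valid])],
                                  id[as.character(nb[valid])]))
  }
  if (is.null(edges)) {
    return(if (min_voxels <= 1L) open else integer(0))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(open) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep <- which(comp$csize[comp$membership] >= min_voxels)
  sort(open[keep])
}

#' Per-frame and cumulative pocket volume table
#'
#' The cumulative volume over frames is reported under both readings of
#' "cumulative": `cumulative_union` (voxels open in at least one frame,
#' times spacing^3) and `cumulative_sum` (the sum of per-frame volumes);
#' `mean_volume` is the per-frame average.
#'
#' @param g an `hxd_pocket_grid`.
#' @return `data.frame` with columns `frame` and `volume`; attributes
#'   `cumulative_union`, `cumulative_sum`, `mean_volume`.
#' @export
pocket_volume_series <- function(g) {
  stopifnot(inherits(g, "hxd_pocket_grid"))
  out <- data.frame(frame = g$frames, volume = g$volume)
  attr(out, "cumulative_union") <- g$cumulative_volume
  attr(out, "cumulative_sum") <- sum(g$volume)
  attr(out, "mean_volume") <- g$mean_volume
  out
}
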