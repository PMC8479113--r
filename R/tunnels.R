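#' Find tunnels from a buried start point to bulk solvent
#'
#' Builds a 26-connected grid graph over the molecular interior. Node
#' clearance is the distance to the nearest atom surface; admissible nodes
#' have clearance >= `probe_radius`. Edge cost is
#' `step_length * (r_u^-2 + r_v^-2) / 2`, so a path cost is the trapezoidal
#' discretization of the tunnel cost integral `int r(l)^-2 dl`. Lowest-cost
#' paths from the start to exit ("portal") nodes are found by Dijkstra's
#' algorithm; exits are bulk nodes (clearance >= `bulk_threshold`) or
#' admissible grid-hull nodes adjacent to the interior. Each surviving path
#' is truncated at the atom bounding box (the cost is a property of the
#' passage through the structure, not of the approach through bulk),
#' lightly smoothed, and scored:
#' bottleneck = min r(l), cost = trapezoid of r(l)^-2, throughput =
#' exp(-cost).
#'
#' @param x an `hxd_trajectory` or `hxd_toy_geometry`.
#' @param start_point numeric xyz triple, or an integer vector of atom
#'   indices whose centroid is used (e.g. the metal site).
#' @param probe_radius minimum clearance of an admissible node (default
#'   1.0 A).
#' @param spacing grid spacing (default 0.6 A).
#' @param bulk_threshold clearance from which a node counts as bulk
#'   solvent (default 4 A; separates tunnels from surface grooves).
#' @param grid_bounds optional 3 x 2 bounds matrix; default: atom bounding
#'   box plus `bulk_threshold + 2` margin.
#' @param frames frames to analyze (trajectory input; default frame 1).
#' @param atoms atoms considered protein (default all).
#' @param max_tunnels maximum exits pursued per frame (default 10).
#' @param exit_sep minimum spatial separation of accepted exits (default
#'   4 A).
#' @param dedup_dist paths closer than this (mean closest-point distance)
#'   are considered duplicates; only the cheaper is kept (default 1.5 A).
#' @return list of `hxd_tunnel_path` objects, each with `frame`, `points`
#'   (centerline), `radius` (clearance profile r(l)), `length`,
#'   `bottleneck`, `cost`, `throughput`. Empty list if the start has no
#'   admissible exit.
#' @export
find_tunnels <- function(x, start_point, probe_radius = 1.0, spacing = 0.6,
                         bulk_threshold = 4.0, grid_bounds = NULL,
                         frames = NULL, atoms = NULL, max_tunnels = 10L,
                         exit_sep = 4.0, dedup_dist = 1.5) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  is_traj <- inherits(x, "hxd_trajectory")
  if (is.null(frames)) frames <- 1L
  if (!is_traj && !identical(frames, 1L)) stop("toy geometries have 1 frame")
  out <- list()
  for (f in frames) {
    cr <- .coords_radii(x, NULL, f)
    coords <- cr$coords
    if (!is.null(atoms)) coords <- coords[atoms, , drop = FALSE]
    radii <- if (!is.null(atoms)) cr$radii[atoms] else cr$radii
    sp <- if (is.numeric(start_point) && length(start_point) == 3L)
      start_point else colMeans(coords[start_point, , drop = FALSE])
    paths <- .find_tunnels_frame(coords, radii, sp, probe_radius, spacing,
                                 bulk_threshold, grid_bounds, max_tunnels,
                                 exit_sep, dedup_dist)
    for (p in paths) { p$frame <- f; out[[length(out) + 1L]] <- p }
  }
  out
}

.find_tunnels_frame <- function(coords, radii, start_point, probe_radius,
                                spacing, bulk_threshold, grid_bounds,
                                max_tunnels, exit_sep, dedup_dist) {
  bbox <- cbind(apply(coords, 2, min), apply(coords, 2, max))
  if (is.null(grid_bounds)) {
    margin <- bulk_threshold + 2
    grid_bounds <- cbind(bbox[, 1] - margin, bbox[, 2] + margin)
  }
  ax <- lapply(1:3, function(k)
    seq(grid_bounds[k, 1] + spacing / 2, grid_bounds[k, 2], by = spacing))
  nd <- vapply(ax, length, integer(1))
  vox <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  clearance <- nearest_clearance(vox, coords, radii)
  admissible <- clearance >= probe_radius
  bulk <- clearance >= bulk_threshold
  hull <- array(FALSE, dim = nd)
  hull[c(1L, nd[1]), , ] <- TRUE
  hull[, c(1L, nd[2]), ] <- TRUE
  hull[, , c(1L, nd[3])] <- TRUE
  hull <- as.vector(hull)
  interior <- admissible & !bulk
  # portals: admissible bulk/hull nodes touching the interior (26-neighb.)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0L, ]
  lin_shift <- shifts[, 1] + shifts[, 2] * nd[1] + shifts[, 3] * nd[1] * nd[2]
  pos_all <- arrayInd(seq_len(prod(nd)), nd)
  near_interior <- rep(FALSE, prod(nd))
  int_idx <- which(interior)
  pos_int <- arrayInd(int_idx, nd)
  for (s in seq_len(nrow(shifts))) {
    ok <- pos_int[, 1] + shifts[s, 1] >= 1L & pos_int[, 1] + shifts[s, 1] <= nd[1] &
          pos_int[, 2] + shifts[s, 2] >= 1L & pos_int[, 2] + shifts[s, 2] <= nd[2] &
          pos_int[, 3] + shifts[s, 3] >= 1L & pos_int[, 3] + shifts[s, 3] <= nd[3]
    near_interior[int_idx[ok] + lin_shift[s]] <- TRUE
  }
  portal <- admissible & (bulk | hull) & near_interior
  nodes <- which(interior | portal)
  if (!length(nodes)) return(list())
  node_id <- integer(prod(nd)); node_id[nodes] <- seq_along(nodes)
  # snap start to the nearest admissible node
  sidx <- vapply(1:3, function(k)
    which.min(abs(ax[[k]] - start_point[k])), integer(1))
  slin <- sidx[1] + (sidx[2] - 1L) * nd[1] + (sidx[3] - 1L) * nd[1] * nd[2]
  if (!admissible[slin])
    stop(sprintf("start point clearance %.2f A is below the probe radius",
                 clearance[slin]))
  if (node_id[slin] == 0L) return(list())  # start already in bulk, or isolated
  # edges: 13 positive shifts among graph nodes
  pos_nodes <- arrayInd(nodes, nd)
  half <- shifts[seq_len(13L), , drop = FALSE]
  half_lin <- lin_shift[seq_len(13L)]
  ef <- et <- integer(0); ew <- numeric(0)
  inv_r2 <- 1 / pmax(clearance, probe_radius)^2
  for (s in seq_len(13L)) {
    ok <- pos_nodes[, 1] + half[s, 1] >= 1L & pos_nodes[, 1] + half[s, 1] <= nd[1] &
          pos_nodes[, 2] + half[s, 2] >= 1L & pos_nodes[, 2] + half[s, 2] <= nd[2] &
          pos_nodes[, 3] + half[s, 3] >= 1L & pos_nodes[, 3] + half[s, 3] <= nd[3]
    from <- nodes[ok]
    to <- from + half_lin[s]
    keep <- node_id[to] > 0L
    from <- from[keep]; to <- to[keep]
    if (!length(from)) next
    steplen <- spacing * sqrt(sum(half[s, ]^2))
    w <- steplen * 0.5 * (inv_r2[from] + inv_r2[to])
    ef <- c(ef, node_id[from]); et <- c(et, node_id[to]); ew <- c(ew, w)
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ef, et), weight = ew)
  sid <- node_id[slin]
  dists <- as.vector(igraph::distances(g, v = sid, weights = igraph::E(g)$weight))
  portal_ids <- node_id[which(portal)]
  portal_ids <- portal_ids[is.finite(dists[portal_ids])]
  if (!length(portal_ids)) return(list())
  ord <- portal_ids[order(dists[portal_ids])]
  accepted <- integer(0)
  for (p in ord) {
    if (length(accepted) >= max_tunnels) break
    pp <- vox[nodes[p], ]
    if (!length(accepted) ||
        min(sqrt(colSums((t(vox[nodes[accepted], , drop = FALSE]) - pp)^2))) >=
          exit_sep)
      accepted <- c(accepted, p)
  }
  paths <- list()
  for (p in accepted) {
    vp <- igraph::shortest_paths(g, from = sid, to = p,
                                 weights = igraph::E(g)$weight)$vpath[[1]]
    if (length(vp) < 2L) next
    pts <- vox[nodes[as.integer(vp)], , drop = FALSE]
    # truncate where the path leaves the atom bounding box
    inside <- pts[, 1] >= bbox[1, 1] & pts[, 1] <= bbox[1, 2] &
              pts[, 2] >= bbox[2, 1] & pts[, 2] <= bbox[2, 2] &
              pts[, 3] >= bbox[3, 1] & pts[, 3] <= bbox[3, 2]
    last <- if (any(!inside)) which(!inside)[1] - 1L else nrow(pts)
    if (last < 2L) next
    pts <- pts[seq_len(last), , drop = FALSE]
    paths[[length(paths) + 1L]] <-
      .make_tunnel_path(pts, coords, radii, probe_radius, spacing)
  }
  if (!length(paths)) return(paths)
  # drop near-duplicate paths (keep the cheaper of each pair)
  keep <- rep(TRUE, length(paths))
  for (i in seq_along(paths)) {
    if (!keep[i]) next
    for (j in seq_along(paths)) {
      if (j <= i || !keep[j]) next
      if (.path_dissimilarity(paths[[i]]$points, paths[[j]]$points) <
            dedup_dist) {
        drop <- if (paths[[i]]$cost <= paths[[j]]$cost) j else i
        keep[drop] <- FALSE
      }
    }
  }
  paths[keep]
}

.make_tunnel_path <- function(pts, coords, radii, probe_radius, spacing) {
  # refine the centerline toward the medial axis: move each point to the
  # best of 27 half-spacing offsets by clearance (2 rounds, deterministic)
  off <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1), c(-1, 0, 1))) *
    (spacing / 2)
  np <- nrow(pts)
  for (round in 1:2) {
    # local tangents (central differences; one-sided at the ends)
    tg <- rbind(pts[2, ] - pts[1, ],
                if (np > 2L) pts[3:np, , drop = FALSE] -
                  pts[1:(np - 2L), , drop = FALSE],
                pts[np, ] - pts[np - 1L, ])
    tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-9)
    cand <- pts[rep(seq_len(np), times = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), each = np), , drop = FALSE]
    cl <- matrix(nearest_clearance(cand, coords, radii), nrow = np)
    # lateral moves only: forbid offsets with an axial component, so the
    # point cannot slide along the tunnel past its own station
    axial <- abs(tcrossprod(tg, off))          # np x 27
    cl[axial > 0.1 * spacing] <- -Inf
    best <- max.col(cl, ties.method = "first")
    pts <- pts + off[best, , drop = FALSE]
  }
  # light smoothing; revert points whose clearance would fall below probe
  if (nrow(pts) >= 3L) {
    sm <- pts
    mid <- 2:(nrow(pts) - 1L)
    sm[mid, ] <- (pts[mid - 1L, ] + pts[mid, ] + pts[mid + 1L, ]) / 3
    cl <- nearest_clearance(sm, coords, radii)
    bad <- cl < probe_radius
    sm[bad, ] <- pts[bad, ]
    pts <- sm
  }
  r <- nearest_clearance(pts, coords, radii)
  seg <- sqrt(rowSums(diff(pts)^2))
  L <- sum(seg)
  inv2 <- 1 / r^2
  cost <- sum(seg * (inv2[-length(inv2)] + inv2[-1]) / 2)
  structure(list(frame = 1L, points = pts, radius = r, length = L,
                 bottleneck = min(r), cost = cost,
                 throughput = exp(-cost)),
            class = "hxd_tunnel_path")
}

#' @export
print.hxd_tunnel_path <- function(x, ...) {
  cat(sprintf(paste0("<hxd_tunnel_path> frame %d: L %.1f A, bottleneck ",
                     "%.2f A, cost %.3f, throughput %.4f\n"),
              x$frame, x$length, x$bottleneck, x$cost, x$throughput))
  invisible(x)
}

# symmetric mean closest-point distance between two centerlines,
# each resampled to n points by arc length
.path_dissimilarity <- function(p, q, n = 64L) {
  a <- .resample_path(p, n); b <- .resample_path(q, n)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d <- sqrt(pmax(d2, 0))
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

.resample_path <- function(p, n = 64L) {
  if (nrow(p) == 1L) return(p[rep(1L, n), , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  l <- c(0, cumsum(seg))
  tt <- seq(0, l[length(l)], length.out = n)
  cbind(stats::approx(l, p[, 1], xout = tt, ties = "ordered")$y,
        stats::approx(l, p[, 2], xout = tt, ties = "ordered")$y,
        stats::approx(l, p[, 3], xout = tt, ties = "ordered")$y)
}

#' Cluster tunnel paths across frames
#'
#' Average-linkage hierarchical clustering on the pairwise centerline
#' dissimilarity (symmetric mean closest-point distance of 64-point
#' resampled centerlines), cut at `threshold` (Angstrom). Clusters are
#' ranked by average bottleneck radius, then average throughput.
#'
#' @param paths list of `hxd_tunnel_path` (from [find_tunnels()]).
#' @param threshold cluster cut height in Angstrom (default 4).
#' @return list of `hxd_tunnel_cluster`: `members` (paths),
#'   `representative` (member with the highest throughput),
#'   `n_snapshots` (frames containing a member), `avg_bottleneck`,
#'   `max_bottleneck`, `avg_throughput`.
#' @export
cluster_tunnels <- function(paths, threshold = 4.0) {
  if (!length(paths)) stop("no paths to cluster")
  n <- length(paths)
  if (n == 1L) {
    memb <- 1L
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <-
        .path_dissimilarity(paths[[i]]$points, paths[[j]]$points)
    }
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    memb <- stats::cutree(hc, h = threshold)
  }
  clusters <- lapply(sort(unique(memb)), function(m) {
    mem <- paths[memb == m]
    bn <- vapply(mem, `[[`, numeric(1), "bottleneck")
    tp <- vapply(mem, `[[`, numeric(1), "throughput")
    structure(list(members = mem,
                   representative = mem[[which.max(tp)]],
                   n_snapshots = length(unique(vapply(mem, `[[`,
                                                      numeric(1), "frame"))),
                   avg_bottleneck = mean(bn), max_bottleneck = max(bn),
                   avg_throughput = mean(tp)),
              class = "hxd_tunnel_cluster")
  })
  rank <- order(vapply(clusters, `[[`, numeric(1), "avg_bottleneck"),
                vapply(clusters, `[[`, numeric(1), "avg_throughput"),
                decreasing = TRUE)
  clusters[rank]
}

#' @export
print.hxd_tunnel_cluster <- function(x, ...) {
  cat(sprintf(paste0("<hxd_tunnel_cluster> %d member(s) in %d snapshot(s); ",
                     "avg BR %.2f A, max BR %.2f A, avg TP %.3f\n"),
              length(x$members), x$n_snapshots, x$avg_bottleneck,
              x$max_bottleneck, x$avg_throughput))
  invisible(x)
}

#' Table-style summary of tunnel clusters
#'
#' One row per cluster: member count, snapshots, average and maximum
#' bottleneck radius, average throughput.
#'
#' @param clusters list of `hxd_tunnel_cluster`.
#' @return `data.frame`.
#' @export
tunnel_summary <- function(clusters) {
  data.frame(
    cluster = seq_along(clusters),
    n_members = vapply(clusters, function(c) length(c$members), integer(1)),
    n_snapshots = vapply(clusters, `[[`, numeric(1), "n_snapshots"),
    avg_bottleneck = vapply(clusters, `[[`, numeric(1), "avg_bottleneck"),
    max_bottleneck = vapply(clusters, `[[`, numeric(1), "max_bottleneck"),
    avg_throughput = vapply(clusters, `[[`, numeric(1), "avg_throughput")
  )
}

#' Residues lining a tunnel cluster
#'
#' Residues with any atom whose van der Waals surface lies within `cutoff`
#' of the tunnel surface (the clearance sphere around any member
#' centerline point), with the number of frames in which each residue
#' appears. Enlarging the cutoff never shrinks the set.
#'
#' @param cluster an `hxd_tunnel_cluster`.
#' @param traj the trajectory the tunnels were found in.
#' @param cutoff distance from the tunnel surface in Angstrom (default 2).
#' @return `data.frame`: `chain_id`, `residue_index`, `residue_name`,
#'   `n_frames`.
#' @export
lining_residues <- function(cluster, traj, cutoff = 2.0) {
  stopifnot(inherits(cluster, "hxd_tunnel_cluster"))
  top <- traj$topology
  res_key <- paste(top$chain_id, top$residue_index, top$residue_name)
  hits <- list()
  for (p in cluster$members) {
    coords <- frame_coords(traj, p$frame)
    d2 <- outer(rowSums(coords^2), rowSums(p$points^2), `+`) -
      2 * tcrossprod(coords, p$points)
    d <- sqrt(pmax(d2, 0))
    # gap between the atom vdW surface and the tunnel clearance sphere
    surf <- sweep(d, 2L, p$radius) - top$vdw_radius
    near <- apply(surf, 1L, min) <= cutoff
    if (!any(near)) next
    hits[[length(hits) + 1L]] <-
      data.frame(key = unique(res_key[near]), frame = p$frame)
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits))
    return(data.frame(chain_id = character(0), residue_index = integer(0),
                      residue_name = character(0), n_frames = integer(0)))
  agg <- stats::aggregate(frame ~ key, data = hits,
                          FUN = function(f) length(unique(f)))
  parts <- do.call(rbind, strsplit(agg$key, " "))
  out <- data.frame(chain_id = parts[, 1],
                    residue_index = as.integer(parts[, 2]),
                    residue_name = parts[, 3],
                    n_frames = agg$frame)
  out[order(out$chain_id, out$residue_index), ]
}
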