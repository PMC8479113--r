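#' Specification for a synthetic pseudo-hexamer trajectory
#'
#' The generator emulates the architecture the analyses assume: a
#' dimer-of-trimers of coarse bead subunits (C3 symmetry per ring, two
#' stacked rings), a buried di-metal site per subunit flanked by six
#' coordinating pseudo-histidine beads, a central axial pore, and one of two
#' planted collective modes on top of Gaussian thermal noise:
#'
#' * `ring_counter_rotation` — the top trimeric ring rotates clockwise and
#'   the bottom ring anticlockwise about the pore axis (the "deoxy-like"
#'   global mode);
#' * `clam_shell` — two adjacent subunits in each ring hinge apart and back
#'   (the "oxy-like" mode);
#' * `rigid` — no collective mode;
#' * `custom` — a user-supplied per-atom displacement field.
#'
#' The mode time course is a full sine period over the trajectory, so the
#' planted displacement has zero mean and a clean single-mode covariance.
#' `packing` controls the stacking: `"open"` subunits sit further from the
#' axis (wider pore, clearance about 2.9 A) with a 3 A gap between the
#' rings; `"closed"` subunits pack tighter (pore clearance about 1.4 A) with
#' the rings in contact.
#'
#' @param n_subunits number of subunits; must be even (half per ring).
#' @param residues_per_subunit beads in each subunit body (default 60).
#' @param packing `"open"` or `"closed"` (see above).
#' @param mode collective mode, see above.
#' @param mode_amplitude amplitude: degrees for the rotation/hinge modes,
#'   a plain multiplier of `custom_mode` for `mode = "custom"`.
#' @param noise_sd isotropic Gaussian displacement noise, sd per coordinate
#'   per frame (Angstrom), uncorrelated in time.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed; the same spec and seed give bitwise-identical
#'   coordinates.
#' @param custom_mode optional `n_atoms x 3` displacement field for
#'   `mode = "custom"`.
#' @return an object of class `hxd_synth_spec`.
#' @export
synthetic_spec <- function(n_subunits = 6L, residues_per_subunit = 60L,
                           packing = c("open", "closed"),
                           mode = c("ring_counter_rotation", "clam_shell",
                                    "rigid", "custom"),
                           mode_amplitude = 5, noise_sd = 0.3,
                           n_frames = 200L, seed = 1L, custom_mode = NULL) {
  packing <- match.arg(packing)
  mode <- match.arg(mode)
  if (n_subunits < 2L || n_subunits %% 2L != 0L)
    stop("n_subunits must be even and >= 2")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_subunits = as.integer(n_subunits),
                 residues_per_subunit = as.integer(residues_per_subunit),
                 packing = packing, mode = mode,
                 mode_amplitude = mode_amplitude, noise_sd = noise_sd,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 custom_mode = custom_mode),
            class = "hxd_synth_spec")
}

#' Convenience specs for the two study states
#'
#' `"deoxy"` is the open packing with the ring counter-rotation mode;
#' `"oxy"` is the closed packing with the clam-shell mode. All other
#' parameters are the [synthetic_spec()] defaults unless overridden.
#'
#' @param state `"deoxy"` or `"oxy"`.
#' @param ... overrides passed to [synthetic_spec()].
#' @return an `hxd_synth_spec`.
#' @export
hexamer_state_spec <- function(state = c("deoxy", "oxy"), ...) {
  state <- match.arg(state)
  args <- list(...)
  base <- if (state == "deoxy")
    list(packing = "open", mode = "ring_counter_rotation")
  else
    list(packing = "closed", mode = "clam_shell")
  base[names(args)] <- args
  do.call(synthetic_spec, base)
}

# Reference (frame-0) geometry: coordinates plus topology plus per-atom
# subunit/ring bookkeeping used by the mode machinery.
.hexamer_reference <- function(spec) {
  ns <- spec$n_subunits
  per_ring <- ns %/% 2L
  r0 <- if (spec$packing == "open") 4.6 else 3.1     # inner bead-center radius
  zc <- if (spec$packing == "open") 5.2 else 3.2     # ring center height
  radial <- r0 + c(0, 2, 4)
  zlay <- c(-2, 0, 2)
  sector <- 112 * pi / 180                           # angular span per subunit
  # allocate beads to the 3 radial x 3 z arcs proportionally to arc length
  nb <- spec$residues_per_subunit
  w <- rep(radial, times = length(zlay))
  counts <- floor(nb * w / sum(w))
  rem <- nb - sum(counts)
  if (rem > 0) {
    extra <- order(nb * w / sum(w) - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  arcs <- expand.grid(radius = radial, z = zlay)
  local_xyz <- do.call(rbind, lapply(seq_len(nrow(arcs)), function(i) {
    k <- counts[i]
    if (k == 0L) return(NULL)
    ang <- seq(-sector / 2, sector / 2, length.out = k + 2L)[-c(1L, k + 2L)]
    cbind(arcs$radius[i] * cos(ang), arcs$radius[i] * sin(ang),
          rep(arcs$z[i], k))
  }))
  # buried di-metal site + 6 pseudo-histidine beads, mid-wall
  rs <- r0 + 2
  site_local <- rbind(
    c(rs, -0.9, 0), c(rs, 0.9, 0),                       # CU1, CU2
    c(rs - 1.6, -2.1, 0), c(rs - 1.6, 2.1, 0),           # HIS beads
    c(rs + 1.6, -2.1, 0), c(rs + 1.6, 2.1, 0),
    c(rs, 0, 2.1), c(rs, 0, -2.1)
  )
  sub_xyz <- rbind(local_xyz, site_local)
  nat_sub <- nrow(sub_xyz)
  body <- seq_len(nb)

  coords <- NULL
  sub_id <- ring <- chain <- character(0)
  atom_name <- res_name <- character(0)
  chains <- LETTERS[seq_len(ns)]
  for (s in seq_len(ns)) {
    top_ring <- s <= per_ring
    k <- if (top_ring) s - 1L else s - per_ring - 1L
    phi <- 2 * pi * k / per_ring + if (top_ring) 0 else pi / per_ring
    zoff <- if (top_ring) zc else -zc
    cp <- cos(phi); sp <- sin(phi)
    xy <- cbind(sub_xyz[, 1] * cp - sub_xyz[, 2] * sp,
                sub_xyz[, 1] * sp + sub_xyz[, 2] * cp,
                sub_xyz[, 3] + zoff)
    coords <- rbind(coords, xy)
    sub_id <- c(sub_id, rep(chains[s], nat_sub))
    ring <- c(ring, rep(if (top_ring) "top" else "bottom", nat_sub))
    atom_name <- c(atom_name,
                   rep("CA", nb), "CU1", "CU2", rep("NE2", 6L))
    res_name <- c(res_name, rep("ALA", nb), rep("CUX", 2L), rep("HIS", 6L))
  }
  n_all <- nrow(coords)
  top <- topology(atom_name = atom_name,
                  residue_index = seq_len(n_all) - 1L,
                  residue_name = res_name, chain_id = sub_id, ring = ring)
  list(coords = coords, topology = top, per_ring = per_ring,
       chains = chains)
}

.rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# rotation by theta about a unit axis u through the origin (Rodrigues)
.rot_axis <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a synthetic hexamer trajectory
#'
#' See [synthetic_spec()] for the model. The dominant collective motion of
#' the result is the requested mode with a sinusoidal time course, plus
#' i.i.d. Gaussian displacement noise of sd `noise_sd` per coordinate.
#' Chain ids (`A`, `B`, ...) distinguish subunits and the topology `ring`
#' column records ring membership.
#'
#' @param spec an [synthetic_spec()].
#' @return an [trajectory()] with attribute `"spec"`.
#' @export
generate_hexamer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "hxd_synth_spec"))
  ref <- .hexamer_reference(spec)
  nf <- spec$n_frames
  nat <- nrow(ref$coords)
  amp <- spec$mode_amplitude
  theta_t <- amp * pi / 180 * sin(2 * pi * (seq_len(nf) - 1L) / nf)
  top_idx <- which(ref$topology$ring == "top")
  bot_idx <- which(ref$topology$ring == "bottom")
  coords <- array(NA_real_, dim = c(nf, nat, 3L))

  if (spec$mode == "custom") {
    if (is.null(spec$custom_mode) ||
        !identical(dim(spec$custom_mode), c(nat, 3L)))
      stop("mode 'custom' needs an n_atoms x 3 custom_mode field")
    s_t <- amp * sin(2 * pi * (seq_len(nf) - 1L) / nf)
  }
  chains <- ref$chains
  per_ring <- ref$per_ring
  # clam-shell hinge: first two subunits of each ring tilt in antiphase
  # about the horizontal axis bisecting their centers
  cs_pairs <- list(
    list(a = which(ref$topology$chain_id == chains[1]),
         b = which(ref$topology$chain_id == chains[2]),
         axis_angle = pi / per_ring),
    list(a = which(ref$topology$chain_id == chains[per_ring + 1]),
         b = which(ref$topology$chain_id == chains[per_ring + 2]),
         axis_angle = pi / per_ring + pi / per_ring)
  )
  for (t in seq_len(nf)) {
    x <- ref$coords
    th <- theta_t[t]
    if (spec$mode == "ring_counter_rotation") {
      x[top_idx, ] <- x[top_idx, ] %*% t(.rot_z(th))
      x[bot_idx, ] <- x[bot_idx, ] %*% t(.rot_z(-th))
    } else if (spec$mode == "clam_shell") {
      for (p in cs_pairs) {
        u <- c(cos(p$axis_angle), sin(p$axis_angle), 0)
        x[p$a, ] <- x[p$a, ] %*% t(.rot_axis(u, th))
        x[p$b, ] <- x[p$b, ] %*% t(.rot_axis(u, -th))
      }
    } else if (spec$mode == "custom") {
      x <- x + s_t[t] * spec$custom_mode
    } # rigid: reference as is
    coords[t, , ] <- x
  }
  if (spec$noise_sd > 0) {
    coords <- coords + with_seed(spec$seed, {
      array(stats::rnorm(length(coords), sd = spec$noise_sd), dim = dim(coords))
    })
  }
  out <- trajectory(coords, ref$topology)
  attr(out, "spec") <- spec
  out
}

#' Toy geometries with analytic ground truth
#'
#' Oracle inputs for the surface, pocket and tunnel analyses. Each geometry
#' is a set of atom centers plus radii and a `truth` list holding the
#' quantities known by construction.
#'
#' Kinds:
#' * `"sphere"` — one atom of radius `radius`; truth: accessible surface
#'   area with probe `probe`, `4*pi*(radius+probe)^2`.
#' * `"sphere_pair"` — two atoms of radius `radius` at distance `d`; truth:
#'   analytic two-sphere ASA (each sphere loses the spherical cap buried in
#'   the other's expanded sphere).
#' * `"hollow_shell"` — a closed cubic shell of wall beads with an empty
#'   cubic cavity; the wall planes are placed so that the region with
#'   clearance >= `probe_min` is a cube of side `cavity_side`; truth:
#'   cavity volume `cavity_side^3`.
#' * `"channel"` — a solid slab pierced by a straight cylindrical channel
#'   of clearance radius `radius` along z over `|z| <= length`; truth per
#'   exit: path length `length`, bottleneck `radius`,
#'   cost `length / radius^2`, throughput `exp(-cost)`.
#' * `"hourglass"` — a channel whose clearance radius grows linearly from
#'   `constriction` at z = 0 with slope `slope`; truth: bottleneck
#'   `constriction`.
#'
#' @param kind geometry kind, see above.
#' @param radius,d,probe,cavity_side,length,constriction,slope,half_length
#'   geometry parameters (Angstrom); see above.
#' @param bead_radius wall bead van der Waals radius.
#' @param spacing wall lattice spacing.
#' @param probe_min clearance at which the shell cavity boundary is defined.
#' @return an object of class `hxd_toy_geometry`: `coords`, `topology`,
#'   `truth`, `kind`.
#' @export
generate_toy_geometry <- function(kind = c("sphere", "sphere_pair",
                                           "hollow_shell", "channel",
                                           "hourglass"),
                                  radius = 1.7, d = 2.0, probe = 1.4,
                                  cavity_side = 6, length = 10,
                                  constriction = 1.5, slope = 0.25,
                                  half_length = 8, bead_radius = 1.7,
                                  spacing = 1.2, probe_min = 1.0) {
  kind <- match.arg(kind)
  if (radius <= 0 || bead_radius <= 0 || spacing <= 0)
    stop("geometry parameters must be positive")
  truth <- list()
  if (kind == "sphere") {
    coords <- matrix(0, 1, 3)
    radii <- radius
    truth$asa <- 4 * pi * (radius + probe)^2
    truth$probe <- probe
  } else if (kind == "sphere_pair") {
    if (d <= 0) stop("sphere distance must be positive")
    coords <- rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0))
    radii <- c(radius, radius)
    R <- radius + probe
    cap <- if (d < 2 * R) 2 * pi * R * (R - d / 2) else 0
    truth$asa <- 2 * (4 * pi * R^2 - cap)
    truth$probe <- probe
  } else if (kind == "hollow_shell") {
    h <- cavity_side / 2 + bead_radius + probe_min  # innermost wall plane
    if (h <= 0) stop("cavity larger than shell")
    s <- h / ceiling(h / spacing)                   # make h a lattice multiple
    g <- seq(-h - 2 * s, h + 2 * s, by = s)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    inner <- pmax(abs(pts[, 1]), pmax(abs(pts[, 2]), abs(pts[, 3])))
    coords <- pts[inner >= h - 1e-9, , drop = FALSE]
    radii <- rep(bead_radius, nrow(coords))
    truth$cavity_volume <- cavity_side^3
    truth$cavity_side <- cavity_side
    truth$probe_min <- probe_min
    truth$wall_spacing <- s
  } else if (kind == "channel" || kind == "hourglass") {
    hl <- if (kind == "channel") length else half_length
    wall_r <- function(z) {
      if (kind == "channel") rep(radius + bead_radius, length(z))
      else constriction + bead_radius + slope * abs(z)
    }
    lat <- max(wall_r(hl)) + 3 * spacing
    gx <- seq(0, lat, by = spacing); gx <- c(-rev(gx[-1]), gx)
    sz <- hl / ceiling(hl / spacing)
    gz <- seq(-hl, hl, by = sz)
    pts <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
    rr <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    coords <- pts[rr >= wall_r(pts[, 3]) + 0.4, , drop = FALSE]
    # line the channel with a dense ring of beads at exactly the nominal
    # wall radius, so the as-built clearance matches the stored truth
    for (z in seq(-hl, hl, by = 0.6)) {
      rw <- wall_r(z)
      nang <- max(8L, ceiling(2 * pi * rw / 0.8))
      ang <- 2 * pi * seq_len(nang) / nang
      coords <- rbind(coords, cbind(rw * cos(ang), rw * sin(ang), z))
    }
    radii <- rep(bead_radius, nrow(coords))
    if (kind == "channel") {
      truth$bottleneck <- radius
      truth$length <- length
      truth$cost <- length / radius^2
      truth$throughput <- exp(-truth$cost)
    } else {
      truth$bottleneck <- constriction
    }
  }
  n <- nrow(coords)
  top <- topology(atom_name = rep("C", n),
                  residue_index = seq_len(n) - 1L,
                  residue_name = rep("TOY", n),
                  chain_id = rep("A", n),
                  vdw_radius = radii)
  structure(list(coords = coords, topology = top, truth = truth, kind = kind),
            class = "hxd_toy_geometry")
}

#' Turn a toy geometry into a (static) single-frame trajectory
#' @param geom an [generate_toy_geometry()] result.
#' @return an [trajectory()].
#' @export
as_trajectory <- function(geom) {
  stopifnot(inherits(geom, "hxd_toy_geometry"))
  trajectory(geom$coords, geom$topology)
}

#' Shell trajectory with a cavity that opens and closes on a schedule
#'
#' Builds a trajectory from a `"hollow_shell"` toy geometry plus a lattice
#' plug that fills the cavity; in "open" frames the plug is parked far
#' outside the shell, in "closed" frames it sits inside the cavity. The
#' per-voxel opening frequency of the cavity is therefore known exactly by
#' construction.
#'
#' @param geom a `"hollow_shell"` [generate_toy_geometry()].
#' @param n_frames total frames.
#' @param open_frames integer vector of frames in which the cavity is open.
#' @return an [trajectory()] with attribute `"open_frames"`.
#' @export
toy_cavity_trajectory <- function(geom, n_frames = 200L,
                                  open_frames = seq_len(40L)) {
  stopifnot(inherits(geom, "hxd_toy_geometry"), geom$kind == "hollow_shell")
  if (any(open_frames < 1L | open_frames > n_frames))
    stop("open_frames out of range")
  s <- geom$truth$wall_spacing
  a2 <- geom$truth$cavity_side / 2
  g <- seq(-a2 - 1, a2 + 1, by = s)
  plug <- as.matrix(expand.grid(x = g, y = g, z = g))
  park <- cbind(plug[, 1] + 100, plug[, 2], plug[, 3])
  all_ref <- rbind(geom$coords, plug)
  n_wall <- nrow(geom$coords); n_plug <- nrow(plug)
  top <- topology(atom_name = rep("C", n_wall + n_plug),
                  residue_index = seq_len(n_wall + n_plug) - 1L,
                  residue_name = c(rep("TOY", n_wall), rep("PLG", n_plug)),
                  chain_id = c(rep("A", n_wall), rep("P", n_plug)),
                  vdw_radius = rep(geom$topology$vdw_radius[1], n_wall + n_plug))
  coords <- array(NA_real_, dim = c(n_frames, n_wall + n_plug, 3L))
  for (t in seq_len(n_frames)) {
    x <- all_ref
    if (t %in% open_frames) x[(n_wall + 1):(n_wall + n_plug), ] <- park
    coords[t, , ] <- x
  }
  out <- trajectory(coords, top)
  attr(out, "open_frames") <- open_frames
  out
}

#' Labelled per-frame site distance matrices for two states
#'
#' For each frame of each state, the pairwise distance matrix over the
#' pseudo-histidine site beads (36 for the default hexamer: 6 per subunit),
#' with the state label attached — the input of the autoencoder module.
#'
#' @param spec_a,spec_b [synthetic_spec()]s for the two states; they must
#'   share the site-atom layout.
#' @param frames_per_state frames generated per state (overrides the specs'
#'   `n_frames` when not `NULL`).
#' @param split train fraction of the train/validation split (default 0.8).
#' @param seed seed for the split.
#' @return an `hxd_distance_dataset` (see [build_dataset()]).
#' @export
generate_site_distance_dataset <- function(spec_a, spec_b,
                                           frames_per_state = NULL,
                                           split = 0.8, seed = 1L) {
  if (!is.null(frames_per_state)) {
    if (frames_per_state == 0L) {
      return(structure(list(matrices = array(0, c(0L, 0L, 0L)),
                            labels = factor(character(0)),
                            split = list(train = integer(0), val = integer(0)),
                            seed = seed),
                       class = "hxd_distance_dataset"))
    }
    spec_a$n_frames <- as.integer(frames_per_state)
    spec_b$n_frames <- as.integer(frames_per_state)
  }
  ta <- generate_hexamer_trajectory(spec_a)
  tb <- generate_hexamer_trajectory(spec_b)
  sel_a <- atom_select(ta, name = "NE2", resname = "HIS")
  sel_b <- atom_select(tb, name = "NE2", resname = "HIS")
  if (length(sel_a) != length(sel_b))
    stop("the two specs do not share the site-atom layout")
  build_dataset(ta, tb, selection = sel_a, selection_b = sel_b,
                split = split, seed = seed)
}
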