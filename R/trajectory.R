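#' Build an atom topology table
#'
#' A topology records, per atom, its name, residue, chain and van der Waals
#' radius. Atom and residue indices are 0-based internally (1-based only at
#' PDB serialization) and coordinates are in Angstrom throughout the package.
#'
#' @param atom_name character vector of atom names (e.g. `"CA"`, `"NE2"`).
#' @param residue_index 0-based integer residue index per atom.
#' @param residue_name character residue names (e.g. `"ALA"`, `"HIS"`).
#' @param chain_id character chain identifier per atom.
#' @param vdw_radius van der Waals radius in Angstrom; if `NULL`, assigned
#'   from the bundled Bondi element table via [element_of()].
#' @param mass atomic mass in amu; if `NULL`, assigned from the element table.
#' @param ring optional per-atom ring label (`"top"`/`"bottom"`) used by the
#'   synthetic hexamer generator.
#'
#' @return a `data.frame` with one row per atom and columns `atom_index`,
#'   `atom_name`, `residue_index`, `residue_name`, `chain_id`, `vdw_radius`,
#'   `mass` (and `ring` when given).
#' @export
topology <- function(atom_name, residue_index, residue_name, chain_id,
                     vdw_radius = NULL, mass = NULL, ring = NULL) {
  n <- length(atom_name)
  stopifnot(length(residue_index) == n, length(residue_name) == n,
            length(chain_id) == n)
  el <- element_of(atom_name)
  if (is.null(vdw_radius)) vdw_radius <- vdw_radius_of(el)
  if (is.null(mass)) mass <- mass_of(el)
  if (any(!is.finite(vdw_radius)) || any(vdw_radius <= 0))
    stop("vdw_radius must be positive and finite")
  top <- data.frame(
    atom_index = seq_len(n) - 1L,
    atom_name = as.character(atom_name),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    chain_id = as.character(chain_id),
    vdw_radius = as.numeric(vdw_radius),
    mass = as.numeric(mass),
    stringsAsFactors = FALSE
  )
  if (!is.null(ring)) top$ring <- as.character(ring)
  top
}

# Bondi radii; metals default to 1.40 A. Masses are only used for optional
# mass-weighted Rg, so a coarse table suffices.
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.mass_table <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
                 P = 30.974, CU = 63.546, ZN = 65.38, FE = 55.845)
.metals <- c("CU", "ZN", "FE", "MG", "MN", "NI", "CO")

#' Infer the chemical element from an atom name
#'
#' Protein atom-name convention: leading digits are stripped and the first
#' letter names the element, except for the recognised metal names
#' (CU, ZN, FE, MG, MN, NI, CO) which are matched in full.
#' @param atom_name character vector.
#' @return character vector of element symbols.
#' @export
element_of <- function(atom_name) {
  nm <- toupper(gsub("^[0-9 ]+", "", as.character(atom_name)))
  el <- substr(nm, 1L, 1L)
  is_metal <- nm %in% .metals
  el[is_metal] <- nm[is_metal]
  el
}

vdw_radius_of <- function(element) {
  r <- .vdw_table[element]
  r[is.na(r)] <- 1.40  # metals / unknowns
  unname(r)
}

mass_of <- function(element) {
  m <- .mass_table[element]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Construct a trajectory
#'
#' The universal input of all analyses: an array of coordinates of dimension
#' frames x atoms x 3 (Angstrom) plus a [topology()].
#'
#' @param coords numeric array `n_frames x n_atoms x 3`, or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param top topology `data.frame` (see [topology()]).
#' @param frame_times optional numeric vector of frame times (ps).
#' @return an object of class `hxd_trajectory`.
#' @export
trajectory <- function(coords, top, frame_times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[1] < 1L) stop("trajectory needs at least one frame")
  if (dim(coords)[2] != nrow(top))
    stop("coordinate array atom count (", dim(coords)[2],
         ") does not match topology (", nrow(top), ")")
  if (!all(is.finite(coords))) stop("coordinates must all be finite")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1])
    stop("frame_times length must equal number of frames")
  structure(list(coords = coords, topology = top, frame_times = frame_times),
            class = "hxd_trajectory")
}

#' @export
print.hxd_trajectory <- function(x, ...) {
  cat(sprintf("<hxd_trajectory> %d frames, %d atoms, %d chains\n",
              n_frames(x), n_atoms(x),
              length(unique(x$topology$chain_id))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `hxd_trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Number of atoms in a trajectory
#' @param traj an `hxd_trajectory`.
#' @return integer.
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Coordinates of one frame
#' @param traj an `hxd_trajectory`.
#' @param i frame number (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i = 1L) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

#' Select atoms by topology predicates
#'
#' All arguments combine with AND; each accepts a vector of admissible values.
#'
#' @param traj an `hxd_trajectory`.
#' @param name atom names to keep (e.g. `"CA"`).
#' @param chain chain ids to keep.
#' @param resname residue names to keep.
#' @param residue 0-based residue indices to keep.
#' @param ring ring labels to keep (synthetic hexamers only).
#' @return 1-based integer vector of atom indices.
#' @export
atom_select <- function(traj, name = NULL, chain = NULL, resname = NULL,
                        residue = NULL, ring = NULL) {
  top <- traj$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(name)) keep <- keep & top$atom_name %in% name
  if (!is.null(chain)) keep <- keep & top$chain_id %in% chain
  if (!is.null(resname)) keep <- keep & top$residue_name %in% resname
  if (!is.null(residue)) keep <- keep & top$residue_index %in% residue
  if (!is.null(ring)) {
    if (is.null(top$ring)) stop("topology has no ring labels")
    keep <- keep & top$ring %in% ring
  }
  which(keep)
}

#' Slice a trajectory by frames and/or atoms
#'
#' Frame and atom order are preserved; selections compose, i.e.
#' `traj_select(traj_select(t, frames = a), frames = b)` equals a single
#' selection with composed indices.
#'
#' @param traj an `hxd_trajectory`.
#' @param frames integer frame indices (1-based), or `NULL` to combine
#'   `start`/`stop`/`stride`.
#' @param start,stop,stride frame range shortcut, 1-based and inclusive.
#' @param atoms integer atom indices (1-based) or a logical mask.
#' @return an `hxd_trajectory`.
#' @export
traj_select <- function(traj, frames = NULL, start = 1L, stop = n_frames(traj),
                        stride = 1L, atoms = NULL) {
  if (is.null(frames)) frames <- seq.int(start, stop, by = stride)
  if (is.logical(frames)) frames <- which(frames)
  if (length(frames) == 0L) stop("empty frame selection")
  if (any(frames < 1L | frames > n_frames(traj)))
    stop("frame selection out of range")
  if (is.null(atoms)) atoms <- seq_len(n_atoms(traj))
  if (is.logical(atoms)) atoms <- which(atoms)
  if (length(atoms) == 0L) stop("empty atom selection")
  top <- traj$topology[atoms, , drop = FALSE]
  top$atom_index <- seq_len(nrow(top)) - 1L
  rownames(top) <- NULL
  trajectory(traj$coords[frames, atoms, , drop = FALSE], top,
             frame_times = traj$frame_times[frames])
}

#' Keep the last fraction of frames
#'
#' Convenience for the usual "equilibrated tail" selection (e.g. the last
#' 40% of a production run).
#' @param traj an `hxd_trajectory`.
#' @param fraction fraction of trailing frames to keep, in (0, 1].
#' @return an `hxd_trajectory`.
#' @export
last_fraction <- function(traj, fraction = 0.4) {
  stopifnot(fraction > 0, fraction <= 1)
  nf <- n_frames(traj)
  keep <- max(1L, ceiling(nf * fraction))
  traj_select(traj, start = nf - keep + 1L, stop = nf)
}
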