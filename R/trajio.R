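#' Read a trajectory from disk
#'
#' Multi-model PDB is the reference format: MODEL/ENDMDL records become
#' frames. Parsing is delegated to \pkg{bio3d}; van der Waals radii are then
#' assigned from the bundled Bondi element table.
#'
#' @param path path to a PDB file.
#' @param format currently only `"pdb_multimodel"`. DCD/XTC are not
#'   supported: no reader for those binary formats is available to this
#'   package, and multi-model PDB is the reference fixture format.
#' @return an [trajectory()] object.
#' @export
read_trajectory <- function(path, format = c("pdb_multimodel", "dcd", "xtc")) {
  format <- match.arg(format)
  if (format != "pdb_multimodel")
    stop("format '", format, "' is not supported; use multi-model PDB")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("cannot parse '", path, "' as PDB: ",
                             conditionMessage(e))
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nat <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * nat)
    stop("atom count mismatch across MODEL records in '", path, "'")
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, nat, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3L * nat, by = 3L), drop = FALSE]
  chain <- pdb$atom$chain
  chain[is.na(chain) | chain == ""] <- "A"
  top <- topology(
    atom_name = pdb$atom$elety,
    residue_index = as.integer(factor(paste(chain, pdb$atom$resno),
                                      levels = unique(paste(chain, pdb$atom$resno)))) - 1L,
    residue_name = pdb$atom$resid,
    chain_id = chain
  )
  trajectory(coords, top)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an `hxd_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  top <- traj$topology
  nf <- n_frames(traj); nat <- n_atoms(traj)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * nat)
  for (k in 1:3) xyz[, seq(k, 3L * nat, by = 3L)] <- traj$coords[, , k]
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nat),
    resno = top$residue_index + 1L,   # 1-based only at serialization
    resid = top$residue_name,
    eleno = seq_len(nat),
    elety = top$atom_name,
    chain = top$chain_id,
    elesy = element_of(top$atom_name)
  )
  invisible(path)
}

#' Serialize an analysis matrix to CSV
#'
#' @param m matrix (e.g. a cross-correlation matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Serialize run metadata as JSON
#'
#' @param meta named list of parameters, seeds and provenance.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export points (e.g. a tunnel centerline) as PDB pseudo-atoms
#'
#' @param points `n x 3` matrix of coordinates (Angstrom).
#' @param path output path.
#' @param bfactor optional per-point scalar written to the B-factor column
#'   (e.g. the local clearance radius).
#' @return `path`, invisibly.
#' @export
write_pseudo_atoms <- function(points, path, bfactor = NULL) {
  n <- nrow(points)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  bio3d::write.pdb(
    file = path, xyz = as.vector(t(points)),
    type = rep("HETATM", n), resno = seq_len(n),
    resid = rep("TUN", n), eleno = seq_len(n),
    elety = rep("C", n), chain = rep("T", n), b = bfactor
  )
  invisible(path)
}
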