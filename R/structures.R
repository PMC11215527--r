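#' Structure frames and trajectories
#'
#' A `structure_frame` holds one conformation: an atom table (`chain`,
#' `resno`, `resname`, `atom`, `element`) plus an `n x 3` coordinate matrix
#' in Angstrom.  A `md_trajectory` holds an ordered set of frames sharing
#' one topology as an `n_atoms x 3 x n_frames` array.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, and optionally `element` (inferred from the first letter of
#'   the atom name when absent).
#' @param xyz Numeric `n x 3` matrix, Angstrom.
#' @return An object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 || nrow(xyz) != nrow(atoms))
    stop("xyz must be an n x 3 matrix matching the atom table")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[0-9]", "", atoms$atom), 1, 1)
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key)) stop("duplicate (chain, resno, atom) keys")
  structure(list(atoms = atoms, xyz = xyz), class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Build a trajectory from structure frames
#'
#' @param frames List of [structure_frame()] objects with identical atom
#'   tables.
#' @param frame_interval Frame spacing, ns (metadata only).
#' @param ground_truth Optional data frame of programmed per-frame values
#'   (e.g. rotation angles).
#' @return An object of class `md_trajectory` with elements `atoms`,
#'   `coords` (`n_atoms x 3 x n_frames`), `frame_interval`, `ground_truth`.
#' @export
md_trajectory <- function(frames, frame_interval = 1, ground_truth = NULL) {
  if (length(frames) < 1) stop("need at least one frame")
  atoms <- frames[[1]]$atoms
  n <- nrow(atoms)
  coords <- array(NA_real_, c(n, 3, length(frames)))
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$atoms) != n)
      stop("all frames must share one topology")
    coords[, , i] <- frames[[i]]$xyz
  }
  structure(list(atoms = atoms, coords = coords,
                 frame_interval = frame_interval,
                 ground_truth = ground_truth),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms\n",
              dim(x$coords)[3], dim(x$coords)[1]))
  invisible(x)
}

#' Extract one frame of a trajectory
#' @param traj A [md_trajectory()].
#' @param i Frame index.
#' @return A [structure_frame()].
#' @export
trajectory_frame <- function(traj, i) {
  structure_frame(traj$atoms, traj$coords[, , i])
}

#' Number of frames in a trajectory
#' @param traj A [md_trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Select atom indices by chain / residue / atom name
#'
#' All supplied filters are combined with AND; `NULL` filters match
#' everything.
#'
#' @param frame A [structure_frame()] or [md_trajectory()] (atom table is
#'   shared across frames).
#' @param chain,resno,atom,resname Optional vectors of admissible values.
#' @return Integer atom indices.
#' @export
select_atoms <- function(frame, chain = NULL, resno = NULL, atom = NULL,
                         resname = NULL) {
  a <- frame$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(atom)) keep <- keep & a$atom %in% atom
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  which(keep)
}

#' Read / write structures and trajectories as PDB
#'
#' Thin wrappers over [bio3d::read.pdb()] / [bio3d::write.pdb()].
#' Multi-model PDB files are mapped to [md_trajectory()] objects.
#'
#' @param path PDB file.
#' @return `read_structure_pdb`: a [structure_frame()];
#'   `read_trajectory_pdb`: a [md_trajectory()].
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  structure_frame(data.frame(chain = a$chain, resno = a$resno,
                             resname = a$resid, atom = a$elety,
                             element = a$elesy),
                  cbind(a$x, a$y, a$z))
}

#' @rdname read_structure_pdb
#' @param frame_interval Frame spacing, ns.
#' @export
read_trajectory_pdb <- function(path, frame_interval = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  a <- pdb$atom
  atoms <- data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
                      atom = a$elety, element = a$elesy)
  nf <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nf), function(i)
    structure_frame(atoms, matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)))
  md_trajectory(frames, frame_interval = frame_interval)
}

#' @rdname read_structure_pdb
#' @param x A [structure_frame()] or [md_trajectory()] to write.
#' @export
write_structure_pdb <- function(x, path) {
  if (inherits(x, "structure_frame")) {
    xyz <- as.numeric(t(x$xyz))
    atoms <- x$atoms
  } else if (inherits(x, "md_trajectory")) {
    atoms <- x$atoms
    xyz <- t(apply(x$coords, 3, function(m) as.numeric(t(m))))
  } else stop("unsupported object")
  bio3d::write.pdb(file = path, xyz = xyz,
                   chain = atoms$chain, resno = atoms$resno,
                   resid = atoms$resname, elety = atoms$atom,
                   elesy = atoms$element)
  invisible(path)
}
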