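# Bondi van der Waals radii (Angstrom). Unknown elements are an error by
# design: guessing a radius silently corrupts SASA and contact analyses.
.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

#' Look up van der Waals radii for element symbols
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @return numeric vector of Bondi radii in Angstrom.
#' @export
vdw_radii <- function(elements) {
  el <- toupper(trimws(elements))
  r <- .bondi_radii[el]
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    stop("unknown element(s): ", paste(bad, collapse = ", "),
         " (no van der Waals radius tabulated)", call. = FALSE)
  }
  unname(r)
}

#' Construct a molecular Structure
#'
#' A `Structure` is the basic container for one conformation: per-atom
#' names, residue assignment, coordinates and van der Waals radii.
#'
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param atom_name character vector of atom identifiers (e.g. "CA").
#' @param residue_index integer vector, 1-based residue number per atom,
#'   non-decreasing along the chain.
#' @param residue_name character vector of 3-letter residue codes.
#' @param element character vector of element symbols; radii are assigned
#'   from the Bondi table.
#' @param b_column optional per-atom scalar (crystallographic B-factor).
#' @return an object of class `Structure`.
#' @export
new_structure <- function(coords, atom_name = NULL, residue_index = NULL,
                          residue_name = NULL, element = "C",
                          b_column = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("Structure needs at least one atom")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(atom_name)) atom_name <- rep("CA", n)
  if (is.null(residue_index)) residue_index <- seq_len(n)
  if (is.null(residue_name)) residue_name <- rep("ALA", n)
  element <- rep_len(element, n)
  residue_index <- as.integer(residue_index)
  if (length(atom_name) != n || length(residue_index) != n ||
      length(residue_name) != n) {
    stop("per-atom metadata lengths must match nrow(coords)")
  }
  if (is.unsorted(residue_index)) {
    stop("residue_index must be non-decreasing along the chain")
  }
  radii <- vdw_radii(element)
  x <- list(
    atom_name = as.character(atom_name),
    residue_index = residue_index,
    residue_name = as.character(residue_name),
    element = toupper(element),
    coords = unname(coords),
    radii = radii,
    b_column = b_column
  )
  class(x) <- "Structure"
  x
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure: %d atoms, %d residues>\n",
              n_atoms(x), n_residues(x)))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param s a `Structure`.
#' @export
n_atoms <- function(s) nrow(s$coords)

#' Number of residues in a Structure
#' @param s a `Structure`.
#' @export
n_residues <- function(s) length(unique(s$residue_index))

#' Construct an Ensemble of conformations sharing one topology
#'
#' @param topology a `Structure` providing the shared per-atom metadata.
#' @param frames list of n x 3 coordinate matrices, one per snapshot.
#' @param frame_labels optional character vector of source/time tags.
#' @param align_mask integer vector of atom indices defining the common
#'   reference system (the structurally conserved region) used for
#'   superposition; defaults to all atoms.
#' @return an object of class `Ensemble`.
#' @export
new_ensemble <- function(topology, frames, frame_labels = NULL,
                         align_mask = NULL) {
  stopifnot(inherits(topology, "Structure"))
  if (length(frames) < 1L) stop("Ensemble needs at least one frame")
  n <- n_atoms(topology)
  for (i in seq_along(frames)) {
    frames[[i]] <- unname(as.matrix(frames[[i]]))
    if (nrow(frames[[i]]) != n || ncol(frames[[i]]) != 3L) {
      stop("frame ", i, " has ", nrow(frames[[i]]),
           " atoms; topology has ", n)
    }
  }
  if (is.null(align_mask)) align_mask <- seq_len(n)
  align_mask <- sort(unique(as.integer(align_mask)))
  if (length(align_mask) < 1L || any(align_mask < 1L | align_mask > n)) {
    stop("align_mask must be a non-empty subset of atom indices")
  }
  x <- list(topology = topology, frames = frames,
            frame_labels = frame_labels, align_mask = align_mask)
  class(x) <- "Ensemble"
  x
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("<Ensemble: %d frames x %d atoms (align mask: %d atoms)>\n",
              n_frames(x), n_atoms(x$topology), length(x$align_mask)))
  invisible(x)
}

#' Number of frames in an Ensemble
#' @param ens an `Ensemble`.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Extract one frame of an Ensemble as a Structure
#' @param ens an `Ensemble`.
#' @param i frame index.
#' @export
frame_structure <- function(ens, i) {
  s <- ens$topology
  s$coords <- ens$frames[[i]]
  s
}

# Atom indices belonging to given residue indices.
atoms_of_residues <- function(s, residues) {
  which(s$residue_index %in% residues)
}
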