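#' Radius of gyration
#'
#' `Rg = sqrt(sum m_i |r_i - r_cm|^2 / sum m_i)`.
#'
#' @param x coordinates (n x 3 matrix or `Structure`).
#' @param masses per-atom masses; default: unit masses.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(x, masses = NULL) {
  X <- .as_coords(x)
  if (is.null(masses)) masses <- rep(1, nrow(X))
  if (length(masses) != nrow(X)) stop("masses length mismatch")
  if (any(masses < 0)) stop("masses must be non-negative")
  W <- sum(masses)
  if (W <= 0) stop("all-zero masses")
  cm <- colSums(X * masses) / W
  sqrt(sum(masses * rowSums(sweep(X, 2, cm)^2)) / W)
}

#' Isotropic B-factors from an ensemble
#'
#' Frames are superposed onto the iteratively refined ensemble mean using
#' the ensemble's alignment mask, then `B_i = (8 pi^2 / 3) <|dr_i|^2>`
#' with `dr_i` the deviation from the mean structure. Reported per residue
#' (mean over member atoms) or per atom.
#'
#' @param ens an `Ensemble` with at least 2 frames.
#' @param per `"residue"` or `"atom"`.
#' @param selection `"all"` atoms or `"ca"` (atoms named CA) before
#'   averaging per residue.
#' @return a `FlexibilityProfile`: list with `per_residue_b` (or
#'   `per_atom_b`), `residue_index`, `mean_structure`.
#' @export
b_factors <- function(ens, per = c("residue", "atom"),
                      selection = c("all", "ca")) {
  per <- match.arg(per)
  selection <- match.arg(selection)
  if (n_frames(ens) < 2L) stop("B-factors need at least 2 frames")
  al <- align_frames_to_mean(ens$frames, ens$align_mask)
  m <- al$mean
  msd <- Reduce(`+`, lapply(al$frames, function(f) rowSums((f - m)^2))) /
    length(al$frames)
  b_atom <- (8 * pi^2 / 3) * msd
  sel <- if (selection == "ca") which(ens$topology$atom_name == "CA")
         else seq_along(b_atom)
  if (per == "atom") {
    out <- list(per_atom_b = b_atom[sel],
                atom_index = sel, mean_structure = m)
  } else {
    ri <- ens$topology$residue_index[sel]
    agg <- tapply(b_atom[sel], ri, mean)
    out <- list(per_residue_b = as.numeric(agg),
                residue_index = as.integer(names(agg)), mean_structure = m)
  }
  class(out) <- "FlexibilityProfile"
  out
}

#' Residue-residue contact map
#'
#' A pair (i, j), i < j, is a contact when the minimum inter-residue atom
#' distance (heavy atoms, or C-beta positions with C-alpha fallback) is at
#' most `cutoff` and the sequence separation `|i - j| >= min_seq_sep`.
#'
#' @param s a `Structure`.
#' @param cutoff distance cutoff in Angstrom (default 5.5).
#' @param min_seq_sep minimum sequence separation (default 2).
#' @param mode `"heavy_atom"` or `"cbeta"`.
#' @return a `ContactMap`: list with `pairs` (2-column matrix, i < j),
#'   `per_residue_counts` (named by residue index), `cutoff`,
#'   `min_seq_sep`, `n_residues`.
#' @export
contact_map <- function(s, cutoff = 5.5, min_seq_sep = 2L,
                        mode = c("heavy_atom", "cbeta")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_seq_sep < 1L) stop("min_seq_sep must be >= 1")
  sel <- .contact_atom_selection(s, mode)
  res <- s$residue_index[sel]
  X <- s$coords[sel, , drop = FALSE]
  dmin <- .min_residue_distances(X, res)
  resids <- sort(unique(s$residue_index))
  pairs <- dmin$pairs[dmin$d <= cutoff &
                        abs(dmin$pairs[, 1] - dmin$pairs[, 2]) >= min_seq_sep,
                      , drop = FALSE]
  counts <- integer(length(resids))
  names(counts) <- resids
  if (nrow(pairs)) {
    tab <- table(factor(c(pairs[, 1], pairs[, 2]), levels = resids))
    counts <- as.integer(tab)
    names(counts) <- resids
  }
  out <- list(pairs = pairs, per_residue_counts = counts,
              cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep),
              mode = mode, n_residues = length(resids))
  class(out) <- "ContactMap"
  out
}

.contact_atom_selection <- function(s, mode) {
  if (mode == "heavy_atom") {
    which(s$element != "H")
  } else {
    # C-beta, falling back to C-alpha (glycine or bead models)
    idx <- integer(0)
    for (r in unique(s$residue_index)) {
      at <- which(s$residue_index == r)
      cb <- at[s$atom_name[at] == "CB"]
      if (!length(cb)) cb <- at[s$atom_name[at] == "CA"]
      if (!length(cb)) cb <- at[1]
      idx <- c(idx, cb[1])
    }
    idx
  }
}

# minimum inter-residue distance for every residue pair
.min_residue_distances <- function(X, res) {
  D <- as.matrix(stats::dist(X))
  resids <- sort(unique(res))
  nr <- length(resids)
  f <- match(res, resids)
  # min over atom pairs, aggregated by residue pair
  agg <- matrix(Inf, nr, nr)
  for (a in seq_len(nrow(X))) {
    ra <- f[a]
    mins <- tapply(D[a, ], f, min)
    agg[ra, ] <- pmin(agg[ra, ], as.numeric(mins))
  }
  ij <- which(upper.tri(agg), arr.ind = TRUE)
  list(pairs = cbind(resids[ij[, 1]], resids[ij[, 2]]),
       d = agg[ij])
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley quadrature)
#'
#' Each atom's sphere is expanded by the probe radius and sampled with a
#' deterministic golden-spiral quadrature; points falling strictly inside
#' any other expanded sphere are buried. Coincident identical spheres do
#' not occlude each other (each reports its full area), a deterministic
#' convention rather than an error.
#'
#' @param s a `Structure`.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param n_points quadrature points per atom (>= 60; default 240).
#' @param trp_side_chain_only if `TRUE` (default), `trp_area` sums
#'   side-chain atoms (C-beta and beyond) of tryptophan residues; in
#'   one-bead-per-residue models the bead counts as the side chain.
#' @return a `SASAResult`: list with `per_atom_area`, `per_residue_area`,
#'   `residue_index`, `trp_area`, `probe_radius`, `n_points`.
#' @export
sasa <- function(s, probe_radius = 1.4, n_points = 240L,
                 trp_side_chain_only = TRUE) {
  if (n_points < 60L) stop("n_points must be >= 60")
  X <- s$coords
  n <- nrow(X)
  rexp <- s$radii + probe_radius
  pts <- .sphere_points(n_points)
  D2 <- as.matrix(stats::dist(X))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D2[i, ] < (rexp[i] + rexp)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * rexp[i]^2
      next
    }
    sp <- sweep(pts * rexp[i], 2, X[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(sp, 2, X[j, ])^2)
      exposed <- exposed & d2 >= (rexp[j]^2 - 1e-9)
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * rexp[i]^2 * sum(exposed) / n_points
  }
  resids <- sort(unique(s$residue_index))
  per_res <- as.numeric(tapply(area, factor(s$residue_index, levels = resids),
                               sum))
  trp_atoms <- which(s$residue_name == "TRP")
  if (length(trp_atoms) && trp_side_chain_only) {
    bb <- s$atom_name %in% c("N", "C", "O", "CA", "H", "HA", "OXT")
    sc <- trp_atoms[!bb[trp_atoms]]
    # bead models: a Trp residue whose only atom is backbone-named still
    # represents the whole residue
    for (r in unique(s$residue_index[trp_atoms])) {
      at <- trp_atoms[s$residue_index[trp_atoms] == r]
      if (!any(at %in% sc)) sc <- c(sc, at)
    }
    trp_atoms <- sort(sc)
  }
  out <- list(per_atom_area = area, per_residue_area = per_res,
              residue_index = resids,
              trp_area = sum(area[trp_atoms]),
              probe_radius = probe_radius, n_points = as.integer(n_points))
  class(out) <- "SASAResult"
  out
}

#' Summed Trp solvent accessibility of one conformation
#'
#' Convenience wrapper around [sasa()] returning only the summed
#' tryptophan side-chain accessible area, the quantity compared against
#' the 100-300 A^2 experimental window for the intermediate.
#'
#' @inheritParams sasa
#' @return Trp SASA in Angstrom^2.
#' @export
trp_sasa <- function(s, probe_radius = 1.4, n_points = 240L) {
  sasa(s, probe_radius, n_points)$trp_area
}
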