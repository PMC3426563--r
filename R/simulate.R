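# Synthetic-data generators. Every fixture the pipeline consumes can be
# produced here with planted ground truth, deterministically per seed.
# Toys are C-alpha bead chains built from helical columns on a grid:
# cores and (natively packed) loops are all helical segments, with the
# segment junction geometry solved so every consecutive bead pair is
# exactly 3.8 A apart. Sufficient for every quantity in scope
# (coordinates, contacts, curves); not a real protein.

.helix_dtheta <- function(step = 3.8, rise = 1.5, radius = 2.3) {
  2 * asin(sqrt(step^2 - rise^2) / (2 * radius))
}

# beads of one helical segment starting at height z0
.helix_beads <- function(n, center_xy, ascending = TRUE, z0 = 0,
                         rise = 1.5, radius = 2.3, phase = 0) {
  dth <- .helix_dtheta(rise = rise, radius = radius)
  i <- seq_len(n) - 1L
  z <- z0 + (if (ascending) rise * i else -rise * i)
  cbind(center_xy[1] + radius * cos(phase + dth * i),
        center_xy[2] + radius * sin(phase + dth * i),
        z)
}

.range_list <- function(x) {
  lapply(x, function(r) as.integer(r[1]):as.integer(r[2]))
}

#' Build a deterministic C-alpha bead toy protein
#'
#' The chain is laid out as a bundle of helical columns (2.3 A radius,
#' 1.5 A rise, exact 3.8 A consecutive-bead spacing), one column per
#' residue range, placed side by side and alternating in direction; this
#' holds for core ranges and for loop ranges alike, so that in the native
#' conformation loops pack against their neighbouring cores and carry
#' native contacts (which disordering generators can then break). The
#' phase and height of every column after the first are solved so the
#' bond joining it to the previous segment is also exactly 3.8 A. The
#' seed only rotates the first column's phase; the construction is
#' otherwise deterministic, and any steric clash (< 2 A between
#' non-consecutive beads) is an error.
#'
#' @param n_residues chain length.
#' @param core_ranges list of `c(start, end)` residue ranges forming the
#'   rigid core (>= 1 range).
#' @param loop_ranges list of `c(start, end)` flexible ranges; together
#'   with the cores they must tile `1..n_residues`.
#' @param trp_positions residue indices labelled TRP.
#' @param seed RNG seed (first-column phase; same seed, same coordinates).
#' @param helix_spacing centre-to-centre distance of neighbouring
#'   columns, Angstrom (default 8: facing beads of neighbouring columns
#'   sit ~3.4 A apart and form inter-segment contacts).
#' @return a `Structure` (one CA bead per residue) with a
#'   `"loop_residues"` attribute.
#' @export
make_toy_protein <- function(n_residues, core_ranges, loop_ranges = list(),
                             trp_positions = integer(0), seed = 1L,
                             helix_spacing = 8) {
  cores <- .range_list(core_ranges)
  loops <- .range_list(loop_ranges)
  segs <- c(lapply(cores, function(x) list(idx = x, kind = "core")),
            lapply(loops, function(x) list(idx = x, kind = "loop")))
  segs <- segs[order(vapply(segs, function(s) s$idx[1], numeric(1)))]
  covered <- unlist(lapply(segs, `[[`, "idx"))
  if (!identical(sort(covered), seq_len(n_residues)) ||
      anyDuplicated(covered)) {
    stop("core and loop ranges must tile 1..n_residues without overlap")
  }
  if (!any(vapply(segs, function(s) s$kind == "core", logical(1)))) {
    stop("need at least one core range")
  }
  rs <- .local_rng(seed)
  coords <- matrix(NA_real_, n_residues, 3)
  radius <- 2.3
  prev_end <- NULL
  cxy <- c(0, 0)
  for (si in seq_along(segs)) {
    s <- segs[[si]]
    n <- length(s$idx)
    ascending <- si %% 2L == 1L
    if (si == 1L) {
      phase <- 2 * pi * rs$unif(1)
      z0 <- 0
    } else {
      # the next column is dropped along the direction the previous end
      # bead faces, so its first bead (facing back) can always close the
      # junction; the height offset makes the junction bond exactly 3.8
      out_dir <- prev_end[1:2] - cxy
      out_dir <- out_dir / sqrt(sum(out_dir^2))
      cxy <- cxy + helix_spacing * out_dir
      phase <- atan2(prev_end[2] - cxy[2], prev_end[1] - cxy[1])
      b0_xy <- cxy + radius * c(cos(phase), sin(phase))
      h2 <- sum((b0_xy - prev_end[1:2])^2)
      if (h2 > 3.8^2) {
        stop("helix_spacing too large: junction bond cannot reach 3.8 A")
      }
      dz <- sqrt(3.8^2 - h2)
      z0 <- prev_end[3] + if (ascending) dz else -dz
    }
    coords[s$idx, ] <- .helix_beads(n, cxy, ascending, z0, phase = phase)
    prev_end <- coords[s$idx[n], ]
  }
  D <- as.matrix(stats::dist(coords))
  sep <- abs(outer(seq_len(n_residues), seq_len(n_residues), `-`))
  if (any(D[sep > 1L & upper.tri(D)] < 2.0)) {
    stop("infeasible geometry: non-consecutive beads closer than 2 A")
  }
  resname <- rep("ALA", n_residues)
  resname[trp_positions] <- "TRP"
  out <- new_structure(coords, atom_name = rep("CA", n_residues),
                       residue_index = seq_len(n_residues),
                       residue_name = resname, element = "C")
  attr(out, "loop_residues") <- unlist(loops)
  out
}

# orthonormal basis of the 6 rigid-body motions (3 translations, 3
# infinitesimal rotations about the centroid) of a structure
.rigid_basis <- function(coords) {
  n <- nrow(coords)
  Xc <- sweep(coords, 2, colMeans(coords))
  Tx <- rep(c(1, 0, 0), n); Ty <- rep(c(0, 1, 0), n); Tz <- rep(c(0, 0, 1), n)
  rot <- function(ax) as.vector(t(Xc %*% rbind(
    c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))))
  B <- cbind(Tx, Ty, Tz, rot(c(1, 0, 0)), rot(c(0, 1, 0)), rot(c(0, 0, 1)))
  qr.Q(qr(B))
}

#' Sample a correlated-Gaussian ensemble around a reference structure
#'
#' Frames are `ref + sum_k z_k v_k + eps` with `z_k ~ N(0, lambda_k)`
#' along orthonormalised planted directions and isotropic per-coordinate
#' noise `eps ~ N(0, sigma^2)`. The planted modes are the ground truth
#' for essential-dynamics recovery tests.
#'
#' @param ref reference `Structure`.
#' @param mode_spec list of `list(v = 3N vector, lambda = variance A^2)`.
#' @param isotropic_noise noise sigma per coordinate, Angstrom.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @return an `Ensemble`; `attr(, "ground_truth")` holds the
#'   orthonormalised `modes` matrix and `lambdas`.
#' @export
sample_gaussian_ensemble <- function(ref, mode_spec, isotropic_noise = 0.1,
                                     n_frames, seed = 1L) {
  if (n_frames < 2L) stop("need at least 2 frames")
  n3 <- 3L * n_atoms(ref)
  V <- do.call(cbind, lapply(mode_spec, function(m) as.numeric(m$v)))
  if (nrow(V) != n3) stop("mode vectors must have length 3N")
  # project out rigid-body motions: superposition during analysis removes
  # them, so only internal deformations are recoverable ground truth
  Rb <- .rigid_basis(ref$coords)
  V <- V - Rb %*% crossprod(Rb, V)
  V <- qr.Q(qr(V))
  lam <- vapply(mode_spec, function(m) m$lambda, numeric(1))
  if (isotropic_noise > 0 && any(lam > 0 & lam <= isotropic_noise^2)) {
    warning("planted variances at or below the noise floor")
  }
  rs <- .local_rng(seed)
  ref_vec <- as.vector(t(ref$coords))
  frames <- lapply(seq_len(n_frames), function(i) {
    z <- rs$norm(length(lam)) * sqrt(lam)
    eps <- rs$norm(n3) * isotropic_noise
    matrix(ref_vec + as.vector(V %*% z) + eps, ncol = 3, byrow = TRUE)
  })
  ens <- new_ensemble(ref, frames)
  attr(ens, "ground_truth") <- list(modes = V, lambdas = lam)
  ens
}

# independent (of the contact_map module) native-contact bookkeeping used
# for generator ground truth: plain bead-distance cutoff
.gt_native_pairs <- function(coords, cutoff, min_seq_sep) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - min_seq_sep)) {
    for (j in (i + min_seq_sep):n) {
      if (sum((coords[i, ] - coords[j, ])^2) <= cutoff^2) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

#' Loop-disordered ensemble with planted contact retention
#'
#' Emulates a partially unfolded state with an intact core and disordered
#' loops. Core beads receive a small jitter (norm clipped at 0.5 A). Each
#' loop bead is, per frame, kept near its native position with its
#' planted retention probability, or displaced by an isotropic random
#' vector of scale `amplitude` (re-drawn up to 10 times if it lands
#' within 2 A of another bead). The realised per-residue native-contact
#' retention, measured post hoc with an independent distance routine, is
#' recorded as ground truth.
#'
#' @param native native `Structure`.
#' @param loop_ranges list of `c(start, end)` flexible ranges.
#' @param retention per-residue contact-retention probability: scalar for
#'   all loop residues, or a full-length vector (core residues are
#'   implicitly 1).
#' @param amplitude loop displacement scale, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param core_jitter sigma of the core jitter (norm clipped at 0.5 A).
#' @param contact_cutoff,min_seq_sep contact definition used for the
#'   realised-retention ground truth (keep equal to the analysis
#'   contact-map parameters).
#' @return an `Ensemble`; `attr(, "ground_truth")` holds `native_pairs`,
#'   `realized_retention` (per residue; NA where a residue has no native
#'   contacts), `retention_input`, `loop_residues`.
#' @export
make_disordered_ensemble <- function(native, loop_ranges, retention = 0.1,
                                     amplitude = 5, n_frames, seed = 1L,
                                     core_jitter = 0.15,
                                     contact_cutoff = 5.5,
                                     min_seq_sep = 2L) {
  n <- n_atoms(native)
  loops <- unlist(.range_list(loop_ranges))
  p_keep <- rep(1, n)
  if (length(retention) == 1L) {
    p_keep[loops] <- retention
  } else {
    if (length(retention) != n) stop("retention must be scalar or length N")
    p_keep <- retention
  }
  if (any(p_keep < 0 | p_keep > 1)) stop("retention must lie in [0, 1]")
  rs <- .local_rng(seed)
  X0 <- native$coords
  jitter_vec <- function(sigma, clip = 0.5) {
    v <- rs$norm(3) * sigma
    nv <- sqrt(sum(v^2))
    if (nv > clip) v <- v * clip / nv
    v
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    X <- X0
    for (i in seq_len(n)) X[i, ] <- X[i, ] + jitter_vec(core_jitter)
    move <- loops[rs$unif(length(loops)) > p_keep[loops]]
    for (i in move) {
      for (try in 1:10) {
        cand <- X0[i, ] + rs$norm(3) * amplitude / sqrt(3)
        d2 <- rowSums(sweep(X[-i, , drop = FALSE], 2, cand)^2)
        if (min(d2) >= 4) break
      }
      X[i, ] <- cand
    }
    frames[[f]] <- X
  }
  core_idx <- setdiff(seq_len(n), loops)
  ens <- new_ensemble(native, frames, align_mask = core_idx)
  pairs <- .gt_native_pairs(X0, contact_cutoff, min_seq_sep)
  kept_frac <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    kept_frac[k] <- mean(vapply(frames, function(X)
      sum((X[i, ] - X[j, ])^2) <= contact_cutoff^2, logical(1)))
  }
  realized <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    inv <- which(pairs[, 1] == i | pairs[, 2] == i)
    if (length(inv)) realized[i] <- mean(kept_frac[inv])
  }
  attr(ens, "ground_truth") <- list(native_pairs = pairs,
                                    realized_retention = realized,
                                    retention_input = p_keep,
                                    loop_residues = loops)
  ens
}

#' Default sequential three-state model of thermal unfolding
#'
#' Gibbs-Helmholtz parameters chosen once to emulate a three-state
#' thermal folder with a well-populated intermediate: transition
#' midpoints 318 K (N to I) and 334 K (I to U) with van 't Hoff
#' enthalpies of 300 and 330 kJ/mol (dCp = 0). The intermediate peaks
#' near 0.9 population around 326 K.
#'
#' @return a `ThreeStateModel`.
#' @export
default_three_state_model <- function() {
  three_state_model(params1 = list(dH = 300, Tm = 318, dCp = 0),
                    params2 = list(dH = 330, Tm = 334, dCp = 0))
}

#' Three bundled SAXS component curves from toy structures
#'
#' Deterministic native-like (compact two-helix toy), intermediate-like
#' (same core with loops pushed outward) and unfolded-like (extended
#' chain) bead structures, scattered with the Debye formula and
#' normalised to I(0) = 1.
#'
#' @param grid momentum-transfer grid, 1/Angstrom (default: 25 points
#'   spanning 0.07-0.31).
#' @return list with `S` (3 x grid matrix, rows native/intermediate/
#'   unfolded), `grid`, `structures`.
#' @export
toy_saxs_components <- function(grid = seq(0.07, 0.31, length.out = 25)) {
  native <- make_toy_protein(60, list(c(1, 20), c(41, 60)),
                             list(c(21, 40)), seed = 101L)
  ctr <- colMeans(native$coords)
  interm <- native
  loopi <- 21:40
  interm$coords[loopi, ] <- ctr +
    sweep(interm$coords[loopi, , drop = FALSE], 2, ctr) * 1.6
  ext <- native
  ext$coords <- cbind(3.8 * (seq_len(60) - 1), 2 * sin(seq_len(60) / 3),
                      2 * cos(seq_len(60) / 4))
  structs <- list(native = native, intermediate = interm, unfolded = ext)
  S <- t(vapply(structs, function(s) {
    cv <- debye_curve(s, grid)
    cv$intensity / debye_curve(s, 0)$intensity
  }, numeric(length(grid))))
  rownames(S) <- names(structs)
  list(S = S, grid = grid, structures = structs)
}

#' Temperature-series SAXS dataset as a noisy three-component mixture
#'
#' Rows are `sum_i X_i(T) S_i(s)` with populations from the three-state
#' model, times multiplicative Gaussian noise `(1 + N(0, noise_frac))`.
#'
#' @param components 3 x grid matrix of component curves (or a list of 3
#'   `SAXSCurve`s on a shared grid).
#' @param population_model a `ThreeStateModel`.
#' @param temperatures temperatures in K.
#' @param s the shared momentum-transfer grid (required when
#'   `components` is a matrix).
#' @param noise_frac multiplicative noise sd (>= 0).
#' @param seed RNG seed.
#' @return a `SAXSDataset`; `attr(, "ground_truth")` holds the
#'   population matrix `C` and component matrix `S`.
#' @export
make_saxs_mixture <- function(components, population_model, temperatures,
                              s = NULL, noise_frac = 0, seed = 1L) {
  if (is.list(components) && inherits(components[[1]], "SAXSCurve")) {
    s <- components[[1]]$s
    S <- t(vapply(components, function(cv) cv$intensity,
                  numeric(length(s))))
  } else {
    S <- as.matrix(components)
    if (is.null(s)) stop("give the shared s grid")
  }
  if (nrow(S) != 3L) stop("expect exactly 3 component curves")
  if (noise_frac < 0) stop("noise_frac must be >= 0")
  X <- populations(population_model, temperatures)
  D <- X %*% S
  if (noise_frac > 0) {
    rs <- .local_rng(seed)
    D <- D * (1 + matrix(rs$norm(length(D)) * noise_frac, nrow(D), ncol(D)))
    D[D < 0] <- 0
  }
  ds <- new_saxs_dataset(D, temperatures, s)
  attr(ds, "ground_truth") <- list(C = X, S = S)
  ds
}

#' Deterministic pure near-UV state spectra for the toy world
#'
#' Smooth Gaussian absorbance bands over 250-310 nm whose amplitude and
#' peak position shift from native through intermediate to unfolded,
#' mimicking the loss of tertiary-contact fine structure.
#'
#' @param wavelengths nm grid (default 250-310 in 1 nm steps).
#' @return list with `wavelengths`, `Y_N`, `Y_I`, `Y_U`.
#' @export
toy_pure_spectra <- function(wavelengths = 250:310) {
  band <- function(center, width, height, shoulder) {
    height * exp(-(wavelengths - center)^2 / (2 * width^2)) +
      shoulder * exp(-(wavelengths - 292)^2 / (2 * 3^2))
  }
  list(wavelengths = wavelengths,
       Y_N = band(278, 9, 1.00, 0.12),
       Y_I = band(280, 11, 0.90, 0.05),
       Y_U = band(283, 14, 0.78, 0.00))
}

#' Temperature-series spectra from pure state spectra and populations
#'
#' `Y(lambda, T) = sum_i X_i(T) Y_i(lambda) + N(0, noise)`.
#'
#' @param pure list with `wavelengths`, `Y_N`, `Y_I`, `Y_U` (see
#'   [toy_pure_spectra()]).
#' @param model a `ThreeStateModel`.
#' @param temperatures temperatures in K.
#' @param noise additive Gaussian noise sd (absorbance units).
#' @param seed RNG seed.
#' @return a `SpectraSeries`; `attr(, "ground_truth")` holds the pure
#'   spectra matrix and population matrix.
#' @export
make_spectra_series <- function(pure, model, temperatures, noise = 0,
                                seed = 1L) {
  X <- populations(model, temperatures)
  Ypure <- rbind(pure$Y_N, pure$Y_I, pure$Y_U)
  Y <- t(X %*% Ypure)   # wavelengths x temperatures
  if (noise > 0) {
    rs <- .local_rng(seed)
    Y <- Y + matrix(rs$norm(length(Y)) * noise, nrow(Y), ncol(Y))
  }
  series <- new_spectra_series(pure$wavelengths, temperatures, Y)
  attr(series, "ground_truth") <- list(Y_pure = Ypure, C = X)
  series
}

#' Synthetic three-population world for intermediate annotation
#'
#' Builds a complete annotated-filter test bed with planted ground truth:
#' a toy native structure whose four Trp beads sit on the core face
#' swept by the loop; a mixed ensemble of native-like frames (small
#' jitter), intermediate-like frames (core intact, loops fully
#' disordered) and unfolded-like frames (noisy extended chain) in
#' planted proportions; an "experimental" intermediate SAXS curve
#' (ensemble-average Debye curve of an independent intermediate sample,
#' 7 percent homogeneous errors) and an "experimental" phi profile (mean
#' phi of another independent intermediate sample).
#'
#' @param seed RNG seed controlling every stochastic choice.
#' @param n_frames total frames in the mixed ensemble.
#' @param fractions length-3 numeric (native, intermediate, unfolded)
#'   summing to 1.
#' @param amplitude loop displacement scale of the intermediate state.
#' @param contact_cutoff native contact cutoff, Angstrom. Default 5.3:
#'   with the toy helix geometry (i, i+2 pairs at 5.45 A, i, i+3 at
#'   5.12 A) this keeps every native contact at least ~0.2 A away from
#'   the threshold, so the small native/core jitter cannot make contacts
#'   flicker and inflate the per-frame phi-error variance.
#' @param core_jitter core bead jitter sigma of all generated states.
#' @param n_ref_frames frames used for the synthetic experimental
#'   references.
#' @return list with `native`, `ensemble`, `labels`, `native_map`,
#'   `exp_phi`, `exp_saxs`, `grid`, `loop_ranges`, `trp_positions`,
#'   `fractions`.
#' @export
toy_intermediate_world <- function(seed = 1L, n_frames = 500L,
                                   fractions = c(native = 0.5,
                                                 intermediate = 0.3,
                                                 unfolded = 0.2),
                                   amplitude = 12,
                                   contact_cutoff = 5.3,
                                   core_jitter = 0.05,
                                   n_ref_frames = 150L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  loop_ranges <- list(c(21, 40))
  base <- make_toy_protein(60, list(c(1, 20), c(41, 60)), loop_ranges,
                           seed = derive_seed(seed, 1))
  # choose 4 Trp beads on helix 1: core-only exposure nearest 55 A^2
  # (in-window once the loop clears), sequence separation >= 3
  core_only <- base
  keep <- setdiff(seq_len(60), 21:40)
  core_only$coords <- base$coords[keep, , drop = FALSE]
  core_only$atom_name <- base$atom_name[keep]
  core_only$residue_index <- base$residue_index[keep]
  core_only$residue_name <- base$residue_name[keep]
  core_only$element <- base$element[keep]
  core_only$radii <- base$radii[keep]
  sr <- sasa(core_only, n_points = 240L)
  helix1 <- which(sr$residue_index >= 3 & sr$residue_index <= 18)
  cand <- sr$residue_index[helix1][order(abs(sr$per_residue_area[helix1] - 55))]
  trp <- integer(0)
  for (r in cand) {
    if (all(abs(trp - r) >= 3)) trp <- c(trp, r)
    if (length(trp) == 4L) break
  }
  native <- make_toy_protein(60, list(c(1, 20), c(41, 60)), loop_ranges,
                             trp_positions = trp,
                             seed = derive_seed(seed, 1))
  native_map <- contact_map(native, cutoff = contact_cutoff)
  grid <- seq(0.07, 0.31, length.out = 25)

  make_int <- function(n, sd) {
    make_disordered_ensemble(native, loop_ranges, retention = 0,
                             amplitude = amplitude, n_frames = n,
                             seed = sd, core_jitter = core_jitter,
                             contact_cutoff = contact_cutoff)
  }
  # synthetic experimental references from independent intermediate draws
  ref_saxs_ens <- make_int(n_ref_frames, derive_seed(seed, 2))
  Imean <- Reduce(`+`, lapply(ref_saxs_ens$frames, function(X)
    debye_curve(X, grid)$intensity)) / n_ref_frames
  exp_saxs <- new_saxs_curve(grid, Imean, 0.07 * Imean)
  ref_phi_ens <- make_int(n_ref_frames, derive_seed(seed, 3))
  exp_phi <- phi_ensemble(ref_phi_ens, native_map)
  exp_phi$source <- "experimental"

  counts <- round(n_frames * fractions)
  counts[1] <- n_frames - sum(counts[-1])
  rs <- .local_rng(derive_seed(seed, 4))
  nat_ens <- make_disordered_ensemble(native, loop_ranges, retention = 1,
                                      amplitude = 0, n_frames = counts[1],
                                      seed = derive_seed(seed, 5),
                                      core_jitter = core_jitter,
                                      contact_cutoff = contact_cutoff)
  int_ens <- make_int(counts[2], derive_seed(seed, 6))
  ext0 <- cbind(3.8 * (seq_len(60) - 1), 2.5 * sin(seq_len(60) / 3),
                2.5 * cos(seq_len(60) / 4))
  unf_frames <- lapply(seq_len(counts[3]), function(i)
    ext0 + matrix(rs$norm(180), 60, 3) * 1.5)
  frames <- c(nat_ens$frames, int_ens$frames, unf_frames)
  labels <- rep(c("native", "intermediate", "unfolded"), counts)
  ord <- rs$sample(length(frames), length(frames))
  ens <- new_ensemble(native, frames[ord],
                      frame_labels = labels[ord],
                      align_mask = setdiff(seq_len(60), 21:40))
  list(native = native, ensemble = ens, labels = labels[ord],
       native_map = native_map, exp_phi = exp_phi, exp_saxs = exp_saxs,
       grid = grid, loop_ranges = loop_ranges, trp_positions = trp,
       fractions = fractions)
}
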