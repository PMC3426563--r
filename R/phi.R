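#' Construct a phi-value profile
#'
#' @param residue_index 1-based residue numbers.
#' @param phi per-residue phi values (>= 0; `NA` marks residues where phi
#'   is undefined, e.g. no native contacts).
#' @param n_native optional per-residue native contact counts.
#' @param source `"calculated"` or `"experimental"`.
#' @return a `PhiProfile`.
#' @export
new_phi_profile <- function(residue_index, phi, n_native = NULL,
                            source = c("calculated", "experimental")) {
  source <- match.arg(source)
  if (length(residue_index) != length(phi)) stop("length mismatch")
  if (any(phi < 0, na.rm = TRUE)) stop("phi values must be >= 0")
  out <- list(residue_index = as.integer(residue_index),
              phi = as.numeric(phi),
              n_native = n_native, source = source)
  class(out) <- "PhiProfile"
  out
}

#' Per-residue phi values of a snapshot from native-contact retention
#'
#' For each residue i, `phi_i = N_i / N_i_nat`: the number of native
#' contact pairs involving i that are still present in the snapshot,
#' divided by the residue's native contact count. Only native pairs are
#' examined; contacts absent from the native map are ignored. Residues
#' with no native contacts have undefined phi (`NA`), not zero.
#'
#' @param snapshot a `Structure` sharing residue numbering with the map.
#' @param native a `ContactMap` of the native (crystal) structure.
#' @param tolerance_factor multiplier on the native cutoff used when
#'   testing contact presence in the snapshot (default 1: same cutoff).
#' @return a `PhiProfile` with `source = "calculated"`.
#' @export
phi_calc <- function(snapshot, native, tolerance_factor = 1) {
  resids <- sort(unique(snapshot$residue_index))
  map_res <- as.integer(names(native$per_residue_counts))
  if (!all(map_res %in% resids)) {
    stop("snapshot and native map have mismatched residue sets")
  }
  present <- .native_pairs_present(snapshot, native, tolerance_factor)
  nn <- native$per_residue_counts
  cnt <- integer(length(map_res))
  names(cnt) <- map_res
  if (any(present)) {
    kept <- native$pairs[present, , drop = FALSE]
    tab <- table(factor(c(kept[, 1], kept[, 2]), levels = map_res))
    cnt <- as.integer(tab)
  }
  phi <- ifelse(nn > 0, cnt / nn, NA_real_)
  new_phi_profile(map_res, phi, n_native = as.integer(nn),
                  source = "calculated")
}

# logical vector over native$pairs: is each native pair within cutoff in
# the snapshot (per the native map's distance mode)?
.native_pairs_present <- function(snapshot, native, tolerance_factor = 1) {
  sel <- .contact_atom_selection(snapshot, native$mode)
  res <- snapshot$residue_index[sel]
  X <- snapshot$coords[sel, , drop = FALSE]
  cutoff <- native$cutoff * tolerance_factor
  if (!nrow(native$pairs)) return(logical(0))
  vapply(seq_len(nrow(native$pairs)), function(k) {
    ai <- which(res == native$pairs[k, 1])
    aj <- which(res == native$pairs[k, 2])
    d2min <- min(vapply(ai, function(a)
      min(rowSums(sweep(X[aj, , drop = FALSE], 2, X[a, ])^2)), numeric(1)))
    d2min <= cutoff^2
  }, logical(1))
}

#' Mean phi profile over an ensemble
#'
#' Averages [phi_calc()] over frames (equivalently, averages per-pair
#' contact indicators), returning the ensemble phi profile.
#'
#' @param ens an `Ensemble`.
#' @param native a native `ContactMap`.
#' @param tolerance_factor see [phi_calc()].
#' @return a `PhiProfile`.
#' @export
phi_ensemble <- function(ens, native, tolerance_factor = 1) {
  profs <- lapply(seq_len(n_frames(ens)), function(i)
    phi_calc(frame_structure(ens, i), native, tolerance_factor)$phi)
  m <- Reduce(`+`, lapply(profs, function(p) ifelse(is.na(p), 0, p))) /
    length(profs)
  m[is.na(profs[[1]])] <- NA_real_
  new_phi_profile(as.integer(names(native$per_residue_counts)), m,
                  n_native = as.integer(native$per_residue_counts),
                  source = "calculated")
}

#' Accumulated error between calculated and experimental phi profiles
#'
#' Signed sum of `phi_calc - phi_exp` over the included residues:
#' residues with experimental phi < 1, a defined calculated phi, and not
#' in the exclusion mask (e.g. a helix with unreliable experimental
#' determinations). Positive totals mean the conformation is too
#' native-like; negative totals, too unfolded. The absolute accumulated
#' error `|signed_sum|` is the quantity thresholded by the intermediate
#' annotation criteria; the sum of per-residue absolute differences is
#' also reported as an alternative metric.
#'
#' @param calc calculated `PhiProfile`.
#' @param exp_profile experimental `PhiProfile` on the same residue
#'   numbering.
#' @param exclude residue indices excluded from the sum.
#' @return a `PhiErrorReport`: list with `signed_sum`, `abs_sum`,
#'   `abs_diff_sum`, `included_residues`.
#' @export
phi_error <- function(calc, exp_profile, exclude = integer(0)) {
  common <- intersect(calc$residue_index, exp_profile$residue_index)
  ic <- match(common, calc$residue_index)
  ie <- match(common, exp_profile$residue_index)
  pc <- calc$phi[ic]
  pe <- exp_profile$phi[ie]
  keep <- !is.na(pc) & !is.na(pe) & pe < 1 & !(common %in% exclude)
  if (!any(keep)) stop("no residues left after exclusions")
  signed <- sum(pc[keep] - pe[keep])
  out <- list(signed_sum = signed, abs_sum = abs(signed),
              abs_diff_sum = sum(abs(pc[keep] - pe[keep])),
              included_residues = common[keep])
  class(out) <- "PhiErrorReport"
  out
}
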