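.as_coords <- function(x) {
  if (inherits(x, "Structure")) x$coords else unname(as.matrix(x))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Rotates and translates `mobile` so that the atoms in `mask` are
#' superposed onto `reference` with minimum RMSD. The rotation is always
#' proper (determinant +1).
#'
#' @param mobile coordinates to move (n x 3 matrix or `Structure`).
#' @param reference target coordinates, same atom count.
#' @param mask atom indices used for the fit (default: all). Must contain
#'   at least 3 non-collinear points.
#' @return list with `coords` (all transformed mobile coordinates),
#'   `rmsd` (over the mask, Angstrom), `rotation`, `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  X <- .as_coords(mobile)
  Y <- .as_coords(reference)
  if (nrow(X) != nrow(Y)) stop("coordinate sets differ in atom count")
  if (is.null(mask)) mask <- seq_len(nrow(X))
  if (length(mask) < 3L) stop("mask must contain at least 3 atoms")
  Xm <- X[mask, , drop = FALSE]
  Ym <- Y[mask, , drop = FALSE]
  cx <- colMeans(Xm); cy <- colMeans(Ym)
  A <- sweep(Xm, 2, cx); B <- sweep(Ym, 2, cy)
  # collinear/coincident mask points give a rank-deficient problem
  if (qr(A)$rank < 2L || qr(B)$rank < 2L) {
    stop("degenerate mask: points are collinear or coincident")
  }
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  coords <- sweep(X, 2, cx) %*% t(R)
  coords <- sweep(coords, 2, cy, `+`)
  fit <- coords[mask, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fit - Ym)^2)))
  list(coords = coords, rmsd = rmsd, rotation = R,
       translation = cy - as.vector(R %*% cx))
}

#' RMSD between two coordinate sets after optimal superposition
#' @inheritParams kabsch_superpose
#' @export
rmsd_fit <- function(mobile, reference, mask = NULL) {
  kabsch_superpose(mobile, reference, mask)$rmsd
}

# Superpose every frame on the running mean until self-consistent.
# Returns the list of aligned frames and the converged mean. The alignment
# mask defines the common reference system (structurally conserved region).
align_frames_to_mean <- function(frames, mask, tol = 1e-6, max_iter = 50L) {
  ref <- frames[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(frames, function(f)
      kabsch_superpose(f, ref, mask)$coords)
    m <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(mean((m - ref)^2))
    ref <- m
    if (delta < tol) break
  }
  list(frames = aligned, mean = ref)
}

# Align every frame of an ensemble onto a fixed reference structure using
# the ensemble's align_mask.
align_frames_to_reference <- function(ens, reference) {
  ref <- .as_coords(reference)
  lapply(ens$frames, function(f)
    kabsch_superpose(f, ref, ens$align_mask)$coords)
}

tm_d0 <- function(L) 1.24 * (L - 15)^(1 / 3) - 1.8

.tm_score_given <- function(mob, ref, d0) {
  d <- sqrt(rowSums((mob - ref)^2))
  mean(1 / (1 + (d / d0)^2))
}

#' Template-modelling score between two conformations
#'
#' Length-normalised structural similarity on C-alpha positions,
#' `TM = max over superpositions of mean(1 / (1 + (d_i/d0)^2))` with
#' `d0 = 1.24 (L-15)^(1/3) - 1.8`. The maximisation uses seed-fragment
#' superpositions followed by iterative refinement on the residues
#' currently within `d0`, the standard heuristic.
#'
#' @param model,reference C-alpha coordinate matrices (or `Structure`s
#'   whose atoms are one bead per residue), equal residue counts > 15.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference) {
  X <- .as_coords(model)
  Y <- .as_coords(reference)
  if (nrow(X) != nrow(Y)) stop("residue counts differ")
  L <- nrow(X)
  if (L <= 15L) stop("TM-score d0 undefined for length <= 15")
  d0 <- tm_d0(L)

  candidates <- list()
  refine <- function(mask) {
    sc <- 0
    coords <- X
    for (it in 1:20) {
      fit <- tryCatch(kabsch_superpose(X, Y, mask), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      coords <- fit$coords
      d <- sqrt(rowSums((coords - Y)^2))
      sc <- mean(1 / (1 + (d / d0)^2))
      new_mask <- which(d < max(d0, 3))
      if (length(new_mask) < 3L) new_mask <- order(d)[1:4]
      if (identical(new_mask, mask)) break
      mask <- new_mask
    }
    list(score = sc, coords = coords)
  }

  seed_lens <- unique(pmax(4L, c(L, L %/% 2L, L %/% 4L)))
  for (len in seed_lens) {
    starts <- seq(1L, L - len + 1L, by = max(1L, len %/% 2L))
    for (st in starts) {
      r <- refine(st:(st + len - 1L))
      if (!is.null(r)) candidates[[length(candidates) + 1L]] <- r
    }
  }
  scores <- vapply(candidates, `[[`, numeric(1), "score")
  best <- max(scores)

  # polish the top candidates: maximise the TM sum itself over an
  # incremental rigid motion (the seed masks optimise RMSD on a hard
  # subset, not the soft TM objective)
  tm_obj <- function(p, M0) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    R <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)) %*%
      rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb)) %*%
      rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
    M <- sweep(M0 %*% t(R), 2, p[4:6], `+`)
    -mean(1 / (1 + rowSums((M - Y)^2) / d0^2))
  }
  for (ci in order(scores, decreasing = TRUE)[seq_len(min(5L,
                                                          length(scores)))]) {
    pol <- stats::optim(rep(0, 6), tm_obj, M0 = candidates[[ci]]$coords,
                        method = "BFGS", control = list(maxit = 200))
    best <- max(best, -pol$value)
  }
  best
}
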