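#' Cartesian covariance matrix of an ensemble
#'
#' Frames are first superposed either onto a fixed reference structure
#' (the common reference system, recommended when two ensembles will be
#' compared) or onto the iteratively refined ensemble mean, always using
#' the ensemble's alignment mask. The covariance of the 3N coordinate
#' vector is then computed about the ensemble mean with the 1/n
#' (population) normalisation, so that `trace(C)` equals the summed
#' per-coordinate variances and `3/(8 pi^2) * sum(B_i)` over atoms.
#'
#' @param ens an `Ensemble` with >= 2 frames.
#' @param selection atom indices entering the covariance (default: all).
#' @param reference optional `Structure` (or coordinate matrix) defining
#'   the common reference system.
#' @return symmetric positive semi-definite `3N x 3N` matrix.
#' @export
covariance_matrix <- function(ens, selection = NULL, reference = NULL) {
  if (n_frames(ens) < 2L) stop("covariance needs at least 2 frames")
  if (is.null(selection)) selection <- seq_len(n_atoms(ens$topology))
  frames <- if (is.null(reference)) {
    align_frames_to_mean(ens$frames, ens$align_mask)$frames
  } else {
    align_frames_to_reference(ens, reference)
  }
  M <- t(vapply(frames, function(f) as.vector(t(f[selection, , drop = FALSE])),
                numeric(3L * length(selection))))
  M <- sweep(M, 2, colMeans(M))
  C <- crossprod(M) / nrow(M)
  (C + t(C)) / 2
}

#' Diagonalise a covariance matrix into an essential space
#'
#' @param cov symmetric PSD matrix (3N x 3N).
#' @param n_modes number of modes to keep; alternatively give
#'   `variance_target` and the smallest mode count reaching that
#'   cumulative variance fraction is kept.
#' @param variance_target cumulative explained-variance fraction in (0,1].
#' @return an `EssentialSpace`: list with `eigenvectors` (orthonormal
#'   columns), `eigenvalues` (descending, >= 0, Angstrom^2), `n_atoms`,
#'   `variance_explained` (cumulative fractions for the kept modes).
#' @export
essential_space <- function(cov, n_modes = NULL, variance_target = NULL) {
  cov <- as.matrix(cov)
  e <- eigen(cov, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  cumfrac <- if (total > 0) cumsum(vals) / total else rep(1, length(vals))
  if (is.null(n_modes)) {
    if (is.null(variance_target)) {
      stop("give n_modes or variance_target")
    }
    n_modes <- which(cumfrac >= variance_target)[1]
  }
  if (n_modes > ncol(cov)) stop("n_modes exceeds matrix dimension")
  out <- list(eigenvectors = e$vectors[, seq_len(n_modes), drop = FALSE],
              eigenvalues = vals[seq_len(n_modes)],
              n_atoms = ncol(cov) %/% 3L,
              variance_explained = cumfrac[seq_len(n_modes)])
  class(out) <- "EssentialSpace"
  out
}

# essential space of an ensemble in one call
ed_space <- function(ens, n_modes, selection = NULL, reference = NULL) {
  essential_space(covariance_matrix(ens, selection, reference),
                  n_modes = n_modes)
}

.space_vectors <- function(x, n) {
  V <- if (inherits(x, "EssentialSpace")) x$eigenvectors else as.matrix(x)
  if (ncol(V) < n) stop("essential space has only ", ncol(V),
                        " modes; ", n, " requested")
  V[, seq_len(n), drop = FALSE]
}

#' Hess similarity between two essential subspaces
#'
#' `gamma = (1/n) * sum_{i,j<=n} (v_i^A . v_j^B)^2`, the mean squared
#' overlap between the first `n` eigenvectors of each space; 1 for
#' identical subspaces, 0 for orthogonal ones, symmetric in A and B.
#'
#' @param A,B `EssentialSpace` objects (or eigenvector matrices) over the
#'   same 3N coordinates.
#' @param n size of the common essential space (default 50).
#' @return gamma in `[0, 1]`.
#' @export
hess_similarity <- function(A, B, n = 50L) {
  VA <- .space_vectors(A, n)
  VB <- .space_vectors(B, n)
  if (nrow(VA) != nrow(VB)) stop("spaces have different 3N dimension")
  sum(crossprod(VA, VB)^2) / n
}

#' Monte-Carlo null distribution of the Hess similarity
#'
#' Gamma between independent uniformly random n-dimensional subspaces of
#' a 3N-dimensional space; its expectation is `n / 3N`. Useful to judge
#' whether an observed gamma is larger than chance.
#'
#' @param n subspace dimension.
#' @param dim ambient dimension (3N).
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @return numeric vector of `n_draws` gamma values.
#' @export
hess_similarity_null <- function(n, dim, n_draws = 200L, seed = 1L) {
  rs <- .local_rng(seed)
  vapply(seq_len(n_draws), function(k) {
    QA <- qr.Q(qr(matrix(rs$norm(dim * n), dim, n)))
    QB <- qr.Q(qr(matrix(rs$norm(dim * n), dim, n)))
    sum(crossprod(QA, QB)^2) / n
  }, numeric(1))
}

#' Relative similarity between two ensembles
#'
#' The absolute Hess gamma between two ensembles is bounded away from 1
#' even for identical dynamics because of finite sampling. The relative
#' index normalises it by the self-similarities obtained by splitting
#' each ensemble into two parts:
#' `kappa = 2 gamma_AB / (gamma_A_self + gamma_B_self)` (arithmetic mean;
#' a geometric-mean variant is available). Values close to (or above) 1
#' indicate the two ensembles are indistinguishable given sampling noise.
#'
#' @param ens_A,ens_B `Ensemble`s with >= 4 frames each.
#' @param n common essential-space dimension (default 50).
#' @param split `"halves"` (first/second half) or `"odd_even"`.
#' @param reference common reference structure for superposition
#'   (default: topology of `ens_A`).
#' @param normalization `"arithmetic"` or `"geometric"` mean of the two
#'   self-similarities.
#' @param selection atom subset for the covariance.
#' @return a `SimilarityResult`: list with `gamma`, `kappa`,
#'   `gamma_self_A`, `gamma_self_B`, `n_modes`.
#' @export
relative_similarity <- function(ens_A, ens_B, n = 50L,
                                split = c("halves", "odd_even"),
                                reference = NULL,
                                normalization = c("arithmetic", "geometric"),
                                selection = NULL) {
  split <- match.arg(split)
  normalization <- match.arg(normalization)
  if (n_frames(ens_A) < 4L || n_frames(ens_B) < 4L) {
    stop("relative similarity needs >= 4 frames per ensemble")
  }
  if (is.null(reference)) reference <- ens_A$topology
  space <- function(e) ed_space(e, n, selection, reference)
  gamma_ab <- hess_similarity(space(ens_A), space(ens_B), n)
  self_gamma <- function(ens) {
    idx <- seq_len(n_frames(ens))
    part <- if (split == "halves") idx <= length(idx) / 2 else idx %% 2L == 1L
    sub <- function(keep) new_ensemble(ens$topology, ens$frames[keep],
                                       align_mask = ens$align_mask)
    hess_similarity(space(sub(part)), space(sub(!part)), n)
  }
  ga <- self_gamma(ens_A)
  gb <- self_gamma(ens_B)
  kappa <- if (normalization == "arithmetic") 2 * gamma_ab / (ga + gb)
           else gamma_ab / sqrt(ga * gb)
  out <- list(gamma = gamma_ab, kappa = kappa,
              gamma_self_A = ga, gamma_self_B = gb, n_modes = as.integer(n))
  class(out) <- "SimilarityResult"
  out
}

#' Inter-state transition vector
#'
#' The unit first principal component of a meta-ensemble pooling an equal
#' number of snapshots from two states (the larger ensemble is
#' downsampled, seeded), all superposed onto a common reference. For two
#' well-separated states this vector points along the inter-state
#' displacement.
#'
#' @param ens_A,ens_B `Ensemble`s sharing a topology.
#' @param seed RNG seed for the downsampling.
#' @param reference common reference structure (default: `ens_A` topology).
#' @param selection atom subset.
#' @return a `TransitionVector`: list with unit 3N-vector `r` and `source`.
#' @export
transition_vector <- function(ens_A, ens_B, seed = 1L, reference = NULL,
                              selection = NULL) {
  if (n_atoms(ens_A$topology) != n_atoms(ens_B$topology)) {
    stop("ensembles have incompatible topologies")
  }
  if (is.null(reference)) reference <- ens_A$topology
  rs <- .local_rng(seed)
  nA <- n_frames(ens_A); nB <- n_frames(ens_B)
  m <- min(nA, nB)
  pick <- function(ntot) if (ntot == m) seq_len(ntot) else
    sort(rs$sample(ntot, m))
  fa <- ens_A$frames[pick(nA)]
  fb <- ens_B$frames[pick(nB)]
  meta <- new_ensemble(ens_A$topology, c(fa, fb),
                       align_mask = ens_A$align_mask)
  C <- covariance_matrix(meta, selection, reference)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  out <- list(r = v, source = c("A", "B"))
  class(out) <- "TransitionVector"
  out
}

#' Overlap between a transition vector and an essential subspace
#'
#' `Ov = sqrt(sum_{i<=n} (r . v_i)^2)`, the norm of the projection of the
#' unit transition vector onto the first `n` essential modes; 1 when the
#' transition lies entirely inside the subspace.
#'
#' @param space an `EssentialSpace`.
#' @param r a `TransitionVector` (or unit numeric vector).
#' @param n number of modes (default 50).
#' @return overlap in `[0, 1]`.
#' @export
overlap <- function(space, r, n = 50L) {
  v <- if (inherits(r, "TransitionVector")) r$r else as.numeric(r)
  if (abs(sqrt(sum(v^2)) - 1) > 1e-8) stop("transition vector must be unit")
  V <- .space_vectors(space, n)
  if (nrow(V) != length(v)) stop("dimension mismatch")
  min(1, sqrt(sum(crossprod(V, v)^2)))
}
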