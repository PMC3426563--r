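#' RMSD-radius clustering of a conformational ensemble
#'
#' Frames are first superposed onto the ensemble topology using the
#' alignment mask; clustering then works on coordinate RMSD in this
#' common frame. The leader algorithm scans frames in order, assigning
#' each to the first cluster whose (incrementally updated) centroid lies
#' within `radius`, opening a new cluster otherwise. With
#' `algorithm = "kmedoid_refine"` a refinement pass then reassigns every
#' frame to its nearest centroid and recomputes centroids until stable.
#'
#' @param ens an `Ensemble`.
#' @param radius cluster radius (RMSD to centroid), Angstrom.
#' @param algorithm `"leader"` or `"kmedoid_refine"`.
#' @param selection atom subset used for the RMSD (default: atoms named
#'   CA if any, otherwise all atoms).
#' @param seed unused by the deterministic leader pass; kept so callers
#'   can fix it for reproducibility contracts.
#' @return a `ClusterSet`: list with `assignments`, `radius`,
#'   `representatives`, `populations`, `centroid_coords`, `n_clusters`.
#' @export
cluster_ensemble <- function(ens, radius,
                             algorithm = c("leader", "kmedoid_refine"),
                             selection = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (radius <= 0) stop("radius must be positive")
  if (is.null(selection)) {
    selection <- which(ens$topology$atom_name == "CA")
    if (!length(selection)) selection <- seq_len(n_atoms(ens$topology))
  }
  aligned <- align_frames_to_reference(ens, ens$topology)
  M <- t(vapply(aligned, function(f)
    as.vector(t(f[selection, , drop = FALSE])),
    numeric(3L * length(selection))))
  nf <- nrow(M)
  nc3 <- ncol(M)
  frame_rmsd <- function(a, b) sqrt(sum((a - b)^2) / (nc3 / 3))

  assignments <- integer(nf)
  centroids <- list()
  sizes <- integer(0)
  for (i in seq_len(nf)) {
    placed <- FALSE
    for (k in seq_along(centroids)) {
      if (frame_rmsd(M[i, ], centroids[[k]]) <= radius) {
        sizes[k] <- sizes[k] + 1L
        centroids[[k]] <- centroids[[k]] + (M[i, ] - centroids[[k]]) / sizes[k]
        assignments[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1L]] <- M[i, ]
      sizes <- c(sizes, 1L)
      assignments[i] <- length(centroids)
    }
  }

  if (algorithm == "kmedoid_refine") {
    for (pass in 1:100) {
      Cm <- do.call(rbind, centroids)
      d2 <- outer(rowSums(M^2), rep(1, nrow(Cm))) - 2 * M %*% t(Cm) +
        outer(rep(1, nf), rowSums(Cm^2))
      new_assign <- max.col(-d2, ties.method = "first")
      # drop emptied clusters
      keep <- sort(unique(new_assign))
      new_assign <- match(new_assign, keep)
      centroids <- lapply(seq_along(keep), function(k)
        colMeans(M[new_assign == k, , drop = FALSE]))
      if (identical(new_assign, assignments)) break
      assignments <- new_assign
    }
  }

  n_clusters <- length(centroids)
  reps <- integer(n_clusters)
  for (k in seq_len(n_clusters)) {
    members <- which(assignments == k)
    d <- vapply(members, function(i) frame_rmsd(M[i, ], centroids[[k]]),
                numeric(1))
    reps[k] <- members[which.min(d)]  # which.min: lowest index on ties
  }
  out <- list(assignments = assignments, radius = radius,
              representatives = reps,
              populations = as.numeric(table(factor(assignments,
                                                    levels = seq_len(n_clusters)))) / nf,
              centroid_coords = lapply(centroids, function(cv)
                matrix(cv, ncol = 3, byrow = TRUE)),
              selection = selection,
              n_clusters = n_clusters)
  class(out) <- "ClusterSet"
  out
}

#' Representative frames of a cluster set
#'
#' Per cluster, the member frame with minimal RMSD to the cluster
#' centroid (ties broken by lowest frame index).
#'
#' @param cs a `ClusterSet` from [cluster_ensemble()].
#' @param ens the `Ensemble` it was computed from.
#' @return integer vector of frame indices, one per cluster.
#' @export
representatives <- function(cs, ens) {
  stopifnot(inherits(cs, "ClusterSet"))
  if (length(cs$assignments) != n_frames(ens)) {
    stop("cluster set does not match ensemble")
  }
  cs$representatives
}
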