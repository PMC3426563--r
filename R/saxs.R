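#' Construct a SAXS curve
#'
#' @param s momentum transfer grid, 1/Angstrom, strictly increasing, >= 0.
#' @param intensity I(s), arbitrary units, >= 0.
#' @param sigma optional per-point errors (> 0).
#' @return a `SAXSCurve`.
#' @export
new_saxs_curve <- function(s, intensity, sigma = NULL) {
  s <- as.numeric(s); intensity <- as.numeric(intensity)
  if (length(s) != length(intensity)) stop("grid/intensity length mismatch")
  if (any(s < 0) || any(diff(s) <= 0)) {
    stop("s grid must be non-negative and strictly increasing")
  }
  if (any(intensity < 0)) stop("intensity must be >= 0")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(s) || any(sigma <= 0)) {
      stop("sigma must be positive and match the grid")
    }
  }
  out <- list(s = s, intensity = intensity, sigma = sigma)
  class(out) <- "SAXSCurve"
  out
}

#' SAXS intensity from coordinates via the Debye formula
#'
#' `I(s) = sum_i sum_j f_i f_j sin(s r_ij) / (s r_ij)` with `sinc(0)=1`.
#' Vacuum scattering from point scatterers: no hydration shell or
#' excluded-volume correction is applied (see the methods vignette), so
#' absolute intensities are idealised; the shape of the curve, which is
#' what chi-based ranking uses, is meaningful.
#'
#' @param x a `Structure` (or n x 3 coordinate matrix).
#' @param grid s values in `[0, 1]` 1/Angstrom.
#' @param representation `"residue_bead"` (one scatterer per residue, at
#'   the C-alpha/bead position) or `"heavy_atom"`.
#' @param scattering_factors optional named vector of per-bead effective
#'   factors keyed by residue (or element) name; default: unit factors.
#' @return a `SAXSCurve` without errors.
#' @export
debye_curve <- function(x, grid, representation = c("residue_bead",
                                                    "heavy_atom"),
                        scattering_factors = NULL) {
  representation <- match.arg(representation)
  if (any(grid < 0) || any(grid > 1)) stop("grid must lie in [0, 1] 1/A")
  if (inherits(x, "Structure")) {
    if (representation == "residue_bead") {
      sel <- .contact_atom_selection(x, "cbeta")
      # one bead per residue at the CA (or first-atom) position
      sel <- vapply(unique(x$residue_index), function(r) {
        at <- which(x$residue_index == r)
        ca <- at[x$atom_name[at] == "CA"]
        if (length(ca)) ca[1] else at[1]
      }, integer(1))
      X <- x$coords[sel, , drop = FALSE]
      keys <- x$residue_name[sel]
    } else {
      sel <- which(x$element != "H")
      X <- x$coords[sel, , drop = FALSE]
      keys <- x$element[sel]
    }
  } else {
    X <- unname(as.matrix(x))
    keys <- rep("X", nrow(X))
  }
  if (nrow(X) < 1L) stop("empty structure")
  f <- rep(1, nrow(X))
  if (!is.null(scattering_factors)) {
    hit <- keys %in% names(scattering_factors)
    f[hit] <- scattering_factors[keys[hit]]
  }
  D <- as.matrix(stats::dist(X))
  ff <- tcrossprod(f)
  dv <- D[upper.tri(D)]
  fv <- ff[upper.tri(ff)]
  self <- sum(f^2)
  I <- vapply(grid, function(sv) {
    if (sv == 0) return(self + 2 * sum(fv))
    sr <- sv * dv
    self + 2 * sum(fv * ifelse(sr == 0, 1, sin(sr) / sr))
  }, numeric(1))
  new_saxs_curve(grid, I)
}

#' Guinier analysis of a SAXS curve
#'
#' Linear fit of `ln I` against `s^2` over the small-angle range,
#' iterated so that the fitted range satisfies `s < limit_factor / Rg`
#' self-consistently. `I(s) = I0 exp(-(s Rg)^2 / 3)` gives `Rg` from the
#' slope and `I0` from the intercept.
#'
#' @param curve a `SAXSCurve`.
#' @param limit_factor the `s_max * Rg` bound (default 1.3).
#' @param max_iter iteration cap (default 50).
#' @return a `GuinierResult`: list with `I0`, `Rg`, `s_range_used`, `r2`,
#'   `n_points_used`.
#' @export
guinier_fit <- function(curve, limit_factor = 1.3, max_iter = 50L) {
  s <- curve$s; I <- curve$intensity
  use <- seq_along(s)
  prev <- NULL
  for (it in seq_len(max_iter)) {
    if (length(use) < 5L) stop("fewer than 5 points in the Guinier range")
    if (any(I[use] <= 0)) stop("non-positive intensities in Guinier range")
    x <- s[use]^2
    y <- log(I[use])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    if (slope >= 0) stop("non-decreasing intensity: no Guinier regime")
    rg <- sqrt(-3 * slope)
    new_use <- which(s < limit_factor / rg)
    if (identical(new_use, use)) {
      r2 <- 1 - sum(fit$residuals^2) /
        max(sum((y - mean(y))^2), .Machine$double.eps)
      out <- list(I0 = unname(exp(fit$coefficients[1])), Rg = unname(rg),
                  s_range_used = range(s[use]), r2 = r2,
                  n_points_used = length(use))
      class(out) <- "GuinierResult"
      return(out)
    }
    if (!is.null(prev) && identical(new_use, prev)) {
      # 2-cycle: take the smaller range
      use <- if (length(new_use) < length(use)) new_use else use
      prev <- NULL
      next
    }
    prev <- use
    use <- new_use
  }
  stop("Guinier range iteration did not converge in ", max_iter, " rounds")
}

#' Scale and chi-value of the fit between two SAXS curves
#'
#' The calculated curve is linearly interpolated onto the experimental
#' grid (restricted to the overlapping s-range); the multiplicative scale
#' `c` minimising `sum(((I_exp - c I_calc) / sigma)^2)` is solved in
#' closed form and `chi = sqrt(min / n_points)`. Smaller chi means better
#' agreement.
#'
#' @param calc calculated `SAXSCurve`.
#' @param exp_curve experimental `SAXSCurve`; if it carries no sigma,
#'   `default_error_frac * I_exp` is used (the homogeneous-error
#'   convention for deconvoluted curves).
#' @param default_error_frac uniform fractional error applied when the
#'   experimental curve has no sigma column (default 0.07).
#' @return a `ChiFit`: list with `chi`, `scale`, `n_points`.
#' @export
chi_fit <- function(calc, exp_curve, default_error_frac = 0.07) {
  lo <- max(min(calc$s), min(exp_curve$s))
  hi <- min(max(calc$s), max(exp_curve$s))
  if (lo >= hi) stop("curves have disjoint s-ranges")
  keep <- which(exp_curve$s >= lo & exp_curve$s <= hi)
  se <- exp_curve$s[keep]
  Ie <- exp_curve$intensity[keep]
  sig <- if (!is.null(exp_curve$sigma)) exp_curve$sigma[keep]
         else default_error_frac * Ie
  if (any(sig <= 0)) stop("non-positive errors")
  Ic <- stats::approx(calc$s, calc$intensity, xout = se)$y
  w <- 1 / sig^2
  cc <- sum(w * Ie * Ic) / sum(w * Ic^2)
  chi2 <- sum(((Ie - cc * Ic) / sig)^2) / length(se)
  out <- list(chi = sqrt(chi2), scale = cc, n_points = length(se))
  class(out) <- "ChiFit"
  out
}

#' Construct a temperature-series SAXS dataset
#'
#' @param D matrix, one row per temperature, one column per s value.
#' @param temperatures temperatures (one per row).
#' @param s shared momentum-transfer grid.
#' @return a `SAXSDataset`.
#' @export
new_saxs_dataset <- function(D, temperatures, s) {
  D <- as.matrix(D)
  if (nrow(D) != length(temperatures)) stop("row count != temperature count")
  if (ncol(D) != length(s)) stop("column count != grid length")
  if (!all(is.finite(D))) stop("dataset contains missing values")
  out <- list(D = unname(D), temperatures = as.numeric(temperatures),
              s = as.numeric(s))
  class(out) <- "SAXSDataset"
  out
}

#' Number of significant components in a SAXS dataset
#'
#' Singular value decomposition of the (uncentred) data matrix. With the
#' default `method = "sv_ratio"` the rank is the number of singular
#' values above `threshold` times the largest one -- a noise-floor
#' criterion that is robust when the component curves are strongly
#' collinear (as SAXS curves of related conformations are, where the
#' first component can already explain > 99.5 percent of the variance).
#' `method = "variance"` instead returns the smallest component count
#' whose cumulative squared singular values reach `threshold` of the
#' total.
#'
#' @param dataset a `SAXSDataset` (or plain matrix) with >= 2 rows.
#' @param threshold singular-value ratio floor (default 0.005) for
#'   `"sv_ratio"`, or explained-variance fraction for `"variance"`.
#' @param method `"sv_ratio"` or `"variance"`.
#' @return integer component count.
#' @export
pca_rank <- function(dataset, threshold = NULL,
                     method = c("sv_ratio", "variance")) {
  method <- match.arg(method)
  D <- if (inherits(dataset, "SAXSDataset")) dataset$D else as.matrix(dataset)
  if (nrow(D) < 2L) stop("need at least 2 rows")
  sv <- svd(D, nu = 0, nv = 0)$d
  if (method == "sv_ratio") {
    if (is.null(threshold)) threshold <- 0.005
    sum(sv >= threshold * sv[1])
  } else {
    if (is.null(threshold)) threshold <- 0.995
    unname(which(cumsum(sv^2) / sum(sv^2) >= threshold)[1])
  }
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0
.nnls <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  b <- as.numeric(b)
  for (outer in seq_len(30L * n)) {
    w <- as.numeric(crossprod(A, b - A %*% x))
    if (!any(!passive & w > tol)) break
    passive[which.max(replace(w, passive, -Inf))] <- TRUE
    repeat {
      z <- numeric(n)
      zp <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      zp[is.na(zp)] <- 0
      z[passive] <- zp
      if (all(z[passive] > 0)) { x <- z; break }
      q <- passive & z <= 0
      denom <- x[q] - z[q]
      ok <- denom > 1e-300
      alpha <- if (any(ok)) min(x[q][ok] / denom[ok]) else 0
      x <- x + alpha * (z - x)
      x[q][!ok] <- 0
      passive <- passive & x > 1e-12
      if (!any(passive)) { x[] <- 0; break }
    }
  }
  x
}

#' Multivariate curve resolution by alternating least squares (MCR-ALS)
#'
#' Factorises a temperature-series data matrix `D` (temperatures x grid)
#' as `D = C S + R`: `C` holds the contribution (concentration) profiles
#' of `n_components` species across temperature, `S` their pure component
#' curves, `R` the residuals. Alternating non-negative least squares with
#' optional closure (rows of `C` sum to 1), iterated until the relative
#' change in lack of fit drops below `tol`.
#'
#' @param dataset a `SAXSDataset` (or matrix).
#' @param n_components number of species.
#' @param nonneg_C,nonneg_S,closure_C constraint switches (all default
#'   `TRUE`).
#' @param init `"svd"` (default) or a list with an initial `S` matrix
#'   (`n_components` x grid).
#' @param tol relative lack-of-fit change declaring convergence.
#' @param max_iter iteration cap.
#' @return an `MCRResult`: list with `C`, `S`, `R`, `lack_of_fit`
#'   (`||R||_F / ||D||_F`), `lof_trace`, `converged`, `n_iter`.
#' @export
mcr_als <- function(dataset, n_components, nonneg_C = TRUE, nonneg_S = TRUE,
                    closure_C = TRUE, init = "svd", tol = 1e-10,
                    max_iter = 500L) {
  D <- if (inherits(dataset, "SAXSDataset")) dataset$D else as.matrix(dataset)
  if (n_components > min(dim(D))) stop("n_components exceeds matrix rank")
  if (!all(is.finite(D))) stop("D must be finite")
  normD <- sqrt(sum(D^2))

  S <- if (is.list(init)) {
    as.matrix(init$S)
  } else {
    # SVD-based start: pick the n most mutually dissimilar rows of D
    # (purest-row heuristic), which respects non-negativity from the off
    idx <- .purest_rows(D, n_components)
    D[idx, , drop = FALSE]
  }

  solve_rows <- function(A, B, nonneg) {
    # min ||t(A) x - b|| per row b of B; solutions as rows
    k <- nrow(A)
    if (nonneg) {
      out <- matrix(0, nrow(B), k)
      At <- t(A)
      for (i in seq_len(nrow(B))) out[i, ] <- .nnls(At, B[i, ])
      out
    } else {
      out <- t(qr.coef(qr(t(A)), t(B)))
      out[is.na(out)] <- 0
      matrix(out, nrow(B), k)
    }
  }

  lof <- Inf
  lof_trace <- numeric(0)
  converged <- FALSE
  C <- NULL
  for (it in seq_len(max_iter)) {
    C <- solve_rows(S, D, nonneg_C)            # rows of D ~ C %*% S
    if (!nonneg_C) C[is.na(C)] <- 0
    if (closure_C) {
      rs <- rowSums(C)
      rs[rs <= 0] <- 1
      C <- C / rs
    }
    St <- solve_rows(t(C), t(D), nonneg_S)     # columns of D ~ C %*% S
    S <- t(St)
    S[is.na(S)] <- 0
    R <- D - C %*% S
    new_lof <- sqrt(sum(R^2)) / normD
    lof_trace <- c(lof_trace, new_lof)
    if (new_lof < 1e-12 ||
        (is.finite(lof) && abs(lof - new_lof) < tol * max(lof, 1e-300))) {
      converged <- TRUE
      lof <- new_lof
      break
    }
    lof <- new_lof
  }
  out <- list(C = C, S = S, R = D - C %*% S, lack_of_fit = lof,
              lof_trace = lof_trace, converged = converged, n_iter = it)
  class(out) <- "MCRResult"
  out
}

# purest-row selection (SIMPLISMA-flavoured): greedily pick rows that are
# least representable by the span of those already picked
.purest_rows <- function(D, k) {
  Dn <- D / pmax(sqrt(rowSums(D^2)), .Machine$double.eps)
  idx <- which.max(rowSums(D^2))
  for (j in seq_len(k - 1)) {
    Q <- qr.Q(qr(t(Dn[idx, , drop = FALSE])))
    resid <- Dn - (Dn %*% Q) %*% t(Q)
    scores <- rowSums(resid^2)
    scores[idx] <- -Inf
    idx <- c(idx, which.max(scores))
  }
  idx
}

#' Match recovered MCR components to reference components
#'
#' Resolves the permutation (and per-component scale) ambiguity of a
#' factorisation by greedily pairing recovered component curves with
#' reference curves by correlation.
#'
#' @param S recovered component matrix (components x grid).
#' @param S_ref reference component matrix.
#' @return integer permutation `p` such that `S[p, ]` aligns with `S_ref`.
#' @export
match_components <- function(S, S_ref) {
  k <- nrow(S_ref)
  cost <- abs(stats::cor(t(S_ref), t(S)))
  cost[is.na(cost)] <- -Inf
  perm <- rep(NA_integer_, k)
  for (step in seq_len(k)) {
    ij <- which(cost == max(cost), arr.ind = TRUE)[1, ]
    perm[ij[1]] <- ij[2]
    cost[ij[1], ] <- -Inf
    cost[, ij[2]] <- -Inf
  }
  perm
}
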