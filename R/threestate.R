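#' Construct a sequential three-state thermodynamic model
#'
#' Sequential N <-> I <-> U equilibria defined by the free energies
#' `dG1` (N to I) and `dG2` (I to U) in kJ/mol. Either supply tabulated
#' free energies on a temperature grid, or Gibbs-Helmholtz parameters
#' per transition: `dG(T) = dH (1 - T/Tm) - dCp (Tm - T + T ln(T/Tm))`
#' with `dH` in kJ/mol, `Tm` in K, `dCp` in kJ/(mol K).
#'
#' @param temperatures temperature grid in K (strictly increasing) for
#'   tabulated models; optional for parametric models.
#' @param dG1,dG2 tabulated free energies (kJ/mol), one per temperature.
#' @param params1,params2 alternatively, lists `list(dH=, Tm=, dCp=)` per
#'   transition.
#' @return a `ThreeStateModel`.
#' @export
three_state_model <- function(temperatures = NULL, dG1 = NULL, dG2 = NULL,
                              params1 = NULL, params2 = NULL) {
  parametric <- !is.null(params1) || !is.null(params2)
  if (parametric && (is.null(params1) || is.null(params2))) {
    stop("give Gibbs-Helmholtz parameters for both transitions")
  }
  if (!is.null(temperatures)) {
    if (any(temperatures <= 0) || is.unsorted(temperatures, strictly = TRUE)) {
      stop("temperatures must be strictly increasing and positive (K)")
    }
  }
  if (!parametric) {
    if (is.null(temperatures) || is.null(dG1) || is.null(dG2)) {
      stop("tabulated models need temperatures, dG1 and dG2")
    }
    if (length(dG1) != length(temperatures) ||
        length(dG2) != length(temperatures)) {
      stop("dG vectors must match the temperature grid")
    }
    if (!all(is.finite(dG1)) || !all(is.finite(dG2))) {
      stop("non-finite free energies")
    }
  }
  out <- list(temperatures = temperatures, dG1 = dG1, dG2 = dG2,
              params1 = params1, params2 = params2, parametric = parametric)
  class(out) <- "ThreeStateModel"
  out
}

.gibbs_helmholtz <- function(p, T) {
  dCp <- if (is.null(p$dCp)) 0 else p$dCp
  p$dH * (1 - T / p$Tm) - dCp * (p$Tm - T + T * log(T / p$Tm))
}

# free energies (kJ/mol) of a model at arbitrary temperatures
model_dG <- function(model, T) {
  if (model$parametric) {
    list(dG1 = .gibbs_helmholtz(model$params1, T),
         dG2 = .gibbs_helmholtz(model$params2, T))
  } else {
    rng <- range(model$temperatures)
    if (any(T < rng[1] - 1e-9) || any(T > rng[2] + 1e-9)) {
      stop("temperature outside the tabulated range")
    }
    list(dG1 = stats::approx(model$temperatures, model$dG1, T)$y,
         dG2 = stats::approx(model$temperatures, model$dG2, T)$y)
  }
}

#' Equilibrium populations of the sequential three-state model
#'
#' `K1 = exp(-dG1/RT)`, `K2 = exp(-dG2/RT)`;
#' `X_N = 1 / (1 + K1 + K1 K2)`, `X_I = K1 X_N`, `X_U = K1 K2 X_N`.
#' The three populations sum to one at every temperature.
#'
#' @param model a `ThreeStateModel`.
#' @param T temperatures in K (vectorised).
#' @return matrix with columns `X_N`, `X_I`, `X_U`, one row per
#'   temperature.
#' @export
populations <- function(model, T) {
  g <- model_dG(model, T)
  if (!all(is.finite(g$dG1)) || !all(is.finite(g$dG2))) {
    stop("non-finite free energy at requested temperature")
  }
  R <- 8.314e-3  # kJ/(mol K)
  # Boltzmann weights 1 : K1 : K1*K2 computed in log space so that very
  # large |dG| cannot overflow
  lw <- cbind(0, -g$dG1 / (R * T), -(g$dG1 + g$dG2) / (R * T))
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  X <- w / rowSums(w)
  colnames(X) <- c("X_N", "X_I", "X_U")
  X
}

#' Construct a temperature-series spectra matrix
#'
#' @param wavelengths wavelength grid, nm.
#' @param temperatures temperatures, K.
#' @param Y observed matrix, wavelengths x temperatures.
#' @return a `SpectraSeries`.
#' @export
new_spectra_series <- function(wavelengths, temperatures, Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) != length(wavelengths) || ncol(Y) != length(temperatures)) {
    stop("Y dimensions must match wavelength and temperature grids")
  }
  if (!all(is.finite(Y))) stop("missing values in spectra matrix")
  out <- list(wavelengths = as.numeric(wavelengths),
              temperatures = as.numeric(temperatures), Y = unname(Y))
  class(out) <- "SpectraSeries"
  out
}

#' Deconvolute temperature-series spectra into pure state spectra
#'
#' Observed absorbance is modelled as a population-weighted combination
#' of the native, intermediate and unfolded state spectra:
#' `Y(lambda, T) = sum_i X_i(T) Y_i(lambda)` (constant baseline) or, with
#' `baseline = "linear_T"`, `Y_i(lambda, T) = a_i(lambda) +
#' b_i(lambda) (T - mean(T))`, six parameters per wavelength. Populations
#' come from the three-state model; the per-wavelength linear systems are
#' solved by least squares.
#'
#' @param series a `SpectraSeries`.
#' @param model a `ThreeStateModel` providing populations at the series
#'   temperatures.
#' @param baseline `"constant"` or `"linear_T"`.
#' @param nonneg force non-negative state spectra (constant baseline
#'   only; default `FALSE`, plain least squares).
#' @param min_rcond condition threshold: the population design matrix
#'   must have reciprocal condition number above this (default 1e-10).
#' @return a `StateSpectra`: list with `Y_native`, `Y_intermediate`,
#'   `Y_unfolded` (per wavelength), optional `slopes`, `populations`,
#'   `residuals`, `condition_number`.
#' @export
deconvolute_spectra <- function(series, model,
                                baseline = c("constant", "linear_T"),
                                nonneg = FALSE, min_rcond = 1e-10) {
  baseline <- match.arg(baseline)
  Tn <- series$temperatures
  if (length(Tn) < 3L) {
    stop("need >= 3 temperatures for a rank-3 population matrix")
  }
  X <- populations(model, Tn)
  design <- if (baseline == "constant") X else {
    tc <- Tn - mean(Tn)
    cbind(X, X * tc)
  }
  sv <- svd(design, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || 1 / cond < min_rcond) {
    stop(sprintf(
      "population design matrix is rank-deficient (condition number %.3g)",
      cond))
  }
  nw <- length(series$wavelengths)
  k <- ncol(design)
  coefs <- matrix(0, nw, k)
  for (w in seq_len(nw)) {
    y <- series$Y[w, ]
    coefs[w, ] <- if (nonneg && baseline == "constant") .nnls(design, y)
                  else qr.coef(qr(design), y)
  }
  fitted <- design %*% t(coefs)
  out <- list(Y_native = coefs[, 1], Y_intermediate = coefs[, 2],
              Y_unfolded = coefs[, 3],
              slopes = if (baseline == "linear_T")
                coefs[, 4:6, drop = FALSE] else NULL,
              populations = X,
              residuals = series$Y - t(fitted),
              condition_number = cond)
  class(out) <- "StateSpectra"
  out
}
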