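#' Experimental criteria set for intermediate annotation
#'
#' A snapshot is annotated as intermediate when its summed Trp
#' solvent-accessible surface lies inside a window, its SAXS curve fits
#' the experimental intermediate curve below a chi threshold, and its
#' absolute accumulated phi-error is below a threshold. Presets follow
#' the published loose (100-300 A^2, chi < 1.5, phi-error < 2) and
#' strict (100-300 A^2, chi < 1.0, phi-error < 1.0) criteria.
#'
#' @param name `"loose"`, `"strict"` or `"custom"`.
#' @param sas_trp_min,sas_trp_max Trp SASA window, A^2.
#' @param chi_max chi threshold.
#' @param phi_err_max absolute accumulated phi-error threshold.
#' @return a `CriteriaSet`.
#' @export
criteria_set <- function(name = c("loose", "strict", "custom"),
                         sas_trp_min = NULL, sas_trp_max = NULL,
                         chi_max = NULL, phi_err_max = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    loose = list(sas_trp_min = 100, sas_trp_max = 300,
                 chi_max = 1.5, phi_err_max = 2),
    strict = list(sas_trp_min = 100, sas_trp_max = 300,
                  chi_max = 1.0, phi_err_max = 1.0),
    custom = list(sas_trp_min = sas_trp_min, sas_trp_max = sas_trp_max,
                  chi_max = chi_max, phi_err_max = phi_err_max))
  if (name != "custom") {
    for (f in names(defaults)) {
      v <- get(f)
      if (!is.null(v)) defaults[[f]] <- v
    }
  }
  if (any(vapply(defaults, is.null, logical(1)))) {
    stop("custom criteria need all four thresholds")
  }
  if (defaults$sas_trp_min >= defaults$sas_trp_max) {
    stop("sas_trp_min must be below sas_trp_max")
  }
  if (defaults$chi_max <= 0 || defaults$phi_err_max <= 0) {
    stop("chi_max and phi_err_max must be positive")
  }
  out <- c(defaults, list(name = name))
  class(out) <- "CriteriaSet"
  out
}

#' Annotate ensemble frames against the experimental intermediate criteria
#'
#' Per frame computes (i) summed Trp side-chain SASA, (ii) the chi of a
#' Debye-formula SAXS curve fitted to the experimental intermediate
#' curve (7 percent homogeneous errors assumed when the curve carries
#' none), and (iii) the absolute accumulated phi-error against the
#' experimental profile. A frame passes when all three criteria hold.
#'
#' @param ens an `Ensemble`.
#' @param native_contacts native `ContactMap` for the phi calculation.
#' @param exp_phi experimental `PhiProfile`.
#' @param exp_saxs experimental intermediate `SAXSCurve`.
#' @param criteria a [criteria_set()].
#' @param exclude_phi residue indices excluded from the phi-error sum
#'   (e.g. a helix with unreliable experimental values).
#' @param sasa_n_points SASA quadrature points per atom.
#' @param saxs_grid grid for the computed curves (default: the
#'   experimental grid).
#' @return an `AnnotationReport`: list with `per_frame` (data.frame:
#'   `sas_trp`, `chi`, `phi_err`, `passes`), `fraction_intermediate`,
#'   `per_criterion_pass_rates`, `criteria`.
#' @export
annotate <- function(ens, native_contacts, exp_phi, exp_saxs, criteria,
                     exclude_phi = integer(0), sasa_n_points = 120L,
                     saxs_grid = NULL) {
  stopifnot(inherits(criteria, "CriteriaSet"))
  if (is.null(saxs_grid)) saxs_grid <- exp_saxs$s
  nf <- n_frames(ens)
  sas_v <- numeric(nf); chi_v <- numeric(nf); err_v <- numeric(nf)
  for (i in seq_len(nf)) {
    fs <- frame_structure(ens, i)
    sas_v[i] <- sasa(fs, n_points = sasa_n_points)$trp_area
    chi_v[i] <- chi_fit(debye_curve(fs, saxs_grid), exp_saxs)$chi
    err_v[i] <- phi_error(phi_calc(fs, native_contacts), exp_phi,
                          exclude = exclude_phi)$abs_sum
  }
  pass_sas <- sas_v >= criteria$sas_trp_min & sas_v <= criteria$sas_trp_max
  pass_chi <- chi_v < criteria$chi_max
  pass_phi <- err_v < criteria$phi_err_max
  passes <- pass_sas & pass_chi & pass_phi
  out <- list(
    per_frame = data.frame(sas_trp = sas_v, chi = chi_v, phi_err = err_v,
                           passes = passes),
    fraction_intermediate = mean(passes),
    per_criterion_pass_rates = c(sas = mean(pass_sas), chi = mean(pass_chi),
                                 phi = mean(pass_phi)),
    criteria = criteria)
  class(out) <- "AnnotationReport"
  out
}

#' @export
print.AnnotationReport <- function(x, ...) {
  cat(sprintf(
    "<AnnotationReport: %d frames, %.1f%% intermediate (%s criteria)>\n",
    nrow(x$per_frame), 100 * x$fraction_intermediate, x$criteria$name))
  invisible(x)
}
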