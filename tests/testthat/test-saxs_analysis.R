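test_that("Debye curve closed forms and invariances", {
  gr <- c(0.02, 0.1, 0.15, 0.22, 0.3)
  # single scatterer: flat f^2
  one <- debye_curve(matrix(0, 1, 3), gr)
  expect_equal(one$intensity, rep(1, 5))
  # two identical scatterers at distance d
  d <- 10
  two <- debye_curve(rbind(c(0, 0, 0), c(d, 0, 0)), gr)
  expect_equal(two$intensity, 2 * (1 + sin(gr * d) / (gr * d)),
               tolerance = 1e-10)
  # forward limit (sum f)^2
  s <- toy60()
  expect_equal(debye_curve(s, 0)$intensity, 60^2)
  # rigid-motion invariance
  curve_a <- debye_curve(s$coords, gr)
  curve_b <- debye_curve(rotate_z(s$coords, 1.3, c(7, -2, 4)), gr)
  expect_equal(curve_a$intensity, curve_b$intensity, tolerance = 1e-9)
  expect_error(debye_curve(matrix(0, 1, 3), c(0.1, 1.5)), "\\[0, 1\\]")
  # scattering factors enter as f_i f_j
  fs <- c(ALA = 2, TRP = 2)
  sc <- debye_curve(s, gr, scattering_factors = fs)
  expect_equal(sc$intensity[1] / curve_a$intensity[1], 4, tolerance = 1e-6)
})

test_that("Guinier fits: exact model, sphere, cross-module consistency", {
  sg <- seq(0.005, 0.2, by = 0.002)
  g <- guinier_fit(new_saxs_curve(sg, 7 * exp(-(sg * 15)^2 / 3)))
  expect_equal(g$I0, 7, tolerance = 1e-6)
  expect_equal(g$Rg, 15, tolerance = 1e-6)

  # sphere of radius 20, curve measured inside the Guinier regime
  R <- 20
  ss <- seq(0.002, 0.05, length.out = 60)
  x <- ss * R
  Isph <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  gs <- guinier_fit(new_saxs_curve(ss, Isph))
  expect_equal(gs$Rg, R * sqrt(3 / 5), tolerance = 0.01)

  # Debye curve of a rigid toy vs its coordinate Rg
  s <- toy60()
  dc <- debye_curve(s, seq(0.005, 0.12, by = 0.0025))
  expect_equal(guinier_fit(dc)$Rg, radius_of_gyration(s), tolerance = 0.02)

  # Rg estimate approaches the coordinate Rg as the range shrinks
  errs <- vapply(c(1.3, 1.0, 0.7), function(lf)
    abs(guinier_fit(dc, limit_factor = lf)$Rg - radius_of_gyration(s)),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-8))

  expect_error(guinier_fit(new_saxs_curve(sg[1:4], exp(-sg[1:4]^2))),
               "5 points")
  expect_error(guinier_fit(new_saxs_curve(sg, rep(1, length(sg)))),
               "Guinier")
})

test_that("chi fitting: scale, unit perturbation, scaling laws", {
  gr <- seq(0.07, 0.31, length.out = 20)
  base <- debye_curve(toy60(), gr)
  sig <- 0.05 * base$intensity

  # calc = 2 x exp -> c = 0.5, chi = 0
  expcv <- new_saxs_curve(gr, base$intensity, sig)
  calc2 <- new_saxs_curve(gr, 2 * base$intensity)
  f <- chi_fit(calc2, expcv)
  expect_equal(f$scale, 0.5, tolerance = 1e-12)
  expect_equal(f$chi, 0, tolerance = 1e-12)

  # perturbation of one sigma per point, orthogonalised against the
  # fitted direction so the scale cannot absorb it -> chi = 1
  set.seed(9)
  u <- sample(c(-1, 1), 20, replace = TRUE)
  w <- 1 / sig^2
  u <- u - sum(w * u * sig * base$intensity) /
    sum(w * base$intensity^2) * base$intensity / sig
  u <- u / sqrt(mean(u^2))
  pert <- new_saxs_curve(gr, base$intensity + u * sig, sig)
  expect_equal(chi_fit(new_saxs_curve(gr, base$intensity), pert)$chi, 1,
               tolerance = 1e-6)

  # doubling sigma halves chi, leaves the scale unchanged
  pert2 <- new_saxs_curve(gr, base$intensity + u * sig, 2 * sig)
  f1 <- chi_fit(base, pert)
  f2 <- chi_fit(base, pert2)
  expect_equal(f2$chi, f1$chi / 2, tolerance = 1e-9)
  expect_equal(f2$scale, f1$scale, tolerance = 1e-9)

  # 7 percent homogeneous error convention when sigma is absent
  nosig <- new_saxs_curve(gr, base$intensity)
  expect_equal(chi_fit(calc2, nosig)$scale, 0.5, tolerance = 1e-12)

  # regridding both curves leaves the scale invariant
  gr2 <- seq(0.08, 0.30, length.out = 41)
  li <- function(cv) new_saxs_curve(
    gr2, stats::approx(cv$s, cv$intensity, gr2)$y)
  expect_equal(chi_fit(li(calc2), li(nosig))$scale, 0.5, tolerance = 1e-6)

  expect_error(chi_fit(new_saxs_curve(c(0.5, 0.6), c(1, 1)), expcv),
               "disjoint")
})

test_that("significant-component counting", {
  comps <- fixture("saxs_comps", toy_saxs_components)
  model <- default_three_state_model()
  temps <- seq(273, 373, length.out = 20)
  D0 <- make_saxs_mixture(comps$S, model, temps, s = comps$grid)
  expect_equal(pca_rank(D0), 3L)
  Dn <- make_saxs_mixture(comps$S, model, temps, s = comps$grid,
                          noise_frac = 0.01, seed = 5)
  expect_equal(pca_rank(Dn), 3L)
  single <- matrix(rep(comps$S[1, ], 4), 4, byrow = TRUE)
  expect_equal(pca_rank(single), 1L)
  expect_error(pca_rank(single[1, , drop = FALSE]), "2 rows")
})

test_that("MCR-ALS: planted factorisations and noise robustness", {
  comps <- fixture("saxs_comps", toy_saxs_components)
  S0 <- comps$S

  # rank-1: exact recovery up to scale
  D1 <- new_saxs_dataset(outer(c(1, 2, 3, 4), S0[1, ]), 1:4, comps$grid)
  r1 <- mcr_als(D1, 1, closure_C = FALSE)
  expect_lt(r1$lack_of_fit, 1e-10)

  # planted closure factorisation with pure rows: essentially unique
  C0 <- rbind(c(1, 0, 0), c(.7, .3, 0), c(.3, .6, .1), c(0, 1, 0),
              c(.1, .6, .3), c(0, .3, .7), c(0, 0, 1), c(.2, .2, .6))
  Dp <- new_saxs_dataset(C0 %*% S0, seq_len(nrow(C0)), comps$grid)
  rp <- mcr_als(Dp, 3)
  perm <- match_components(rp$S, S0)
  expect_lt(rp$lack_of_fit, 1e-8)
  expect_lt(max(abs(rp$C[, perm] - C0)), 1e-3)

  # generator-recorded ground truth is an exact ALS fixed point
  model <- default_three_state_model()
  temps <- seq(273, 373, length.out = 25)
  D0 <- make_saxs_mixture(S0, model, temps, s = comps$grid)
  gt <- attr(D0, "ground_truth")
  rf <- mcr_als(D0, 3, init = list(S = gt$S))
  pf <- match_components(rf$S, gt$S)
  expect_lt(max(abs(rf$C[, pf] - gt$C)), 1e-3)
  expect_lt(rf$lack_of_fit, 1e-8)

  # 2 percent multiplicative noise: component curves still recovered
  Dn <- make_saxs_mixture(S0, model, temps, s = comps$grid,
                          noise_frac = 0.02, seed = 5)
  rn <- mcr_als(Dn, 3)
  pn <- match_components(rn$S, gt$S)
  for (k in 1:3) expect_gt(cor(rn$S[pn[k], ], gt$S[k, ]), 0.99)

  # lack of fit never increases along plain ALS iterations (the closure
  # renormalisation is not an orthogonal projection, so strict
  # monotonicity is only guaranteed without it)
  rn_nc <- mcr_als(Dn, 3, closure_C = FALSE)
  expect_true(all(diff(rn_nc$lof_trace) <= 1e-10))
  # residual definition
  expect_equal(rn$C %*% rn$S + rn$R,
               if (inherits(Dn, "SAXSDataset")) Dn$D else Dn,
               tolerance = 1e-12)
  expect_error(mcr_als(D1, 10), "exceeds")
})
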