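test_that("covariance matrix: degenerate, sampled and algebraic checks", {
  s <- toy60()
  ens_same <- new_ensemble(s, list(s$coords, s$coords, s$coords))
  expect_equal(max(abs(covariance_matrix(ens_same))), 0)
  expect_error(covariance_matrix(new_ensemble(s, list(s$coords))),
               "2 frames")

  # diagonal Gaussian: diagonal approaches sigma^2 (superposition removes
  # 6 of 180 DOF, well inside the 10 percent band)
  sigma2 <- 0.25
  rs <- thermint:::.local_rng(21)
  fr <- lapply(seq_len(5000), function(i)
    s$coords + matrix(rs$norm(180), 60, 3) * sqrt(sigma2))
  ens <- new_ensemble(s, fr)
  C <- covariance_matrix(ens)
  expect_equal(mean(diag(C)), sigma2, tolerance = 0.1)
  expect_true(isSymmetric(C))
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)

  # trace identity with B-factors over the same alignment
  bf <- b_factors(ens, per = "atom")
  expect_equal(sum(diag(C)), sum(bf$per_atom_b) * 3 / (8 * pi^2),
               tolerance = 1e-10)
})

test_that("essential space extraction", {
  v <- c(3, -4, 0, 0, 0, 12)
  sp1 <- essential_space(tcrossprod(v), n_modes = 1)
  expect_equal(sp1$eigenvalues[1], sum(v^2))
  expect_equal(abs(sum(sp1$eigenvectors[, 1] * v / sqrt(sum(v^2)))), 1,
               tolerance = 1e-12)

  spI <- essential_space(diag(6), n_modes = 5)
  expect_equal(spI$eigenvalues, rep(1, 5))
  expect_equal(crossprod(spI$eigenvectors), diag(5), tolerance = 1e-12)
  expect_error(essential_space(diag(6), n_modes = 7), "exceeds")

  # planted low-rank + noise covariance
  set.seed(31)
  V <- qr.Q(qr(matrix(rnorm(300 * 3), 300, 3)))
  C <- V %*% diag(c(50, 20, 10)) %*% t(V) + diag(0.01, 300)
  sp <- essential_space(C, n_modes = 3)
  for (k in 1:3) {
    expect_gt(abs(sum(sp$eigenvectors[, k] * V[, k])), 0.99)
  }
  # variance-target selection
  spv <- essential_space(C, variance_target = 0.9)
  expect_lte(spv$eigenvalues[length(spv$eigenvalues)] /
               spv$eigenvalues[1], 1)
  expect_gte(spv$variance_explained[length(spv$eigenvalues)], 0.9)
})

test_that("Hess similarity identities and random-subspace null", {
  set.seed(41)
  Q <- qr.Q(qr(matrix(rnorm(120 * 20), 120, 20)))
  A <- Q[, 1:10]; B <- Q[, 11:20]
  expect_equal(hess_similarity(A, A, 10), 1, tolerance = 1e-12)
  expect_equal(hess_similarity(A, B, 10), 0, tolerance = 1e-12)
  expect_equal(hess_similarity(A, B, 10), hess_similarity(B, A, 10))
  expect_error(hess_similarity(A, B, 15), "only")
  expect_error(hess_similarity(A, Q[1:60, 1:10], 10), "dimension")

  nulls <- hess_similarity_null(10, 300, n_draws = 200, seed = 3)
  expect_equal(mean(nulls), 10 / 300, tolerance = 0.2)
  expect_true(all(nulls >= 0 & nulls <= 1))
})

test_that("relative similarity of matched and mismatched dynamics", {
  ref <- toy60()
  set.seed(51)
  spec <- lapply(1:12, function(k) list(v = rnorm(180), lambda = 120 / k))
  eA <- sample_gaussian_ensemble(ref, spec, 0.1, 600, seed = 11)
  eB <- sample_gaussian_ensemble(ref, spec, 0.1, 600, seed = 12)
  rsim <- relative_similarity(eA, eB, n = 8, reference = ref)
  expect_gt(rsim$kappa, 0.8)
  expect_lt(rsim$kappa, 1.2)
  expect_true(rsim$gamma >= 0 && rsim$gamma <= 1)
  expect_true(rsim$gamma_self_A > 0 && rsim$gamma_self_A <= 1)

  # orthogonal planted dominant modes: kappa far below 1
  specs <- lapply(1:16, function(k) list(v = rnorm(180), lambda = 0))
  V <- qr.Q(qr(do.call(cbind, lapply(specs, `[[`, "v"))))
  mk <- function(cols, sd) sample_gaussian_ensemble(
    ref, lapply(cols, function(k) list(v = V[, k], lambda = 80)),
    0.05, 400, seed = sd)
  rs2 <- relative_similarity(mk(1:8, 13), mk(9:16, 14), n = 8,
                             reference = ref)
  expect_lt(rs2$kappa, 0.2)
  expect_error(relative_similarity(
    new_ensemble(ref, list(ref$coords, ref$coords)),
    eA), "4 frames")
})

test_that("transition vector construction and invariances", {
  ref <- toy60()
  refB <- ref
  refB$coords[21:40, ] <- refB$coords[21:40, ] + 8  # internal deformation
  set.seed(61)
  eA <- sample_gaussian_ensemble(ref, list(list(v = rnorm(180), lambda = 1)),
                                 0.05, 150, seed = 2)
  eB <- sample_gaussian_ensemble(refB, list(list(v = rnorm(180), lambda = 1)),
                                 0.05, 200, seed = 3)
  tv <- transition_vector(eA, eB, seed = 1, reference = ref)
  expect_equal(sqrt(sum(tv$r^2)), 1, tolerance = 1e-10)

  # parallel to the aligned inter-state displacement
  dA <- kabsch_superpose(ref$coords, ref$coords)$coords
  dB <- kabsch_superpose(refB$coords, ref$coords)$coords
  d <- as.vector(t(dB - dA)); d <- d / sqrt(sum(d^2))
  expect_gt(abs(sum(tv$r * d)), 0.99)

  # self meta-ensemble: r is the first ED mode
  tvs <- transition_vector(eA, eA, seed = 1, reference = ref)
  sp <- essential_space(covariance_matrix(eA, reference = ref), n_modes = 1)
  expect_gt(abs(sum(tvs$r * sp$eigenvectors[, 1])), 0.99)
  expect_error(transition_vector(eA, new_ensemble(
    new_structure(matrix(0, 3, 3) + 1:3), list(matrix(1:9, 3, 3)))),
    "incompatible")
})

test_that("overlap projections and sign invariance", {
  set.seed(71)
  V <- qr.Q(qr(matrix(rnorm(90 * 5), 90, 5)))
  sp <- list(eigenvectors = V, eigenvalues = rep(1, 5), n_atoms = 30)
  class(sp) <- "EssentialSpace"
  expect_equal(overlap(sp, V[, 1], 5), 1)
  # orthogonal-complement vector
  w <- rnorm(90); w <- w - V %*% crossprod(V, w); w <- w / sqrt(sum(w^2))
  expect_equal(overlap(sp, w, 5), 0, tolerance = 1e-10)
  # 45 degrees between mode 1 and the complement
  r45 <- (V[, 1] + as.numeric(w)) / sqrt(2)
  expect_equal(overlap(sp, r45, 5), sqrt(0.5), tolerance = 1e-10)
  # sign invariance and monotonicity in n
  expect_equal(overlap(sp, -r45, 5), overlap(sp, r45, 5))
  ovs <- vapply(1:5, function(n) overlap(sp, r45, n), numeric(1))
  expect_true(all(diff(ovs) >= -1e-12))
  expect_error(overlap(sp, 2 * V[, 1], 5), "unit")
})
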