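test_that("PDB reading, writing and round trips", {
  p <- write_tiny_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_structure(p)
  expect_equal(n_atoms(s), 3L)
  expect_equal(s$residue_index, c(1L, 1L, 2L))
  expect_equal(s$element, c("N", "C", "C"))
  expect_equal(s$radii, c(1.55, 1.70, 1.70))

  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, p2)
  s2 <- read_structure(p2)
  expect_equal(s2$coords, s$coords, tolerance = 1e-3)
  expect_identical(s2$residue_name, s$residue_name)
})

test_that("malformed and unknown-element inputs are informative errors", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      xx.xxx   6.134  -6.504  1.00  0.00           C",
    "END"), p)
  expect_error(read_structure(p), "line 1")
  expect_error(new_structure(matrix(0, 1, 3), element = "XX"),
               "unknown element")
  expect_error(new_structure(matrix(c(0, NA, 0), 1, 3)), "finite")
  expect_error(new_structure(matrix(0, 2, 3), residue_index = c(2, 1)),
               "non-decreasing")
})

test_that("XYZ parsing matches hand-parsed values", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "five points",
               "C 0.0 0.0 0.0", "N 1.5 0.0 0.0", "O 0.0 2.5 0.0",
               "S 0.0 0.0 3.5", "H 1.0 1.0 1.0"), p)
  s <- read_structure(p)
  expect_equal(n_atoms(s), 5L)
  expect_equal(s$coords[4, ], c(0, 0, 3.5))
  expect_equal(s$radii, c(1.70, 1.55, 1.52, 1.80, 1.20))
})

test_that("multi-model ensembles read frame-by-frame with validation", {
  ens0 <- make_disordered_ensemble(toy60(), list(c(21, 40)), 0.5, 5,
                                   n_frames = 10, seed = 2)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens0, p)
  ens <- read_ensemble(p)
  expect_equal(n_frames(ens), 10L)
  expect_equal(ens$frames[[7]], ens0$frames[[7]], tolerance = 1e-3)
  expect_error(read_structure(p), "multi-model")

  # single model is a valid 1-frame ensemble
  p1 <- write_tiny_pdb(withr::local_tempfile(fileext = ".pdb"))
  expect_equal(n_frames(read_ensemble(p1)), 1L)

  # a frame with a missing atom is reported by index
  lines <- readLines(p)
  drop <- grep("^ATOM", lines)[121]   # first atom of frame 3
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-drop], p3)
  expect_error(read_ensemble(p3), "frame 3")
})

test_that("kabsch superposition minimises mask RMSD", {
  set.seed(5)
  X <- matrix(rnorm(12), 4, 3) * 3
  # proper rigid motion leaves zero RMSD
  Y <- rotate_z(X, pi / 2, c(1, 2, 3))
  expect_lt(kabsch_superpose(X, Y)$rmsd, 1e-12)
  fit <- kabsch_superpose(X, Y)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # noisy 4-point problem: no better rotation exists on a fine grid
  Y2 <- X + matrix(rnorm(12), 4, 3)
  r_kabsch <- kabsch_superpose(X, Y2)$rmsd
  grid_best <- Inf
  ang <- seq(0, 2 * pi, length.out = 24)
  Rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
  Ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                          c(-sin(t), 0, cos(t)))
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y2, 2, colMeans(Y2))
  for (a in ang) for (b in seq(0, pi, length.out = 12)) for (g in ang) {
    R <- Rz(a) %*% Ry(b) %*% Rz(g)
    r <- sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
    if (r < grid_best) grid_best <- r
  }
  expect_lte(r_kabsch, grid_best + 1e-9)

  # invariance to rigid motion of either input
  expect_equal(kabsch_superpose(rotate_z(X, 1.1, c(4, 5, 6)), Y2)$rmsd,
               r_kabsch, tolerance = 1e-9)
  expect_error(kabsch_superpose(X[1:2, ], Y2[1:2, ]), "at least 3")
  lin <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(lin, lin + 1), "degenerate")
})

test_that("TM-score identities and oracle agreement", {
  s <- toy60()
  expect_equal(tm_score(s, s), 1)
  far <- s$coords + matrix(seq_len(180) * 2, 60, 3)
  expect_lt(tm_score(far, s$coords), 0.15)
  expect_error(tm_score(s$coords[1:10, ], s$coords[1:10, ]), "length")
  expect_error(tm_score(s$coords[1:20, ], s$coords[1:30, ]), "differ")

  # 20-residue pair with a dominant superposition basin: seed-and-refine
  # must agree with an independent multi-start optimiser
  set.seed(17)
  X <- s$coords[1:20, ]
  Y <- X + matrix(rnorm(60), 20, 3) * 0.4
  Y[9:11, ] <- Y[9:11, ] + 4       # one displaced stretch
  Y <- rotate_z(Y, 1.2, c(3, -4, 7))
  tm <- tm_score(X, Y)
  oracle <- tm_oracle(X, Y)
  expect_gt(tm, 0)
  expect_lte(tm, 1)
  expect_equal(tm, oracle, tolerance = 1e-3)
})

test_that("radius of gyration closed forms and invariance", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radius_of_gyration(cube), sqrt(3))
  expect_equal(radius_of_gyration(rotate_z(cube, 0.7, c(5, -2, 1))),
               sqrt(3), tolerance = 1e-12)
  expect_error(radius_of_gyration(two, c(0, 0)), "all-zero")
})

test_that("B-factors: zero, locality, and Gaussian-jitter expectation", {
  s <- toy60()
  ens_same <- new_ensemble(s, list(s$coords, s$coords, s$coords))
  expect_equal(max(b_factors(ens_same)$per_residue_b), 0)
  expect_error(b_factors(new_ensemble(s, list(s$coords))), "2 frames")

  # one mobile residue, rest frozen (alignment on the frozen part)
  fr <- lapply(1:20, function(i) {
    X <- s$coords
    X[30, ] <- X[30, ] + c(i %% 5, 0, 0)
    X
  })
  bf <- b_factors(new_ensemble(s, fr, align_mask = setdiff(1:60, 30)))
  expect_gt(bf$per_residue_b[30], 1)
  expect_lt(max(bf$per_residue_b[-30]), 1e-20)

  # isotropic jitter sigma: <B> -> 8 pi^2 sigma^2 (superposition removes
  # 6 rigid DOF, a factor (3N-6)/3N = 0.967 at N = 60, inside the band)
  sigma <- 0.3
  rs <- thermint:::.local_rng(11)
  fr2 <- lapply(seq_len(6000), function(i)
    s$coords + matrix(rs$norm(180), 60, 3) * sigma)
  bf2 <- b_factors(new_ensemble(s, fr2), per = "atom")
  expect_equal(mean(bf2$per_atom_b), 8 * pi^2 * sigma^2, tolerance = 0.05)
})

test_that("contact map geometry, separation filter and counts", {
  # 3 collinear residues spaced 4 A
  s3 <- new_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  cm <- contact_map(s3, cutoff = 5.5, min_seq_sep = 1)
  expect_equal(cm$pairs, cbind(c(1, 2), c(2, 3)), ignore_attr = TRUE)
  expect_equal(unname(cm$per_residue_counts), c(1L, 2L, 1L))
  expect_equal(nrow(contact_map(s3, 5.5, min_seq_sep = 3)$pairs), 0L)

  far <- new_structure(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(nrow(contact_map(far, 5.5, 1)$pairs), 0L)

  # counts always consistent with pairs
  cm2 <- contact_map(toy60())
  tab <- table(factor(c(cm2$pairs), levels = names(cm2$per_residue_counts)))
  expect_equal(as.integer(tab), unname(cm2$per_residue_counts))
  expect_error(contact_map(s3, cutoff = -1), "positive")
})

test_that("SASA quadrature against analytic spheres", {
  iso <- new_structure(matrix(0, 1, 3))     # carbon, r = 1.7
  a <- sasa(iso, n_points = 240)
  expect_equal(a$per_atom_area, 4 * pi * 3.1^2, tolerance = 0.02)

  # fully enclosed: H (r 1.2) at the centre of a coincident S (r 1.8)
  encl <- new_structure(rbind(c(0, 0, 0), c(0.05, 0, 0)),
                        element = c("H", "S"))
  expect_equal(sasa(encl)$per_atom_area[1], 0)

  # two identical atoms beyond the sum of expanded radii: full spheres
  two <- new_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(sasa(two)$per_atom_area, rep(4 * pi * 3.1^2, 2),
               tolerance = 0.02)

  # total area shrinks monotonically as two rigid bodies approach
  areas <- vapply(c(10, 6, 4.5, 3.5), function(d)
    sum(sasa(new_structure(rbind(c(0, 0, 0), c(d, 0, 0))))$per_atom_area),
    numeric(1))
  expect_true(all(diff(areas) < 1e-6))

  # per-residue sums equal their member atoms; Trp side-chain sum
  w <- world_small()
  sr <- sasa(w$native, n_points = 120)
  expect_equal(sum(sr$per_residue_area), sum(sr$per_atom_area))
  expect_equal(sr$trp_area,
               sum(sr$per_atom_area[w$native$residue_name == "TRP"]))
  expect_lte(sr$trp_area, sum(sr$per_atom_area))
  expect_error(sasa(w$native, n_points = 10), ">= 60")
})
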