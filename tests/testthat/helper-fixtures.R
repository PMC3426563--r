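# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

toy60 <- function() {
  fixture("toy60", function()
    make_toy_protein(60, list(c(1, 20), c(41, 60)), list(c(21, 40)),
                     trp_positions = c(5, 9, 13, 17), seed = 1L))
}

# small annotation world shared by the filter tests
world_small <- function() {
  fixture("world_small", function()
    toy_intermediate_world(seed = 1L, n_frames = 60L, n_ref_frames = 60L))
}

# a handwritten 3-atom PDB fixture
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2      12.345   7.890  -4.000  1.00  0.00           C",
    "END"), path)
  path
}

# rigid-motion helper
rotate_z <- function(X, theta, shift = c(0, 0, 0)) {
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  sweep(X %*% t(R), 2, shift, `+`)
}

# brute-force oracle: maximise the TM sum over rigid motions (many optim
# starts seeded from mask superpositions), independent of tm_score()'s
# seed-and-refine path
tm_oracle <- function(X, Y, n_starts = 40L) {
  L <- nrow(X)
  d0 <- 1.24 * (L - 15)^(1 / 3) - 1.8
  M0 <- kabsch_superpose(X, Y)$coords   # dominant basin start
  obj <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    R <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)) %*%
      rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb)) %*%
      rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
    M <- sweep(M0 %*% t(R), 2, p[4:6], `+`)
    -mean(1 / (1 + (rowSums((M - Y)^2)) / d0^2))
  }
  starts <- list(rep(0, 6))
  set.seed(99)
  for (i in seq_len(n_starts)) {
    starts[[i + 1]] <- c(stats::runif(3, 0, 2 * pi), stats::rnorm(3, 0, 4))
  }
  best <- -Inf
  for (s0 in starts) {
    r <- stats::optim(s0, obj, method = "BFGS",
                      control = list(maxit = 300))
    if (-r$value > best) best <- -r$value
  }
  best
}
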