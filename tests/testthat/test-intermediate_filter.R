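test_that("criteria presets carry the published thresholds", {
  loose <- criteria_set("loose")
  expect_equal(c(loose$sas_trp_min, loose$sas_trp_max), c(100, 300))
  expect_equal(loose$chi_max, 1.5)
  expect_equal(loose$phi_err_max, 2)
  strict <- criteria_set("strict")
  expect_equal(strict$chi_max, 1.0)
  expect_equal(strict$phi_err_max, 1.0)
  expect_equal(c(strict$sas_trp_min, strict$sas_trp_max), c(100, 300))
  expect_error(criteria_set("custom", sas_trp_min = 100), "all four")
  expect_error(criteria_set("custom", sas_trp_min = 300, sas_trp_max = 100,
                            chi_max = 1, phi_err_max = 1), "below")
})

test_that("annotation logic: windows, degeneracy, subset, monotonicity", {
  w <- world_small()
  loose <- annotate(w$ensemble, w$native_map, w$exp_phi, w$exp_saxs,
                    criteria_set("loose"))
  strict <- annotate(w$ensemble, w$native_map, w$exp_phi, w$exp_saxs,
                     criteria_set("strict"))

  # frames below the SAS window fail regardless of the other criteria:
  # any frame with sas < 100 must not pass, whatever its chi/phi
  low_sas <- loose$per_frame$sas_trp < 100 | loose$per_frame$sas_trp > 300
  expect_true(all(!loose$per_frame$passes[low_sas]))

  # strict-pass frames are a subset of loose-pass frames
  expect_true(all(which(strict$per_frame$passes) %in%
                    which(loose$per_frame$passes)))

  # fraction is the mean of passes; marginal rates dominate the joint rate
  expect_equal(loose$fraction_intermediate, mean(loose$per_frame$passes))
  expect_true(all(loose$per_criterion_pass_rates >=
                    loose$fraction_intermediate - 1e-12))

  # degenerate criteria reduce to a pure SAS filter
  sas_only <- annotate(w$ensemble, w$native_map, w$exp_phi, w$exp_saxs,
                       criteria_set("custom", sas_trp_min = 100,
                                    sas_trp_max = 300, chi_max = Inf,
                                    phi_err_max = Inf))
  expect_equal(sas_only$fraction_intermediate,
               mean(loose$per_frame$sas_trp >= 100 &
                      loose$per_frame$sas_trp <= 300))

  # tightening any single threshold never raises the fraction
  fr <- function(chi_max = 1.5, phi_max = 2, smin = 100, smax = 300) {
    annotate(w$ensemble, w$native_map, w$exp_phi, w$exp_saxs,
             criteria_set("custom", sas_trp_min = smin, sas_trp_max = smax,
                          chi_max = chi_max,
                          phi_err_max = phi_max))$fraction_intermediate
  }
  chis <- vapply(c(2, 1.5, 1, 0.5), function(cm) fr(chi_max = cm),
                 numeric(1))
  expect_true(all(diff(chis) <= 1e-12))
  phis <- vapply(c(4, 2, 1, 0.5), function(pm) fr(phi_max = pm), numeric(1))
  expect_true(all(diff(phis) <= 1e-12))
  sass <- vapply(c(300, 250, 220), function(sm) fr(smax = sm), numeric(1))
  expect_true(all(diff(sass) <= 1e-12))
})

test_that("pipeline produces its full report bundle deterministically", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(seed = 7, output_dir = out1,
              simulate = list(n_frames = 30, n_ref_frames = 40),
              cluster_radius = 3, ed_modes = 5)
  res <- run_pipeline(cfg)
  produced <- list.files(out1)
  expect_true(all(c("descriptors.tsv", "b_factors.tsv", "clusters.tsv",
                    "ed_similarity.json", "phi_profile.tsv",
                    "chi_series.tsv", "summary.json", "pipeline.log")
                  %in% produced))
  cfg$output_dir <- out2
  run_pipeline(cfg)
  for (f in c("summary.json", "ed_similarity.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # missing experimental input is a clean, named error
  bad <- list(seed = 1, output_dir = withr::local_tempdir(),
              inputs = list(ensemble = "nope.pdb", native = "nope.pdb",
                            exp_saxs = "missing.dat", exp_phi = "m.tsv"))
  expect_error(run_pipeline(bad), "nope.pdb")
  expect_error(run_pipeline(list(seed = 1)), "output_dir")
})

test_that("pipeline runs from files written by the simulate subcommand", {
  fixdir <- withr::local_tempdir()
  thermint_cli(c("simulate", "--out", fixdir, "--seed", "3",
                 "--n-frames", "12"))
  expect_true(file.exists(file.path(fixdir, "native.pdb")))
  out <- withr::local_tempdir()
  cfgfile <- file.path(fixdir, "config.json")
  jsonlite::write_json(list(
    seed = 3, output_dir = out,
    inputs = list(ensemble = file.path(fixdir, "ensemble.pdb"),
                  native = file.path(fixdir, "native.pdb"),
                  exp_saxs = file.path(fixdir, "exp_intermediate.dat"),
                  exp_phi = file.path(fixdir, "exp_phi.tsv"))),
    cfgfile, auto_unbox = TRUE)
  res <- run_pipeline(cfgfile)
  expect_true(file.exists(file.path(out, "summary.json")))
  sm <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(sm$n_frames, 12L)
})
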