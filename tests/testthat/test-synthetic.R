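make_spec <- function(material = mcc_model(), scf = mcc_scf(),
                      rs = study_rs(), ...) {
  generator_spec(material, study_geometry(),
                 compaction_settings(scf, rs), ...)
}

test_that("compression-profile generation is deterministic and mode-checked", {
  mat <- mcc_model()
  a <- generate_compression_profiles(mat, mode = "power_law", noise_cv = 0.02,
                                     seed = 5)
  b <- generate_compression_profiles(mat, mode = "power_law", noise_cv = 0.02,
                                     seed = 5)
  expect_identical(a, b)
  c <- generate_compression_profiles(mat, mode = "power_law", noise_cv = 0.02,
                                     seed = 6)
  expect_false(identical(a, c))
  expect_error(generate_compression_profiles(mat, noise_cv = 0), "mode")
})

test_that("generated records round-trip the sampled density exactly", {
  mat <- mcc_model()
  recs <- generate_compression_profiles(mat, mode = "power_law",
                                        noise_cv = 0.05, seed = 9, n = 4)
  density <- in_die_density(recs$mass, in_die_volume(recs$thickness, recs$radius))
  # the density implied by the back-solved thickness is the sampled one;
  # refitting the noiseless law after dividing out the noise is exact
  c0 <- 0.95 * mat$rho0 / 250^(1 / mat$K)
  noise <- density / (c0 * recs$pressure^(1 / mat$K))
  expect_true(all(noise > 0.8 & noise < 1.25))
})

test_that("ribbon study without attenuation closes the Midoux loop", {
  spec <- make_spec(noise_cv = 0, replicates = 2)
  study <- generate_ribbon_study(spec)
  mat <- spec$material
  geom <- spec$geometry
  sfg <- sf_gap(study$ribbon_runs$mass_g, study$ribbon_runs$duration_s,
                study$ribbon_runs$rs_rpm, geom, mat$rho0)
  pmax_cells <- pmax_from_scf(study$ribbon_runs$scf_kN_cm, geom, mat$K)
  sfmi <- predict_sf_gap(midoux_number(pmax_cells, mat$P_alpha), mat$K,
                         mat$rho_alpha, mat$rho0)
  expect_equal(prediction_accuracy(sfg, sfmi), rep(1, nrow(study$ribbon_runs)),
               tolerance = 1e-12)
  expect_true(all(study$truth$attenuation == 1))
  # elastic recovery links the two solid fractions
  expect_equal(study$truth$sf_ribbon, study$truth$sf_gap * 0.9,
               tolerance = 1e-12)
})

test_that("dwell-time attenuation lowers densification only below the yield pressure", {
  spec <- make_spec(noise_cv = 0, attenuation = shortest_dt_attenuation)
  study <- generate_ribbon_study(spec)
  tr <- study$truth
  low <- tr$pmax_nominal_MPa < spec$material$yield_pressure
  short <- tr$dt_ms < 25
  expect_true(all(tr$attenuation[low & short] == 0.9))
  expect_true(all(tr$attenuation[!low | !short] == 1))
  # and the effect propagates to the ribbon solid fraction within each series
  for (scf in unique(tr$scf_kN_cm[low])) {
    series <- tr[tr$scf_kN_cm == scf, ]
    expect_lt(series$sf_ribbon[which.max(series$rs_rpm)],
              series$sf_ribbon[which.min(series$rs_rpm)])
  }
})

test_that("replicate count changes only the replicate dimension", {
  s3 <- make_spec(noise_cv = 0.01, replicates = 3, seed = 4)
  s6 <- make_spec(noise_cv = 0.01, replicates = 6, seed = 4)
  r3 <- generate_ribbon_study(s3)$ribbon_runs
  r6 <- generate_ribbon_study(s6)$ribbon_runs
  expect_identical(names(r3), names(r6))
  expect_equal(nrow(r6), 2 * nrow(r3))
  # per-condition substreams: the first 3 replicates of each cell are identical
  first3 <- do.call(rbind, lapply(split(r6, interaction(r6$scf_kN_cm, r6$rs_rpm)),
                                  function(d) d[1:3, ]))
  key <- function(d) d[order(d$scf_kN_cm, d$rs_rpm, d$mass_g), "mass_g"]
  expect_equal(key(first3), key(r3), tolerance = 1e-15)
})

test_that("fracture-test generation inverts the reducers", {
  b <- generate_fracture_tests(2.4, "bend", noise_cv = 0, n = 3)
  expect_equal(ts_ribbon(b$force_N, b$span_mm, b$width_mm, b$thickness_mm),
               rep(2.4, 3), tolerance = 1e-12)
  d <- generate_fracture_tests(1.8, "diametral", noise_cv = 0, n = 3)
  expect_equal(ts_tablet(d$force_N, d$diameter_mm, d$thickness_mm),
               rep(1.8, 3), tolerance = 1e-12)
  # seeded Monte-Carlo: n = 100 at 5 percent noise recovers the mean within 2 percent
  mc <- generate_fracture_tests(2.0, "bend", noise_cv = 0.05, seed = 13, n = 100)
  ts <- ts_ribbon(mc$force_N, mc$span_mm, mc$width_mm, mc$thickness_mm)
  expect_lt(abs(mean(ts) - 2.0) / 2.0, 0.02)
  expect_error(generate_fracture_tests(-1, "bend"), "true_ts")
})

test_that("estimator dispersion shrinks with the square root of the sample size", {
  recover <- function(n, seed) {
    d <- generate_fracture_tests(2.0, "diametral", noise_cv = 0.10,
                                 seed = seed, n = n)
    mean(ts_tablet(d$force_N, d$diameter_mm, d$thickness_mm))
  }
  seeds <- 1:40
  sd_small <- sd(vapply(seeds, function(s) recover(8, s), numeric(1)))
  sd_large <- sd(vapply(seeds, function(s) recover(32, s), numeric(1)))
  # fourfold n should halve the dispersion; allow stochastic slack
  expect_lt(sd_large, sd_small / 1.4)
})

test_that("a written synthetic study is bit-identical under a fixed seed", {
  spec <- make_spec(noise_cv = 0.01, seed = 21, replicates = 3,
                    scf = c(2.9, 7.6), rs = c(1, 10))
  d1 <- file.path(tempdir(), "synth1")
  d2 <- file.path(tempdir(), "synth2")
  write_synthetic_study(spec, d1)
  write_synthetic_study(spec, d2)
  for (f in c("ribbon_runs.csv", "pycnometry.csv", "bend_tests.csv",
              "tablet_tests.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # the files re-enter through the measurement readers
  rr <- read_ribbon_runs(file.path(d1, "ribbon_runs.csv"))
  expect_equal(nrow(rr), 2 * 2 * 3)
  expect_gt(nrow(read_pycnometry(file.path(d1, "pycnometry.csv"))), 0)
  expect_gt(nrow(read_bend_tests(file.path(d1, "bend_tests.csv"))), 0)
  expect_gt(nrow(read_tablet_tests(file.path(d1, "tablet_tests.csv"))), 0)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generator validates attenuation output and recovery range", {
  expect_error(make_spec(elastic_recovery = 0.5), "elastic_recovery")
  bad <- make_spec(attenuation = function(dt) 1.5)
  expect_error(generate_ribbon_study(bad), "multiplier")
})
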