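test_that("maximum pressure closed form reproduces the study settings", {
  geom <- study_geometry()
  expect_equal(round(pmax_from_scf(mcc_scf(), geom, K = 3.84)),
               c(41, 56, 81, 106))
  # lactose settings away from integer-rounding boundaries
  expect_equal(round(pmax_from_scf(c(3.5, 7.0, 8.6, 10.3), geom, K = 6.90)),
               c(66, 131, 161, 193))
  # linearity in SCF and zero-force limit
  p1 <- pmax_from_scf(1, geom, K = 3.84)
  expect_equal(pmax_from_scf(3, geom, K = 3.84), 3 * p1, tolerance = 1e-12)
  expect_lt(pmax_from_scf(1e-9, geom, K = 3.84), 1e-7)
  expect_error(pmax_from_scf(-1, geom, K = 3.84), "SCF")
  # strictly increasing in K at fixed geometry
  ks <- seq(2, 10, by = 0.5)
  pk <- vapply(ks, function(k) pmax_from_scf(5, geom, k), numeric(1))
  expect_true(all(diff(pk) > 0))
})

test_that("scf_from_pmax is the exact inverse of pmax_from_scf", {
  geom <- study_geometry()
  expect_equal(round(scf_from_pmax(106, geom, K = 3.84), 1), 7.6)
  set.seed(1)
  scf <- runif(100, 0.5, 15)
  k <- runif(100, 2, 10)
  for (i in seq_along(scf)) {
    p <- pmax_from_scf(scf[i], geom, k[i])
    expect_equal(scf_from_pmax(p, geom, k[i]), scf[i], tolerance = 1e-12)
  }
  expect_error(scf_from_pmax(0, geom, K = 3.84), "Pmax")
})

test_that("pressure-angle profile equals Pmax at the gap and decreases with angle", {
  geom <- study_geometry()
  expect_equal(pressure_at_angle(0, Pmax = 200, geom, K = 3.84), 200)
  for (k in c(3.84, 6.90)) {
    grid <- seq(1e-5, 0.2, length.out = 2000)
    p <- pressure_at_angle(grid, Pmax = 200, geom, K = k)
    expect_true(all(diff(p) < 0))
    expect_true(all(p <= 200))
  }
  expect_error(pressure_at_angle(-0.1, 200, geom, K = 3.84), "theta")
  expect_error(pressure_at_angle(pi / 2, 200, geom, K = 3.84), "theta")
})

test_that("threshold angle matches a brute-force grid scan and is Pmax-free", {
  geom <- study_geometry()
  # grid-scan oracle at 1e-6 rad resolution (frozen values)
  expect_equal(threshold_angle(0.9, geom, K = 3.84), 0.021188, tolerance = 1e-4)
  expect_equal(threshold_angle(0.9, geom, K = 6.90), 0.015756, tolerance = 1e-4)
  # the 180-of-200 MPa crossing is the same angle as the 0.9 fraction
  th <- threshold_angle(0.9, geom, K = 3.84)
  expect_equal(pressure_at_angle(th, Pmax = 200, geom, K = 3.84), 180,
               tolerance = 1e-7)
  # continuity limit: fraction near 1 drives the angle to 0
  expect_lt(threshold_angle(0.99999, geom, K = 3.84), 1e-3)
  # steeper pressure drop for the higher compressibility index
  expect_lt(threshold_angle(0.9, geom, K = 6.90),
            threshold_angle(0.9, geom, K = 3.84))
})

test_that("dwell times reproduce the reference table and scale with roll speed", {
  geom <- study_geometry()
  dt_mcc <- dwell_time(study_rs(), geom, K = 3.84, round_theta = TRUE)
  dt_lac <- dwell_time(study_rs(), geom, K = 6.90, round_theta = TRUE)
  expect_equal(round(dt_mcc), c(200, 167, 133, 100, 67, 33, 20))
  expect_equal(round(dt_lac), c(150, 125, 100, 75, 50, 25, 15))
  # angular-velocity scaling: doubling RS halves the dwell time exactly
  expect_equal(dwell_time(4, geom, K = 3.84), dwell_time(2, geom, K = 3.84) / 2,
               tolerance = 1e-12)
  # DT * RS is constant for a fixed material and geometry
  prod <- dwell_time(study_rs(), geom, K = 3.84) * study_rs()
  expect_equal(max(prod) - min(prod), 0, tolerance = 1e-9)
  # the brittle material dwells less at every roll speed
  expect_true(all(dwell_time(study_rs(), geom, K = 6.90) <
                  dwell_time(study_rs(), geom, K = 3.84)))
})

test_that("pressure-time profile is internally consistent with the dwell time", {
  geom <- study_geometry()
  prof <- pressure_time_profile(RS = 2, Pmax = 200, geom, K = 3.84,
                                n_points = 4000, theta_max = 0.1)
  expect_equal(prof$pressure_MPa[1], 200)
  expect_true(all(diff(prof$pressure_MPa) <= 0))
  # time at which the profile crosses 0.9 Pmax equals the dwell time
  idx <- which.max(prof$pressure_MPa < 180)
  dt_profile_ms <- 1000 * prof$time_s[idx]
  dt_model_ms <- dwell_time(2, geom, K = 3.84)
  grid_step_ms <- 1000 * diff(prof$time_s[1:2])
  expect_lt(abs(dt_profile_ms - dt_model_ms), grid_step_ms + 1e-9)
  # halving RS doubles every time coordinate with identical pressures
  slow <- pressure_time_profile(RS = 1, Pmax = 200, geom, K = 3.84,
                                n_points = 4000, theta_max = 0.1)
  expect_equal(slow$time_s, 2 * prof$time_s, tolerance = 1e-12)
  expect_equal(slow$pressure_MPa, prof$pressure_MPa)
})

test_that("peripheral speed converts rpm to m/s", {
  expect_equal(round(peripheral_speed(2, D = 250), 3), 0.026)
  expect_equal(round(peripheral_speed(3, D = 250), 3), 0.039)
  # closed-form inversion: RS = 60 / (pi D[m]) gives exactly 1 m/s
  expect_equal(peripheral_speed(60 / (pi * 0.25), D = 250), 1,
               tolerance = 1e-12)
  expect_error(peripheral_speed(0, 250), "RS")
})

test_that("Midoux number and at-gap prediction behave as a scale-up invariant", {
  expect_equal(midoux_number(41, 1), 41)
  expect_equal(midoux_number(5, 5), 1)
  expect_error(midoux_number(0.5, 1), "nip pressure")

  expect_equal(predict_sf_gap(1, K = 3.84, rho_alpha = 0.42, rho0 = 1.56),
               0.42 / 1.56)
  mi_full <- (1.56 / 0.42)^3.84
  expect_equal(predict_sf_gap(mi_full, K = 3.84, rho_alpha = 0.42, rho0 = 1.56),
               1, tolerance = 1e-12)
  # log-domain oracle for the power-law densification
  mi <- c(5, 50, 500)
  expect_equal(suppressWarnings(
                 predict_sf_gap(mi, K = 3.84, rho_alpha = 0.42, rho0 = 1.56)),
               exp(log(mi) / 3.84) * 0.42 / 1.56, tolerance = 1e-12)
  expect_warning(predict_sf_gap(mi_full * 2, K = 3.84, rho_alpha = 0.42,
                                rho0 = 1.56), "exceed 1")
  expect_error(predict_sf_gap(0.5, K = 3.84, rho_alpha = 0.42, rho0 = 1.56),
               "at least 1")

  # constant-Mi transfer: equal Mi and K give equal predicted solid fraction
  # on two different geometries
  g1 <- roll_geometry(250, 25, 2)
  g2 <- roll_geometry(120, 40, 1.5)
  p1 <- pmax_from_scf(4, g1, K = 3.84)
  scf2 <- scf_from_pmax(p1, g2, K = 3.84)  # same Pmax, hence same Mi
  mi1 <- midoux_number(p1, 1)
  mi2 <- midoux_number(pmax_from_scf(scf2, g2, K = 3.84), 1)
  expect_equal(predict_sf_gap(mi1, 3.84, 0.42, 1.56),
               predict_sf_gap(mi2, 3.84, 0.42, 1.56), tolerance = 1e-12)
})

test_that("roll geometry validates its invariants", {
  expect_error(roll_geometry(250, 25, 0), "S")
  expect_error(roll_geometry(250, 25, 300), "smaller than roll diameter")
  g <- study_geometry()
  expect_equal(g$S / g$D, 0.008)
})
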