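#' Roll geometry
#'
#' Roll diameter, roll width and gap width of a roll compactor, all in mm.
#' The gap-to-diameter ratio `S/D` drives the pressure-angle profile; the
#' study geometry (D = 250 mm, S = 2.0 mm) has S/D = 0.008.
#'
#' @param D roll diameter (mm, > 0)
#' @param W roll width (mm, > 0)
#' @param S gap width (mm, > 0, < D)
#' @return an object of class `roll_geometry`
#' @examples
#' roll_geometry(D = 250, W = 25, S = 2)
#' @export
roll_geometry <- function(D, W, S) {
  assert_positive(D); assert_scalar(D)
  assert_positive(W); assert_scalar(W)
  assert_positive(S); assert_scalar(S)
  if (S >= D) stop("gap width `S` must be smaller than roll diameter `D`",
                   call. = FALSE)
  structure(list(D = D, W = W, S = S), class = "roll_geometry")
}

#' @export
print.roll_geometry <- function(x, ...) {
  cat(sprintf("<roll_geometry> D = %g mm, W = %g mm, S = %g mm (S/D = %g)\n",
              x$D, x$W, x$S, x$S / x$D))
  invisible(x)
}

#' Process settings grid
#'
#' Expands specific compaction forces and roll speeds into the full grid of
#' process conditions of a study.
#'
#' @param scf specific compaction forces (kN/cm, > 0)
#' @param rs roll speeds (rpm, > 0)
#' @return data frame with columns `scf_kN_cm`, `rs_rpm`
#' @export
compaction_settings <- function(scf, rs) {
  assert_positive(scf, "scf")
  assert_positive(rs, "rs")
  expand.grid(scf_kN_cm = scf, rs_rpm = rs, KEEP.OUT.ATTRS = FALSE)
}

#' Maximum roll pressure from the specific compaction force
#'
#' Closed-form Johanson-type relation
#' `Pmax = (2 SCF / D) * sqrt(2 K / (pi S/D))`,
#' with SCF converted from kN/cm to N/m and lengths to m; the result is
#' returned in MPa. Pmax is linear in SCF and increases with the
#' compressibility index K at fixed geometry.
#'
#' @param SCF specific compaction force (kN/cm, > 0); vectorized
#' @param geometry a [roll_geometry()]
#' @param K compressibility index (> 1)
#' @return maximum pressure in MPa
#' @examples
#' geom <- roll_geometry(250, 25, 2)
#' round(pmax_from_scf(c(2.9, 4.0, 5.8, 7.6), geom, K = 3.84))  # 41 56 81 106
#' @export
pmax_from_scf <- function(SCF, geometry, K) {
  assert_positive(SCF, "SCF")
  assert_positive(K); assert_scalar(K)
  stopifnot(inherits(geometry, "roll_geometry"))
  scf_nm <- kn_per_cm_to_n_per_m(SCF)
  D <- mm_to_m(geometry$D)
  S <- mm_to_m(geometry$S)
  pa_to_mpa((2 * scf_nm / D) * sqrt(2 * K / (pi * S / D)))
}

#' Specific compaction force from a target maximum pressure
#'
#' Exact inverse of [pmax_from_scf()].
#'
#' @param Pmax maximum pressure (MPa, > 0); vectorized
#' @inheritParams pmax_from_scf
#' @return specific compaction force in kN/cm
#' @export
scf_from_pmax <- function(Pmax, geometry, K) {
  assert_positive(Pmax, "Pmax")
  assert_positive(K); assert_scalar(K)
  stopifnot(inherits(geometry, "roll_geometry"))
  D <- mm_to_m(geometry$D)
  S <- mm_to_m(geometry$S)
  scf_nm <- Pmax * 1e6 * D / (2 * sqrt(2 * K / (pi * S / D)))
  scf_nm / 1e5
}

# Dimensionless pressure ratio P(theta)/Pmax of the Johanson profile.
# Equal to 1 at theta = 0 and monotone decreasing over the physical range.
pressure_ratio_at_angle <- function(theta, geometry, K) {
  sd <- geometry$S / geometry$D
  ((sd / ((1 + sd - cos(theta)) * cos(theta))))^(K * cos(theta))
}

#' Pressure at a roll angle
#'
#' Johanson pressure-angle profile
#' `P(theta) = Pmax * [ (S/D) / ((1 + S/D - cos theta) cos theta) ]^(K cos theta)`.
#' The bracketed ratio equals 1 at the gap (theta = 0) and is below 1 for
#' theta > 0, so the profile never exceeds Pmax.
#'
#' @param theta roll angle from the gap (rad, in `[0, pi/2)`); vectorized
#' @param Pmax maximum pressure at the gap (MPa, > 0)
#' @inheritParams pmax_from_scf
#' @return pressure in MPa
#' @export
pressure_at_angle <- function(theta, Pmax, geometry, K) {
  if (!is.numeric(theta) || anyNA(theta) || any(theta < 0) || any(theta >= pi / 2)) {
    stop("`theta` must lie in [0, pi/2)", call. = FALSE)
  }
  assert_positive(Pmax, "Pmax")
  assert_positive(K); assert_scalar(K)
  stopifnot(inherits(geometry, "roll_geometry"))
  Pmax * pressure_ratio_at_angle(theta, geometry, K)
}

#' Angle at which the pressure falls to a fraction of Pmax
#'
#' Solves `P(theta)/Pmax = fraction` on the pre-gap branch by bisection-based
#' root finding on (1e-8, 0.5] rad. Because the ratio form cancels Pmax, the
#' threshold angle depends only on the geometry (through S/D), the material
#' (through K) and the fraction.
#'
#' @param fraction pressure fraction of Pmax (in (0, 1)); 0.9 defines the
#'   dwell-time convention
#' @inheritParams pmax_from_scf
#' @return threshold angle theta* in rad
#' @examples
#' geom <- roll_geometry(250, 25, 2)
#' threshold_angle(0.9, geom, K = 3.84)  # about 0.0212 rad
#' @export
threshold_angle <- function(fraction, geometry, K) {
  assert_positive(fraction); assert_scalar(fraction)
  if (fraction >= 1) stop("`fraction` must be below 1", call. = FALSE)
  assert_positive(K); assert_scalar(K)
  stopifnot(inherits(geometry, "roll_geometry"))
  f <- function(th) pressure_ratio_at_angle(th, geometry, K) - fraction
  lower <- 1e-8; upper <- 0.5
  if (f(lower) <= 0 || f(upper) >= 0) {
    stop(sprintf(
      "no sign change for fraction %.6g on (%g, %g]: f(lower) = %.3g, f(upper) = %.3g",
      fraction, lower, upper, f(lower), f(upper)), call. = FALSE)
  }
  root <- stats::uniroot(f, c(lower, upper), tol = 1e-13)$root
  resid <- abs(pressure_ratio_at_angle(root, geometry, K) - fraction)
  if (resid > 1e-10) {
    stop(sprintf("root residual %.3g exceeds 1e-10", resid), call. = FALSE)
  }
  root
}

#' Dwell time above a pressure threshold
#'
#' Time spent, before gap passage, at pressures above `fraction * Pmax`:
#' `DT = theta* / omega` with `omega = 2 pi RS / 60` rad/s, returned in ms.
#' Only the pre-gap branch of the profile is counted; the post-gap relaxation
#' branch is ignored. The threshold angle is independent of Pmax and RS, so
#' `DT * RS` is constant for a fixed material and geometry.
#'
#' With `round_theta = TRUE` the threshold angle is rounded to 0.1 degree
#' before division by the angular velocity, the convention under which the
#' reference dwell-time table (200/150 ms at 1 rpm for K = 3.84/6.90,
#' S/D = 0.008) is reproduced exactly.
#'
#' @param RS roll speed (rpm, > 0); vectorized
#' @inheritParams threshold_angle
#' @param fraction pressure fraction defining the threshold (default 0.9)
#' @param round_theta round the threshold angle to 0.1 degree first
#' @return dwell time in ms
#' @examples
#' geom <- roll_geometry(250, 25, 2)
#' dwell_time(1, geom, K = 3.84, round_theta = TRUE)  # 200 ms
#' @export
dwell_time <- function(RS, geometry, K, fraction = 0.9, round_theta = FALSE) {
  assert_positive(RS, "RS")
  theta_star <- threshold_angle(fraction, geometry, K)
  if (round_theta) {
    theta_star <- deg_to_rad(round(rad_to_deg(theta_star), 1))
  }
  1000 * theta_star / rpm_to_rad_per_s(RS)
}

#' Sampled pressure-angle / pressure-time profile
#'
#' Samples the Johanson profile on an even angle grid over `[0, theta_max]`
#' and maps angles to pre-gap times via the angular velocity at the given roll
#' speed. The profile starts at Pmax (theta = 0, t = 0) and is non-increasing
#' in theta.
#'
#' @inheritParams dwell_time
#' @param Pmax maximum pressure at the gap (MPa, > 0)
#' @param n_points number of samples (>= 2)
#' @param theta_max largest sampled angle (rad, default 0.2)
#' @return data frame of class `pressure_profile` with columns `theta_rad`,
#'   `time_s`, `pressure_MPa`, plus attributes `RS`, `Pmax`, `K`
#' @export
pressure_time_profile <- function(RS, Pmax, geometry, K, n_points = 500,
                                  theta_max = 0.2) {
  assert_positive(RS, "RS"); assert_scalar(RS)
  assert_positive(Pmax, "Pmax"); assert_scalar(Pmax)
  if (n_points < 2) stop("`n_points` must be at least 2", call. = FALSE)
  theta <- seq(0, theta_max, length.out = n_points)
  pressure <- pressure_at_angle(theta, Pmax, geometry, K)
  profile <- data.frame(
    theta_rad = theta,
    time_s = theta / rpm_to_rad_per_s(RS),
    pressure_MPa = pressure
  )
  structure(profile, class = c("pressure_profile", "data.frame"),
            RS = RS, Pmax = Pmax, K = K)
}

#' Peripheral roll speed
#'
#' Linear speed of the roll surface, `pi * D * RS / 60`, in m/s.
#'
#' @param RS roll speed (rpm, > 0); vectorized
#' @param D roll diameter (mm, > 0)
#' @return peripheral speed in m/s
#' @examples
#' round(peripheral_speed(c(2, 3), D = 250), 3)  # 0.026 0.039
#' @export
peripheral_speed <- function(RS, D) {
  assert_positive(RS, "RS")
  assert_positive(D, "D")
  pi * mm_to_m(D) * RS / 60
}

#' Midoux number
#'
#' Dimensionless ratio of the maximum roll pressure to the nip-state pressure,
#' `Mi = Pmax / P_alpha`. Holding Mi constant across equipment implies a
#' constant predicted at-gap solid fraction, which makes Mi a scale-up
#' invariant.
#'
#' @param Pmax maximum pressure (MPa, >= P_alpha); vectorized
#' @param P_alpha pressure at the nip angle (MPa, > 0)
#' @return Midoux number (dimensionless)
#' @export
midoux_number <- function(Pmax, P_alpha) {
  assert_positive(Pmax, "Pmax")
  assert_positive(P_alpha, "P_alpha")
  if (any(Pmax < P_alpha)) {
    stop("`Pmax` must not be below `P_alpha`: the nip pressure cannot exceed the gap pressure",
         call. = FALSE)
  }
  Pmax / P_alpha
}

#' Predicted at-gap solid fraction from the Midoux number
#'
#' Uniaxial power-law densification from the nip state:
#' `rho_Mi = rho_alpha * Mi^(1/K)` and `SF_Mi = rho_Mi / rho0`. Predictions
#' above 1 are physically impossible and reported with a warning, not an
#' error, so that the surrounding analysis can flag them.
#'
#' @param Mi Midoux number (>= 1); vectorized
#' @param K compressibility index (> 1)
#' @param rho_alpha powder density at the nip angle (g/cm3, in (0, rho0))
#' @param rho0 particle density (g/cm3, > 0)
#' @return predicted at-gap solid fraction (dimensionless)
#' @export
predict_sf_gap <- function(Mi, K, rho_alpha, rho0) {
  if (any(Mi < 1)) stop("`Mi` must be at least 1", call. = FALSE)
  assert_positive(K); assert_scalar(K)
  if (K <= 1) stop("`K` must exceed 1", call. = FALSE)
  assert_positive(rho_alpha); assert_positive(rho0)
  if (rho_alpha >= rho0) {
    stop("`rho_alpha` must be below `rho0`", call. = FALSE)
  }
  sf <- rho_alpha * Mi^(1 / K) / rho0
  if (any(sf > 1)) {
    warning(sprintf("%d predicted solid fraction(s) exceed 1 (physically impossible)",
                    sum(sf > 1)), call. = FALSE)
  }
  sf
}
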