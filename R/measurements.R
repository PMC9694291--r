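#' Ribbon volume produced during a collection interval
#'
#' Volume of ribbon that passed the gap during `duration` seconds at roll
#' speed `RS`: the gap cross-section `S x W` times the arc length travelled at
#' the effective diameter `(D + S)`, i.e. `V = S * W * pi * (D + S) * n_rev`
#' with `n_rev = RS * duration / 60` revolutions.
#'
#' @param geometry a [roll_geometry()]
#' @param RS roll speed during collection (rpm, > 0); vectorized
#' @param duration collection time (s, > 0)
#' @return ribbon volume in cm3
#' @examples
#' geom <- roll_geometry(250, 25, 2)
#' ribbon_volume_at_gap(geom, RS = 1, duration = 60)  # about 39.6 cm3
#' @export
ribbon_volume_at_gap <- function(geometry, RS, duration) {
  stopifnot(inherits(geometry, "roll_geometry"))
  assert_positive(RS, "RS")
  assert_positive(duration, "duration")
  n_rev <- rpm_to_rev_per_s(RS) * duration
  v_mm3 <- geometry$S * geometry$W * pi * (geometry$D + geometry$S) * n_rev
  v_mm3 / 1000
}

#' Measured at-gap solid fraction
#'
#' `SFgap = (m / V) / rho0` with the ribbon volume from
#' [ribbon_volume_at_gap()]. Values outside (0, 1] can arise from measurement
#' noise; they are flagged with a warning and returned.
#'
#' @param mass collected ribbon mass (g, > 0); vectorized
#' @param duration collection time (s, > 0)
#' @param RS roll speed during collection (rpm, > 0)
#' @param geometry a [roll_geometry()]
#' @param rho0 particle density (g/cm3, > 0)
#' @return at-gap solid fraction (dimensionless)
#' @export
sf_gap <- function(mass, duration, RS, geometry, rho0) {
  assert_positive(mass, "mass")
  assert_positive(rho0)
  v <- ribbon_volume_at_gap(geometry, RS, duration)
  sf <- (mass / v) / rho0
  if (any(sf > 1)) {
    warning(sprintf("%d at-gap solid fraction(s) exceed 1 (physically suspect)",
                    sum(sf > 1)), call. = FALSE)
  }
  sf
}

#' Prediction accuracy of the Midoux solid-fraction prediction
#'
#' Measured over predicted at-gap solid fraction, `PA = SFgap / SFMi`. A value
#' of 1 means the Midoux number predicted the at-gap densification exactly;
#' values below 1 indicate over-prediction (e.g. when the actual maximum
#' pressure falls short of the calculated one at high roll speed).
#'
#' @param SFgap measured at-gap solid fraction (> 0); vectorized
#' @param SFMi predicted at-gap solid fraction (> 0)
#' @return prediction accuracy (dimensionless)
#' @export
prediction_accuracy <- function(SFgap, SFMi) {
  assert_positive(SFgap, "SFgap")
  assert_positive(SFMi, "SFMi")
  SFgap / SFMi
}

#' Ribbon solid fraction from pycnometric density
#'
#' `SFribbon = rho_ribbon / rho0`; the off-roll solid fraction after elastic
#' recovery. Values above 1 are flagged with a warning.
#'
#' @param rho_ribbon ribbon envelope density (g/cm3, > 0); vectorized
#' @param rho0 particle density (g/cm3, > 0)
#' @return ribbon solid fraction (dimensionless)
#' @export
sf_ribbon <- function(rho_ribbon, rho0) {
  assert_positive(rho_ribbon, "rho_ribbon")
  assert_positive(rho0)
  sf <- rho_ribbon / rho0
  if (any(sf > 1)) {
    warning(sprintf("%d ribbon solid fraction(s) exceed 1 (physically suspect)",
                    sum(sf > 1)), call. = FALSE)
  }
  sf
}

#' Dwell-time sensitivity coefficient of the ribbon solid fraction
#'
#' Ratio of the ribbon solid fraction at the shortest dwell time (fastest
#' roll) to that at the longest dwell time (slowest roll) within one Pmax
#' series. A coefficient of 1 means no dwell-time effect; values below 1
#' quantify the loss of densification at short dwell times.
#'
#' @param SF_lowest_DT ribbon solid fraction at the shortest dwell time
#'   (in (0, 1]); vectorized
#' @param SF_highest_DT ribbon solid fraction at the longest dwell time
#'   (in (0, 1])
#' @return solid-fraction coefficient (dimensionless)
#' @export
sf_coefficient <- function(SF_lowest_DT, SF_highest_DT) {
  assert_positive(SF_lowest_DT, "SF_lowest_DT")
  assert_positive(SF_highest_DT, "SF_highest_DT")
  SF_lowest_DT / SF_highest_DT
}

# Average per-fragment replicate dimension lists (triplicate width/thickness
# measurements per ribbon fragment) down to one value per record.
average_dims <- function(x, name) {
  if (is.list(x)) {
    x <- vapply(x, function(v) {
      assert_positive(v, name)
      mean(v)
    }, numeric(1))
  }
  assert_positive(x, name)
  x
}

#' Ribbon tensile strength from a three-point beam fracture test
#'
#' `TS = 3 F span / (2 w h^2)`; with force in N and dimensions in mm the
#' result is in N/mm2, identical to MPa. `w` and `h` may be lists of replicate
#' measurements per fragment (e.g. triplicates at different positions), which
#' are averaged before use.
#'
#' @param F force at tensile failure (N, > 0); vectorized
#' @param span span of loading between the support beams (mm, > 0)
#' @param w ribbon fragment width (mm, > 0), numeric or list of replicate
#'   vectors
#' @param h ribbon fragment thickness (mm, > 0, < span), numeric or list of
#'   replicate vectors
#' @return tensile strength in MPa
#' @examples
#' ts_ribbon(F = 10, span = 42, w = 25, h = 2)  # 6.3 MPa
#' @export
ts_ribbon <- function(F, span, w, h) {
  assert_positive(F, "F")
  assert_positive(span, "span")
  w <- average_dims(w, "w")
  h <- average_dims(h, "h")
  if (any(span <= h)) {
    stop("`span` must exceed the ribbon thickness `h` (beam geometry)",
         call. = FALSE)
  }
  3 * F * span / (2 * w * h^2)
}

#' Tablet tensile strength from a diametral compression test
#'
#' `TS = 2 F / (pi d h)` with force in N and dimensions in mm, giving MPa.
#'
#' @param F fracture force (N, > 0); vectorized
#' @param d tablet diameter (mm, > 0)
#' @param h tablet thickness (mm, > 0)
#' @return tensile strength in MPa
#' @examples
#' ts_tablet(F = 100, d = 11.28, h = 3)  # about 1.881 MPa
#' @export
ts_tablet <- function(F, d, h) {
  assert_positive(F, "F")
  assert_positive(d, "d")
  assert_positive(h, "h")
  2 * F / (pi * d * h)
}

#' Replicate summary: mean, sample standard deviation, n
#'
#' The study convention for replicate reporting (arithmetic mean, sample SD
#' with n - 1 denominator, typically n = 3).
#'
#' @param x numeric replicate values
#' @return named list with `mean`, `sd`, `n`
#' @export
summarise_replicates <- function(x) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop("`x` must be numeric and non-missing", call. = FALSE)
  }
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
       n = length(x))
}
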