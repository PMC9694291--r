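#' Material compression descriptors
#'
#' A `material_model` bundles the descriptors the roll model needs: the
#' particle density `rho0`, the compressibility index `K` (exponent of the
#' power law rho ~ P^(1/K)), the Heckel constant and its reciprocal, the yield
#' pressure, and optionally the nip-state reference pressure `P_alpha` and
#' density `rho_alpha` required by the Midoux scale-up number.
#'
#' `yield_pressure` and `heckel_constant` are exact reciprocals; supply either
#' one. `P_alpha` and `rho_alpha` have no defaults: they are not tabulated for
#' the study materials and must come from the user (or from a synthetic truth).
#'
#' @param name material label, e.g. `"MCC"`
#' @param rho0 particle density (g/cm3, > 0)
#' @param K compressibility index (dimensionless, > 1)
#' @param heckel_constant slope of the Heckel regression (1/MPa, > 0)
#' @param yield_pressure reciprocal of the Heckel constant (MPa, > 0)
#' @param P_alpha pressure at the nip angle (MPa, > 0), optional
#' @param rho_alpha powder density at the nip angle (g/cm3, in (0, rho0)),
#'   optional
#' @return an object of class `material_model`
#' @examples
#' mcc <- material_model("MCC", rho0 = 1.54, K = 3.84, yield_pressure = 65)
#' mcc$heckel_constant * mcc$yield_pressure  # exactly 1
#' @export
material_model <- function(name, rho0, K = NULL, heckel_constant = NULL,
                           yield_pressure = NULL, P_alpha = NULL,
                           rho_alpha = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  assert_positive(rho0); assert_scalar(rho0)
  if (!is.null(K)) {
    assert_positive(K); assert_scalar(K)
    if (K <= 1) stop("`K` must exceed 1", call. = FALSE)
  }
  if (is.null(heckel_constant) && !is.null(yield_pressure)) {
    assert_positive(yield_pressure)
    heckel_constant <- 1 / yield_pressure
  } else if (!is.null(heckel_constant)) {
    assert_positive(heckel_constant)
    if (!is.null(yield_pressure) &&
        abs(yield_pressure * heckel_constant - 1) > 1e-12) {
      stop("`yield_pressure` must be the exact reciprocal of `heckel_constant`",
           call. = FALSE)
    }
    yield_pressure <- 1 / heckel_constant
  }
  if (!is.null(P_alpha)) assert_positive(P_alpha)
  if (!is.null(rho_alpha)) {
    assert_positive(rho_alpha)
    if (rho_alpha >= rho0) {
      stop("`rho_alpha` must be below the particle density `rho0`", call. = FALSE)
    }
  }
  structure(
    list(name = name, rho0 = rho0, K = K,
         heckel_constant = heckel_constant, yield_pressure = yield_pressure,
         P_alpha = P_alpha, rho_alpha = rho_alpha),
    class = "material_model"
  )
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("<material_model> %s\n", x$name))
  cat(sprintf("  rho0: %.4g g/cm3\n", x$rho0))
  if (!is.null(x$K)) cat(sprintf("  K: %.4g\n", x$K))
  if (!is.null(x$yield_pressure))
    cat(sprintf("  yield pressure: %.4g MPa (Heckel constant %.4g 1/MPa)\n",
                x$yield_pressure, x$heckel_constant))
  if (!is.null(x$P_alpha))
    cat(sprintf("  nip state: P_alpha = %.4g MPa, rho_alpha = %.4g g/cm3\n",
                x$P_alpha, x$rho_alpha))
  invisible(x)
}

#' In-die tablet volume
#'
#' Cylinder volume from the corrected tablet thickness at maximum force and the
#' tablet radius.
#'
#' @param thickness tablet thickness at maximum force (mm, > 0)
#' @param radius tablet radius (mm, > 0)
#' @return volume in mm3
#' @examples
#' in_die_volume(thickness = 3, radius = 5.64)
#' @export
in_die_volume <- function(thickness, radius) {
  assert_positive(thickness)
  assert_positive(radius)
  pi * radius^2 * thickness
}

#' In-die tablet density
#'
#' Mass over in-die volume; with mass in mg and volume in mm3 the result is
#' numerically identical to g/cm3.
#'
#' @param mass tablet mass (mg, > 0)
#' @param volume in-die volume (mm3, > 0)
#' @return density in g/cm3
#' @export
in_die_density <- function(mass, volume) {
  assert_positive(mass)
  assert_positive(volume)
  mass / volume
}

#' In-die porosity
#'
#' `1 - density / rho0`. Values at or below zero (in-die density at or above
#' the particle density) are physically degenerate for log-based fits; they are
#' returned as-is and excluded, with a warning, by [fit_heckel()].
#'
#' @param density in-die density (g/cm3, > 0)
#' @param rho0 particle density (g/cm3, > 0)
#' @return porosity (dimensionless)
#' @export
in_die_porosity <- function(density, rho0) {
  assert_positive(density)
  assert_positive(rho0)
  1 - density / rho0
}

#' Validate a table of in-die compression records
#'
#' Checks column presence, strict positivity, and (when a material is given)
#' that no derived in-die density exceeds the particle density by more than a
#' physical tolerance factor.
#'
#' @param records data frame with columns `pressure` (MPa), `mass` (mg),
#'   `thickness` (mm), `radius` (mm)
#' @param material optional [material_model()] used for the density bound
#' @param tol_factor physical tolerance factor on density/rho0 (default
#'   `1 + 1e-6`)
#' @return the validated records, invisibly, with a `density` column added
#' @export
validate_compression_records <- function(records, material = NULL,
                                         tol_factor = 1 + 1e-6) {
  needed <- c("pressure", "mass", "thickness", "radius")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) assert_positive(records[[col]], name = col)
  records$density <- in_die_density(records$mass,
                                    in_die_volume(records$thickness,
                                                  records$radius))
  if (!is.null(material)) {
    over <- records$density > material$rho0 * tol_factor
    if (any(over)) {
      stop(sprintf(
        "%d record(s) imply in-die density above the particle density of %s (tolerance factor %.8g)",
        sum(over), material$name, tol_factor), call. = FALSE)
    }
  }
  invisible(records)
}

derived_densities <- function(records, rho0) {
  records <- validate_compression_records(records)
  records$density
}

# Coefficient of determination without summary.lm (which warns on exact fits).
r_squared <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

#' Fit the compressibility index K
#'
#' Ordinary least-squares regression of `ln(in-die density)` on
#' `ln(pressure)`. The power law rho ~ P^(1/K) makes the fitted ln-ln slope
#' equal to `1/K`, so `K` is returned as the reciprocal of the slope: a slope
#' near 0.26 corresponds to K near 3.84.
#'
#' @param records data frame of in-die compression records (see
#'   [validate_compression_records()])
#' @param rho0 particle density (g/cm3); carried for the fit report
#' @return list with `K`, `slope`, `intercept`, `r_squared`, `n_used`
#' @examples
#' recs <- data.frame(pressure = c(100, 200), mass = 300, radius = 5.64,
#'                    thickness = 300 / (c(1, 2^(1/4)) * pi * 5.64^2))
#' fit_compressibility_index(recs, rho0 = 1.54)$K  # 4
#' @export
fit_compressibility_index <- function(records, rho0) {
  assert_positive(rho0)
  density <- derived_densities(records, rho0)
  pressure <- records$pressure
  if (length(unique(pressure)) < 2L) {
    stop("need at least 2 records with distinct pressures to fit K", call. = FALSE)
  }
  fit <- stats::lm(log(density) ~ log(pressure))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-densifying data: ln-ln slope is not positive", call. = FALSE)
  }
  list(
    K = 1 / slope,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r_squared(fit, log(density)),
    n_used = length(pressure)
  )
}

#' Fit the Heckel constant and yield pressure
#'
#' Ordinary least-squares regression of `-ln(in-die porosity)` on pressure.
#' The Heckel constant is the slope; the yield pressure is its exact
#' reciprocal. Records whose in-die density reaches or exceeds the particle
#' density (porosity <= 0) cannot enter the log and are excluded with a
#' warning.
#'
#' @inheritParams fit_compressibility_index
#' @param pressure_range optional length-2 numeric; keep only records with
#'   pressure inside `[min, max]` before fitting
#' @return list with `heckel_constant`, `yield_pressure`, `intercept`,
#'   `r_squared`, `n_used`, `n_excluded`
#' @export
fit_heckel <- function(records, rho0, pressure_range = NULL) {
  assert_positive(rho0)
  density <- derived_densities(records, rho0)
  pressure <- records$pressure
  if (!is.null(pressure_range)) {
    stopifnot(length(pressure_range) == 2L)
    keep <- pressure >= min(pressure_range) & pressure <= max(pressure_range)
    pressure <- pressure[keep]
    density <- density[keep]
  }
  porosity <- in_die_porosity(density, rho0)
  fittable <- porosity > 0 & porosity < 1
  n_excluded <- sum(!fittable)
  if (n_excluded > 0) {
    warning(sprintf(
      "%d record(s) with porosity outside (0, 1) excluded from the Heckel fit",
      n_excluded), call. = FALSE)
  }
  pressure <- pressure[fittable]
  porosity <- porosity[fittable]
  if (length(unique(pressure)) < 2L) {
    stop("need at least 2 fittable records with distinct pressures for the Heckel fit",
         call. = FALSE)
  }
  fit <- stats::lm(I(-log(porosity)) ~ pressure)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-densifying data: Heckel slope is not positive", call. = FALSE)
  }
  list(
    heckel_constant = slope,
    yield_pressure = 1 / slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r_squared(fit, -log(porosity)),
    n_used = length(pressure),
    n_excluded = n_excluded
  )
}

#' Fit both material descriptors and report them
#'
#' Convenience wrapper running [fit_compressibility_index()] and
#' [fit_heckel()] on one record table.
#'
#' @inheritParams fit_compressibility_index
#' @param name material label for the report
#' @return list with `name`, `rho0`, `K`, `heckel_constant`, `yield_pressure`,
#'   `r_squared_K`, `r_squared_heckel`, `n_used`, `n_excluded`
#' @export
fit_material <- function(records, rho0, name = "material") {
  k_fit <- fit_compressibility_index(records, rho0)
  h_fit <- fit_heckel(records, rho0)
  list(
    name = name, rho0 = rho0,
    K = k_fit$K,
    heckel_constant = h_fit$heckel_constant,
    yield_pressure = h_fit$yield_pressure,
    r_squared_K = k_fit$r_squared,
    r_squared_heckel = h_fit$r_squared,
    n_used = h_fit$n_used,
    n_excluded = h_fit$n_excluded
  )
}
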