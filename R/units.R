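# Centralized, exact unit conversions. External interfaces use
# pharma-conventional units: MPa, mg, mm, g/cm3, kN/cm, rpm.

#' Unit conversion helpers
#'
#' Exact conversions between the external (pharma-conventional) units used at
#' the package interfaces and the SI units used internally by the roll model.
#'
#' @param scf specific compaction force in kN/cm
#' @param x length in mm
#' @param pa pressure in Pa
#' @param rs roll speed in rpm
#' @return converted numeric value(s)
#' @name units
#' @keywords internal
NULL

#' @rdname units
kn_per_cm_to_n_per_m <- function(scf) scf * 1e5

#' @rdname units
mm_to_m <- function(x) x / 1000

#' @rdname units
pa_to_mpa <- function(pa) pa / 1e6

#' @rdname units
rpm_to_rad_per_s <- function(rs) 2 * pi * rs / 60

#' @rdname units
rpm_to_rev_per_s <- function(rs) rs / 60

#' @rdname units
#' @param deg angle in degrees
deg_to_rad <- function(deg) deg * pi / 180

#' @rdname units
#' @param rad angle in radians
rad_to_deg <- function(rad) rad * 180 / pi

# Scalar/vector positivity guard that names the offending argument.
assert_positive <- function(x, name = deparse(substitute(x)), strict = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop(sprintf("`%s` must be numeric and non-missing", name), call. = FALSE)
  }
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (bad) {
    stop(sprintf("`%s` must be %s (got %s)", name,
                 if (strict) "strictly positive" else "non-negative",
                 paste(format(x[if (strict) x <= 0 else x < 0][1]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

assert_scalar <- function(x, name = deparse(substitute(x))) {
  if (length(x) != 1L) stop(sprintf("`%s` must be a single value", name), call. = FALSE)
  invisible(x)
}
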