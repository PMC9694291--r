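# Delimited-text readers/writers for the study's table dialects. All files are
# plain CSV with fixed headers; readers validate the header and positivity.

read_table_checked <- function(path, expected, positive_cols = expected) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in positive_cols) assert_positive(df[[col]], name = col)
  df
}

#' Read and write in-die compression tables
#'
#' CSV dialect with header `pressure_MPa,mass_mg,thickness_mm,radius_mm`.
#' The reader returns a record table with the internal column names
#' `pressure`, `mass`, `thickness`, `radius` used by the fitting functions.
#'
#' @param path file path
#' @param records data frame of in-die compression records
#' @return `read_compression_table()` returns a data frame of records;
#'   `write_compression_table()` returns `path` invisibly
#' @export
read_compression_table <- function(path) {
  cols <- c("pressure_MPa", "mass_mg", "thickness_mm", "radius_mm")
  df <- read_table_checked(path, cols)
  out <- data.frame(pressure = df$pressure_MPa, mass = df$mass_mg,
                    thickness = df$thickness_mm, radius = df$radius_mm)
  validate_compression_records(out)
  out
}

#' @rdname read_compression_table
#' @export
write_compression_table <- function(records, path) {
  validate_compression_records(records)
  out <- data.frame(pressure_MPa = records$pressure, mass_mg = records$mass,
                    thickness_mm = records$thickness, radius_mm = records$radius)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read ribbon-collection, pycnometry and fracture-test tables
#'
#' CSV dialects:
#' * `ribbon_runs.csv`: `mass_g,duration_s,rs_rpm,scf_kN_cm`
#' * `pycnometry.csv`: `rho_ribbon_g_cm3,scf_kN_cm,rs_rpm`
#' * `bend_tests.csv`: `force_N,span_mm,width_mm,thickness_mm,scf_kN_cm,rs_rpm`
#' * `tablet_tests.csv`: `force_N,diameter_mm,thickness_mm,scf_kN_cm,rs_rpm`
#'
#' @param path file path
#' @return data frame with the dialect's columns
#' @name study_tables
NULL

#' @rdname study_tables
#' @export
read_ribbon_runs <- function(path) {
  read_table_checked(path, c("mass_g", "duration_s", "rs_rpm", "scf_kN_cm"))
}

#' @rdname study_tables
#' @export
read_pycnometry <- function(path) {
  read_table_checked(path, c("rho_ribbon_g_cm3", "scf_kN_cm", "rs_rpm"))
}

#' @rdname study_tables
#' @export
read_bend_tests <- function(path) {
  read_table_checked(path, c("force_N", "span_mm", "width_mm", "thickness_mm",
                             "scf_kN_cm", "rs_rpm"))
}

#' @rdname study_tables
#' @export
read_tablet_tests <- function(path) {
  read_table_checked(path, c("force_N", "diameter_mm", "thickness_mm",
                             "scf_kN_cm", "rs_rpm"))
}

#' Write a material fit report as JSON
#'
#' Serializes the output of [fit_material()] (K, Heckel constant, yield
#' pressure, R-squared values, record counts) to a JSON file.
#'
#' @param fit a fit report from [fit_material()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(fit, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
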