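#' Study configuration
#'
#' Everything the study runner needs: the materials (with their
#' compressibility indices and, when prediction accuracy is to be computed,
#' the nip-state reference pressure and density), the roll geometry, the
#' process grids and the dwell-time conventions.
#'
#' @param materials named list of [material_model()] objects
#' @param geometry a [roll_geometry()]
#' @param scf_grid specific compaction forces (kN/cm): either one numeric
#'   vector used for every material or a named list keyed by material name
#' @param rs_grid roll speeds (rpm), non-empty
#' @param dwell_fraction pressure fraction defining the dwell time (default
#'   0.9)
#' @param round_theta apply the 0.1-degree threshold-angle rounding convention
#'   in the dwell-time table (default `FALSE`)
#' @param paths optional named list of input/output locations
#' @return an object of class `study_config`
#' @export
study_config <- function(materials, geometry, scf_grid, rs_grid,
                         dwell_fraction = 0.9, round_theta = FALSE,
                         paths = list()) {
  if (!is.list(materials) || length(materials) == 0L ||
      is.null(names(materials)) || any(names(materials) == "")) {
    stop("`materials` must be a non-empty named list of material models",
         call. = FALSE)
  }
  for (m in materials) stopifnot(inherits(m, "material_model"))
  stopifnot(inherits(geometry, "roll_geometry"))
  if (is.numeric(scf_grid)) {
    scf_grid <- stats::setNames(rep(list(scf_grid), length(materials)),
                                names(materials))
  }
  if (!all(names(materials) %in% names(scf_grid))) {
    stop("`scf_grid` must cover every material", call. = FALSE)
  }
  for (g in scf_grid) {
    if (length(g) == 0L) stop("`scf_grid` entries must be non-empty", call. = FALSE)
    assert_positive(g, "scf_grid")
  }
  if (length(rs_grid) == 0L) stop("`rs_grid` must be non-empty", call. = FALSE)
  assert_positive(rs_grid, "rs_grid")
  if (dwell_fraction <= 0 || dwell_fraction >= 1) {
    stop("`dwell_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(materials = materials, geometry = geometry, scf_grid = scf_grid,
         rs_grid = rs_grid, dwell_fraction = dwell_fraction,
         round_theta = isTRUE(round_theta), paths = paths),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#'
#' Expected layout: a `geometry` map (`D`, `W`, `S` in mm), a `materials` map
#' of `{rho0, K, yield_pressure?, P_alpha?, rho_alpha?, scf: [..]}` entries,
#' an `rs_grid` list (rpm), and optional `dwell_fraction` / `round_theta`
#' scalars.
#'
#' @param path YAML file path
#' @return a [study_config()]
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$geometry) || is.null(cfg$materials) || is.null(cfg$rs_grid)) {
    stop("config must define `geometry`, `materials` and `rs_grid`",
         call. = FALSE)
  }
  geometry <- roll_geometry(cfg$geometry$D, cfg$geometry$W, cfg$geometry$S)
  materials <- list()
  scf_grid <- list()
  for (name in names(cfg$materials)) {
    m <- cfg$materials[[name]]
    materials[[name]] <- material_model(
      name, rho0 = m$rho0, K = m$K,
      yield_pressure = m$yield_pressure,
      P_alpha = m$P_alpha, rho_alpha = m$rho_alpha
    )
    if (is.null(m$scf)) stop("material `", name, "` has no `scf` list",
                             call. = FALSE)
    scf_grid[[name]] <- unlist(m$scf)
  }
  study_config(materials, geometry, scf_grid, unlist(cfg$rs_grid),
               dwell_fraction = cfg$dwell_fraction %||% 0.9,
               round_theta = isTRUE(cfg$round_theta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Maximum-pressure table (one row per material x SCF), full precision plus the
# integer-MPa convention used in study tables.
pmax_table <- function(config) {
  rows <- lapply(names(config$materials), function(name) {
    mat <- config$materials[[name]]
    scf <- config$scf_grid[[name]]
    data.frame(material = name, scf_kN_cm = scf, K = mat$K,
               pmax_MPa = pmax_from_scf(scf, config$geometry, mat$K))
  })
  out <- do.call(rbind, rows)
  out$pmax_MPa_int <- as.integer(round(out$pmax_MPa))
  out
}

# Dwell-time table (RS rows, one column per material), in ms.
dt_table <- function(config) {
  out <- data.frame(rs_rpm = config$rs_grid)
  for (name in names(config$materials)) {
    mat <- config$materials[[name]]
    out[[name]] <- dwell_time(config$rs_grid, config$geometry, mat$K,
                              fraction = config$dwell_fraction,
                              round_theta = config$round_theta)
  }
  out
}

agg_cell <- function(df, value_col, by = c("scf_kN_cm", "rs_rpm")) {
  if (is.null(df) || nrow(df) == 0L) return(NULL)
  split_keys <- interaction(df[by], drop = TRUE)
  parts <- lapply(split(df, split_keys), function(chunk) {
    s <- summarise_replicates(chunk[[value_col]])
    cbind(chunk[1, by, drop = FALSE],
          data.frame(mean = s$mean, sd = s$sd, n = s$n))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$scf_kN_cm, out$rs_rpm), , drop = FALSE]
}

#' Reduce measurement tables for one material to per-condition summaries
#'
#' Computes, per (SCF, RS) cell, the measured at-gap solid fraction, the
#' Midoux-predicted solid fraction and prediction accuracy (when the material
#' carries `P_alpha` and `rho_alpha`), the ribbon solid fraction, and ribbon /
#' tablet tensile strengths — each as mean, sample SD and n over replicates.
#'
#' @param tables named list with any of `ribbon_runs`, `pycnometry`,
#'   `bend_tests`, `tablet_tests` (data frames in the dialects of
#'   [read_ribbon_runs()] and friends)
#' @param material a [material_model()]
#' @param geometry a [roll_geometry()]
#' @return named list of per-cell summary data frames (`sf_gap`, `pa`,
#'   `sf_ribbon`, `ts_ribbon`, `ts_tablet`; absent inputs yield `NULL`)
#' @export
summarise_study_cells <- function(tables, material, geometry) {
  stopifnot(inherits(material, "material_model"),
            inherits(geometry, "roll_geometry"))
  out <- list(sf_gap = NULL, pa = NULL, sf_ribbon = NULL,
              ts_ribbon = NULL, ts_tablet = NULL)
  rr <- tables$ribbon_runs
  if (!is.null(rr)) {
    rr$sf_gap <- sf_gap(rr$mass_g, rr$duration_s, rr$rs_rpm, geometry,
                        material$rho0)
    out$sf_gap <- agg_cell(rr, "sf_gap")
    if (!is.null(material$P_alpha) && !is.null(material$rho_alpha)) {
      pmax_cell <- pmax_from_scf(rr$scf_kN_cm, geometry, material$K)
      mi <- midoux_number(pmax_cell, material$P_alpha)
      rr$sf_mi <- predict_sf_gap(mi, material$K, material$rho_alpha,
                                 material$rho0)
      rr$pa <- prediction_accuracy(rr$sf_gap, rr$sf_mi)
      out$pa <- agg_cell(rr, "pa")
      sfmi <- unique(rr[c("scf_kN_cm", "sf_mi")])
      out$pa <- merge(out$pa, sfmi, by = "scf_kN_cm", sort = FALSE)
    }
  }
  pyc <- tables$pycnometry
  if (!is.null(pyc)) {
    pyc$sf_ribbon <- sf_ribbon(pyc$rho_ribbon_g_cm3, material$rho0)
    out$sf_ribbon <- agg_cell(pyc, "sf_ribbon")
  }
  bend <- tables$bend_tests
  if (!is.null(bend)) {
    bend$ts <- ts_ribbon(bend$force_N, bend$span_mm, bend$width_mm,
                         bend$thickness_mm)
    out$ts_ribbon <- agg_cell(bend, "ts")
  }
  tab <- tables$tablet_tests
  if (!is.null(tab)) {
    tab$ts <- ts_tablet(tab$force_N, tab$diameter_mm, tab$thickness_mm)
    out$ts_tablet <- agg_cell(tab, "ts")
  }
  out
}

#' Dwell-time sensitivity coefficients per maximum-pressure series
#'
#' For each SCF (equivalently each Pmax) series in a ribbon solid-fraction
#' summary, forms the ratio of the cell-mean solid fraction at the shortest
#' dwell time (fastest roll speed) to that at the longest dwell time (slowest
#' roll speed).
#'
#' @param sf_ribbon_cells per-cell summary from [summarise_study_cells()]
#'   (`scf_kN_cm`, `rs_rpm`, `mean`, ...)
#' @return data frame with `scf_kN_cm`, `rs_lowest_dt`, `rs_highest_dt`,
#'   `sf_coefficient`
#' @export
sf_coefficients_by_series <- function(sf_ribbon_cells) {
  parts <- lapply(split(sf_ribbon_cells, sf_ribbon_cells$scf_kN_cm),
                  function(series) {
    fast <- series[which.max(series$rs_rpm), ]  # shortest dwell time
    slow <- series[which.min(series$rs_rpm), ]  # longest dwell time
    data.frame(scf_kN_cm = fast$scf_kN_cm,
               rs_lowest_dt = fast$rs_rpm, rs_highest_dt = slow$rs_rpm,
               sf_coefficient = sf_coefficient(fast$mean, slow$mean))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Prediction-accuracy summary per roll speed
#'
#' Aggregates prediction accuracy over maximum-pressure levels at fixed roll
#' speed, either by first averaging replicates within each cell and then
#' averaging the cell means over levels (`"levels"`), or by pooling all
#' replicates at a roll speed (`"pooled"`). The method used is recorded in the
#' output.
#'
#' @param pa_cells per-cell `pa` summary from [summarise_study_cells()]
#' @param raw optional raw per-replicate data frame with `rs_rpm` and `pa`
#'   columns, required for `method = "pooled"`
#' @param method `"levels"` (default) or `"pooled"`
#' @return data frame with `rs_rpm`, `pa_mean`, `pa_sd`, `n`, `method`
#' @export
pa_summary <- function(pa_cells, raw = NULL, method = c("levels", "pooled")) {
  method <- match.arg(method)
  if (method == "levels") {
    parts <- lapply(split(pa_cells, pa_cells$rs_rpm), function(chunk) {
      s <- summarise_replicates(chunk$mean)
      data.frame(rs_rpm = chunk$rs_rpm[1], pa_mean = s$mean, pa_sd = s$sd,
                 n = s$n, method = "levels")
    })
  } else {
    if (is.null(raw)) stop('method "pooled" needs the raw per-replicate data',
                           call. = FALSE)
    parts <- lapply(split(raw, raw$rs_rpm), function(chunk) {
      s <- summarise_replicates(chunk$pa)
      data.frame(rs_rpm = chunk$rs_rpm[1], pa_mean = s$mean, pa_sd = s$sd,
                 n = s$n, method = "pooled")
    })
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$rs_rpm), , drop = FALSE]
}

#' Run a full study
#'
#' Chains every stage: the maximum-pressure table per material, the dwell-time
#' table, and — when measurement tables are supplied — per-condition solid
#' fraction, prediction accuracy and tensile-strength summaries plus
#' dwell-time sensitivity coefficients. A machine-readable run log records
#' versions, the configuration hash and record counts.
#'
#' @param config a [study_config()]
#' @param measurements optional named list keyed by material name; each entry
#'   a list of measurement tables as in [summarise_study_cells()]
#' @return an object of class `study_report`: list with `pmax_table`,
#'   `dt_table`, `cells` (per material), `sf_coefficients`, `pa_by_rs`, `log`
#' @export
run_study <- function(config, measurements = NULL) {
  stopifnot(inherits(config, "study_config"))
  report <- list(
    pmax_table = pmax_table(config),
    dt_table = dt_table(config),
    cells = NULL, sf_coefficients = NULL, pa_by_rs = NULL
  )
  counts <- list()
  if (!is.null(measurements)) {
    unknown <- setdiff(names(measurements), names(config$materials))
    if (length(unknown)) {
      stop("measurements supplied for unknown material(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cells <- list(); coefs <- list(); pa_rs <- list()
    for (name in names(measurements)) {
      mat <- config$materials[[name]]
      tabs <- measurements[[name]]
      cells[[name]] <- summarise_study_cells(tabs, mat, config$geometry)
      counts[[name]] <- vapply(tabs, function(t) if (is.null(t)) 0L else nrow(t),
                               integer(1))
      if (!is.null(cells[[name]]$sf_ribbon)) {
        co <- sf_coefficients_by_series(cells[[name]]$sf_ribbon)
        co$material <- name
        coefs[[name]] <- co
      }
      if (!is.null(cells[[name]]$pa)) {
        ps <- pa_summary(cells[[name]]$pa)
        ps$material <- name
        pa_rs[[name]] <- ps
      }
    }
    report$cells <- cells
    if (length(coefs)) report$sf_coefficients <- do.call(rbind, coefs)
    if (length(pa_rs)) report$pa_by_rs <- do.call(rbind, pa_rs)
  }
  report$log <- list(
    package_version = as.character(utils::packageVersion("rollcompact")),
    r_version = R.version.string,
    config_hash = config_hash(config),
    dwell_fraction = config$dwell_fraction,
    round_theta = config$round_theta,
    record_counts = counts
  )
  structure(report, class = "study_report")
}

# md5 of the serialized configuration (stable across identical configs).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 3)
  unname(tools::md5sum(tmp))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  materials: %s\n",
              paste(unique(x$pmax_table$material), collapse = ", ")))
  cat(sprintf("  Pmax rows: %d, dwell-time rows: %d\n",
              nrow(x$pmax_table), nrow(x$dt_table)))
  if (!is.null(x$cells)) {
    cat(sprintf("  measurement summaries for: %s\n",
                paste(names(x$cells), collapse = ", ")))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits delimited-text tables (fixed column order mirroring the
#' maximum-pressure and dwell-time study tables) plus JSON mirrors and the run
#' log.
#'
#' @param report a `study_report` from [run_study()]
#' @param dir output directory (created if absent)
#' @return the directory, invisibly
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$pmax_table, file.path(dir, "pmax_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$dt_table, file.path(dir, "dt_table.csv"),
                   row.names = FALSE)
  if (!is.null(report$sf_coefficients)) {
    utils::write.csv(report$sf_coefficients,
                     file.path(dir, "sf_coefficients.csv"), row.names = FALSE)
  }
  if (!is.null(report$pa_by_rs)) {
    utils::write.csv(report$pa_by_rs, file.path(dir, "pa_by_rs.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$cells)) {
    for (name in names(report$cells)) {
      for (what in names(report$cells[[name]])) {
        tab <- report$cells[[name]][[what]]
        if (!is.null(tab)) {
          utils::write.csv(tab, file.path(dir, sprintf("%s_%s.csv", name, what)),
                           row.names = FALSE)
        }
      }
    }
  }
  jsonlite::write_json(
    list(pmax_table = report$pmax_table, dt_table = report$dt_table,
         sf_coefficients = report$sf_coefficients,
         pa_by_rs = report$pa_by_rs, log = report$log),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows", null = "null")
  invisible(dir)
}
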