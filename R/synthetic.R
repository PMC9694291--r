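# Seeded synthetic-data generator. Emulates the measurement chain the analysis
# assumes: power-law / Heckel in-die densification, the Midoux at-gap solid
# fraction (optionally with a dwell-time-dependent attenuation of the maximum
# pressure), elastic recovery from gap to relaxed ribbon, and multiplicative
# log-normal measurement noise on masses, densities and forces.

# Deterministic child seed for a labeled substream, kept inside 32-bit range.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647L) + 1L
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Multiplicative log-normal noise factors with coefficient of variation ~ cv.
noise_factor <- function(n, cv) {
  if (cv < 0) stop("`noise_cv` must be non-negative", call. = FALSE)
  if (cv == 0) rep(1, n) else exp(cv * stats::rnorm(n))
}

#' Specification for a synthetic ribbon study
#'
#' Bundles the generating truth (material, geometry, process grid) with the
#' noise and mechanism knobs of the generator:
#' * `noise_cv` — multiplicative log-normal coefficient of variation applied
#'   per measured quantity (default 0.01, a 1 percent CV);
#' * `elastic_recovery` — fractional solid-fraction loss from the gap to the
#'   relaxed ribbon (default 0.10);
#' * `attenuation` — optional function mapping dwell time (ms) to a maximum-
#'   pressure multiplier in (0, 1], emulating the hypothesis that faster rolls
#'   reach a lower actual maximum pressure;
#' * `attenuate_below_yield_only` — apply the attenuation only to process
#'   conditions whose nominal maximum pressure is below the material's yield
#'   pressure, where densification is dwell-time-sensitive (plastic
#'   deformation); above the yield pressure the attenuation is ignored.
#'
#' @param material a [material_model()] with `K`, `P_alpha`, `rho_alpha` set
#'   (and `yield_pressure`, when the attenuation is gated on it)
#' @param geometry a [roll_geometry()]
#' @param settings process grid from [compaction_settings()]
#' @param noise_cv measurement coefficient of variation (>= 0)
#' @param elastic_recovery fractional SF loss from gap to ribbon (in [0, 0.3))
#' @param attenuation `NULL` or `function(dt_ms)` returning a multiplier in
#'   (0, 1]
#' @param attenuate_below_yield_only logical; see above
#' @param seed integer root seed; all substreams derive from it
#' @param replicates records per process condition
#' @param collection_s ribbon collection time per run (s, default 60)
#' @return an object of class `generator_spec`
#' @export
generator_spec <- function(material, geometry, settings, noise_cv = 0.01,
                           elastic_recovery = 0.10, attenuation = NULL,
                           attenuate_below_yield_only = TRUE, seed = 1L,
                           replicates = 3L, collection_s = 60) {
  stopifnot(inherits(material, "material_model"),
            inherits(geometry, "roll_geometry"))
  if (is.null(material$K)) stop("material needs `K`", call. = FALSE)
  if (is.null(material$P_alpha) || is.null(material$rho_alpha)) {
    stop("material needs `P_alpha` and `rho_alpha` as generating truths",
         call. = FALSE)
  }
  if (!all(c("scf_kN_cm", "rs_rpm") %in% names(settings)) || nrow(settings) == 0L) {
    stop("`settings` must be a non-empty grid from compaction_settings()",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("`noise_cv` must be non-negative", call. = FALSE)
  if (elastic_recovery < 0 || elastic_recovery >= 0.3) {
    stop("`elastic_recovery` must lie in [0, 0.3)", call. = FALSE)
  }
  if (!is.null(attenuation)) {
    if (!is.function(attenuation)) {
      stop("`attenuation` must be NULL or a function of dwell time (ms)",
           call. = FALSE)
    }
    if (attenuate_below_yield_only && is.null(material$yield_pressure)) {
      stop("gating the attenuation on the yield pressure requires `yield_pressure` in the material",
           call. = FALSE)
    }
  }
  if (replicates < 1L) stop("`replicates` must be at least 1", call. = FALSE)
  assert_positive(collection_s)
  structure(
    list(material = material, geometry = geometry, settings = settings,
         noise_cv = noise_cv, elastic_recovery = elastic_recovery,
         attenuation = attenuation,
         attenuate_below_yield_only = attenuate_below_yield_only,
         seed = as.integer(seed), replicates = as.integer(replicates),
         collection_s = collection_s),
    class = "generator_spec"
  )
}

#' Synthetic in-die compression records
#'
#' Generates tableting records whose densities follow either the power law
#' `rho(P) = c P^(1/K)` (mode `"power_law"`, with `c` set so the solid
#' fraction at the highest pressure equals `sf_at_max`) or the Heckel law
#' `-ln(porosity) = a + P / yield_pressure` (mode `"heckel"`, intercept `a =
#' heckel_intercept`). The two laws are mutually inconsistent except locally,
#' so the mode must be chosen explicitly. Densities are multiplied by
#' log-normal noise `exp(noise_cv * z)`; thickness is back-solved from the
#' sampled density at fixed tablet mass and radius, so density(mass,
#' volume(thickness, radius)) round-trips the sampled value exactly.
#'
#' @param material a [material_model()]; `K` is required for `"power_law"`,
#'   `yield_pressure` for `"heckel"`
#' @param pressures tableting pressures (MPa); default five levels spanning
#'   25-250 MPa
#' @param mode `"power_law"` or `"heckel"`; no default
#' @param noise_cv multiplicative noise CV on density (>= 0)
#' @param seed integer seed
#' @param n records per pressure level (default 10 tablets per pressure)
#' @param mass_mg tablet mass (default 300 mg)
#' @param radius_mm tablet radius (default 5.64 mm, an 11.28 mm punch)
#' @param sf_at_max solid fraction reached at the highest pressure under the
#'   power law (default 0.95)
#' @param heckel_intercept intercept of the Heckel line (default 0.66)
#' @return data frame of in-die compression records (`pressure`, `mass`,
#'   `thickness`, `radius`)
#' @export
generate_compression_profiles <- function(material,
                                          pressures = seq(25, 250, length.out = 5),
                                          mode, noise_cv = 0, seed = 1L, n = 10L,
                                          mass_mg = 300, radius_mm = 5.64,
                                          sf_at_max = 0.95,
                                          heckel_intercept = 0.66) {
  stopifnot(inherits(material, "material_model"))
  if (missing(mode) || !mode %in% c("power_law", "heckel")) {
    stop('`mode` must be chosen explicitly: "power_law" or "heckel"',
         call. = FALSE)
  }
  assert_positive(pressures, "pressures")
  assert_positive(mass_mg); assert_positive(radius_mm)
  law <- switch(mode,
    power_law = {
      if (is.null(material$K)) stop("material needs `K` for power_law mode",
                                    call. = FALSE)
      c0 <- sf_at_max * material$rho0 / max(pressures)^(1 / material$K)
      function(P) c0 * P^(1 / material$K)
    },
    heckel = {
      if (is.null(material$yield_pressure)) {
        stop("material needs `yield_pressure` for heckel mode", call. = FALSE)
      }
      function(P) {
        porosity <- exp(-(heckel_intercept + P * material$heckel_constant))
        material$rho0 * (1 - porosity)
      }
    }
  )
  p_all <- rep(pressures, each = n)
  density <- with_seed(substream_seed(seed, "compression"), {
    law(p_all) * noise_factor(length(p_all), noise_cv)
  })
  thickness <- mass_mg / (density * pi * radius_mm^2)
  data.frame(pressure = p_all, mass = mass_mg, thickness = thickness,
             radius = radius_mm)
}

# Truth chain for one process condition: nominal Pmax, dwell time, attenuated
# Pmax, Midoux number and at-gap solid fraction.
cell_truth <- function(spec, scf, rs) {
  mat <- spec$material
  pmax_nom <- pmax_from_scf(scf, spec$geometry, mat$K)
  dt <- dwell_time(rs, spec$geometry, mat$K)
  mult <- 1
  if (!is.null(spec$attenuation)) {
    gated_out <- spec$attenuate_below_yield_only &&
      pmax_nom >= mat$yield_pressure
    if (!gated_out) {
      mult <- spec$attenuation(dt)
      if (!is.numeric(mult) || length(mult) != 1L || mult <= 0 || mult > 1) {
        stop("attenuation must return a single multiplier in (0, 1]",
             call. = FALSE)
      }
    }
  }
  pmax_eff <- mult * pmax_nom
  mi <- midoux_number(pmax_eff, mat$P_alpha)
  sfg <- predict_sf_gap(mi, mat$K, mat$rho_alpha, mat$rho0)
  list(pmax_nominal = pmax_nom, dt_ms = dt, attenuation = mult,
       pmax_effective = pmax_eff, mi = mi, sf_gap = sfg,
       sf_ribbon = sfg * (1 - spec$elastic_recovery))
}

#' Synthetic ribbon study
#'
#' For every process condition and replicate, chains the roll model (maximum
#' pressure, dwell time, optional dwell-time attenuation, Midoux at-gap solid
#' fraction, elastic recovery) and inverts the measurement reductions to
#' produce the raw records a study would collect: ribbon-collection masses and
#' pycnometric ribbon densities, both with multiplicative log-normal noise.
#'
#' @param spec a [generator_spec()]
#' @return list with `ribbon_runs` (columns `mass_g`, `duration_s`, `rs_rpm`,
#'   `scf_kN_cm`), `pycnometry` (`rho_ribbon_g_cm3`, `scf_kN_cm`, `rs_rpm`)
#'   and `truth` (per-condition nominal/effective Pmax, dwell time, at-gap and
#'   ribbon solid fractions)
#' @export
generate_ribbon_study <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  mat <- spec$material
  runs <- vector("list", nrow(spec$settings))
  pyc <- vector("list", nrow(spec$settings))
  truth <- vector("list", nrow(spec$settings))
  for (i in seq_len(nrow(spec$settings))) {
    scf <- spec$settings$scf_kN_cm[i]
    rs <- spec$settings$rs_rpm[i]
    tr <- cell_truth(spec, scf, rs)
    v <- ribbon_volume_at_gap(spec$geometry, rs, spec$collection_s)
    cell_label <- sprintf("cell_%g_%g", scf, rs)
    mass <- with_seed(substream_seed(spec$seed, paste0(cell_label, "_mass")), {
      tr$sf_gap * mat$rho0 * v * noise_factor(spec$replicates, spec$noise_cv)
    })
    rho_ribbon <- with_seed(substream_seed(spec$seed, paste0(cell_label, "_pyc")), {
      tr$sf_ribbon * mat$rho0 * noise_factor(spec$replicates, spec$noise_cv)
    })
    runs[[i]] <- data.frame(mass_g = mass, duration_s = spec$collection_s,
                            rs_rpm = rs, scf_kN_cm = scf)
    pyc[[i]] <- data.frame(rho_ribbon_g_cm3 = rho_ribbon, scf_kN_cm = scf,
                           rs_rpm = rs)
    truth[[i]] <- data.frame(scf_kN_cm = scf, rs_rpm = rs,
                             pmax_nominal_MPa = tr$pmax_nominal,
                             dt_ms = tr$dt_ms, attenuation = tr$attenuation,
                             pmax_effective_MPa = tr$pmax_effective,
                             mi = tr$mi, sf_gap = tr$sf_gap,
                             sf_ribbon = tr$sf_ribbon)
  }
  list(ribbon_runs = do.call(rbind, runs),
       pycnometry = do.call(rbind, pyc),
       truth = do.call(rbind, truth))
}

#' Synthetic fracture-test records
#'
#' Back-solves the failure force from a chosen true tensile strength through
#' the beam (three-point bend) or diametral formula, then applies
#' multiplicative log-normal noise to the force, so that the corresponding
#' reducer recovers `true_ts` up to noise.
#'
#' @param true_ts true tensile strength (MPa, > 0)
#' @param type `"bend"` (ribbon fragments) or `"diametral"` (tablets)
#' @param noise_cv multiplicative noise CV on the force (>= 0)
#' @param seed integer seed
#' @param n number of records
#' @param span_mm bend-test span of loading (default 42 mm)
#' @param width_mm ribbon fragment width (default 25 mm, the roll width)
#' @param thickness_mm ribbon or tablet thickness (default 2 mm bend, 3 mm
#'   diametral)
#' @param diameter_mm tablet diameter (default 11.28 mm)
#' @return data frame of test records; columns `force_N`, `span_mm`,
#'   `width_mm`, `thickness_mm` for `"bend"`, or `force_N`, `diameter_mm`,
#'   `thickness_mm` for `"diametral"`
#' @export
generate_fracture_tests <- function(true_ts, type = c("bend", "diametral"),
                                    noise_cv = 0, seed = 1L, n = 3L,
                                    span_mm = 42, width_mm = 25,
                                    thickness_mm = NULL, diameter_mm = 11.28) {
  type <- match.arg(type)
  assert_positive(true_ts, "true_ts"); assert_scalar(true_ts)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (is.null(thickness_mm)) thickness_mm <- if (type == "bend") 2 else 3
  noise <- with_seed(substream_seed(seed, paste0("fracture_", type)), {
    noise_factor(n, noise_cv)
  })
  if (type == "bend") {
    f0 <- true_ts * 2 * width_mm * thickness_mm^2 / (3 * span_mm)
    data.frame(force_N = f0 * noise, span_mm = span_mm, width_mm = width_mm,
               thickness_mm = thickness_mm)
  } else {
    f0 <- true_ts * pi * diameter_mm * thickness_mm / 2
    data.frame(force_N = f0 * noise, diameter_mm = diameter_mm,
               thickness_mm = thickness_mm)
  }
}

#' Write a complete synthetic study to disk
#'
#' Emits the CSV dialects consumed by the measurement readers
#' (`ribbon_runs.csv`, `pycnometry.csv`, `bend_tests.csv`,
#' `tablet_tests.csv`) plus `truth.json` holding every generating parameter
#' and the per-condition truth chain, for recovery tests.
#'
#' @param spec a [generator_spec()]
#' @param dir output directory (created if absent)
#' @param true_ts_ribbon true ribbon tensile strength for the bend tests (MPa)
#' @param true_ts_tablet true tablet tensile strength for the diametral tests
#'   (MPa)
#' @return the output directory, invisibly
#' @export
write_synthetic_study <- function(spec, dir, true_ts_ribbon = 1.0,
                                  true_ts_tablet = 2.0) {
  stopifnot(inherits(spec, "generator_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_ribbon_study(spec)
  utils::write.csv(study$ribbon_runs, file.path(dir, "ribbon_runs.csv"),
                   row.names = FALSE)
  utils::write.csv(study$pycnometry, file.path(dir, "pycnometry.csv"),
                   row.names = FALSE)
  frac <- lapply(seq_len(nrow(spec$settings)), function(i) {
    scf <- spec$settings$scf_kN_cm[i]; rs <- spec$settings$rs_rpm[i]
    b <- generate_fracture_tests(true_ts_ribbon, "bend",
                                 noise_cv = spec$noise_cv,
                                 seed = substream_seed(spec$seed,
                                                       sprintf("bend_%g_%g", scf, rs)),
                                 n = spec$replicates)
    d <- generate_fracture_tests(true_ts_tablet, "diametral",
                                 noise_cv = spec$noise_cv,
                                 seed = substream_seed(spec$seed,
                                                       sprintf("diam_%g_%g", scf, rs)),
                                 n = spec$replicates)
    b$scf_kN_cm <- scf; b$rs_rpm <- rs
    d$scf_kN_cm <- scf; d$rs_rpm <- rs
    list(bend = b, diametral = d)
  })
  utils::write.csv(do.call(rbind, lapply(frac, `[[`, "bend")),
                   file.path(dir, "bend_tests.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(frac, `[[`, "diametral")),
                   file.path(dir, "tablet_tests.csv"), row.names = FALSE)
  truth <- list(
    material = spec$material[c("name", "rho0", "K", "heckel_constant",
                               "yield_pressure", "P_alpha", "rho_alpha")],
    geometry = unclass(spec$geometry),
    noise_cv = spec$noise_cv,
    elastic_recovery = spec$elastic_recovery,
    attenuation_used = !is.null(spec$attenuation),
    attenuate_below_yield_only = spec$attenuate_below_yield_only,
    seed = spec$seed, replicates = spec$replicates,
    collection_s = spec$collection_s,
    true_ts_ribbon = true_ts_ribbon, true_ts_tablet = true_ts_tablet,
    cells = study$truth
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
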