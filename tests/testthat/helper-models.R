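# Shared fixtures: the study geometry and the two study materials with
# synthetic nip-state truths (the nip-state pressure and density are not
# tabulated for these materials; the values here are realistic choices used
# as generating truths).

study_geometry <- function() roll_geometry(D = 250, W = 25, S = 2.0)

mcc_model <- function() {
  material_model("MCC", rho0 = 1.56, K = 3.84, yield_pressure = 65,
                 P_alpha = 1, rho_alpha = 0.42)
}

lactose_model <- function() {
  material_model("lactose", rho0 = 1.54, K = 6.90, yield_pressure = 131,
                 P_alpha = 1, rho_alpha = 0.58)
}

mcc_scf <- function() c(2.9, 4.0, 5.8, 7.6)
lactose_scf <- function() c(3.5, 5.2, 7.0, 8.6, 10.3)
study_rs <- function() c(1.0, 1.2, 1.5, 2.0, 3.0, 6.0, 10.0)

# Exact two-point compression records at given pressures/densities
# (thickness back-solved at fixed mass and radius).
records_from_densities <- function(pressure, density, mass = 300, radius = 5.64) {
  data.frame(pressure = pressure, mass = mass,
             thickness = mass / (density * pi * radius^2), radius = radius)
}

# Attenuation map used in pipeline tests: the maximum pressure drops to 90%
# at the shortest dwell time of the study grid (about 20 ms at 10 rpm) and is
# unaffected elsewhere.
shortest_dt_attenuation <- function(dt_ms) if (dt_ms < 25) 0.9 else 1
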