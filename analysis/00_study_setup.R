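# Shared study definition sourced by the numbered analysis drivers: the roll
# compactor geometry, the two study materials and their process grids.
#
# The nip-state pressure and density (P_alpha, rho_alpha) are not tabulated
# for these materials; the values below are realistic choices used as
# generating truths for the synthetic studies (see the methods vignette).

library(rollcompact)

geometry <- roll_geometry(D = 250, W = 25, S = 2.0)

mcc <- material_model("MCC", rho0 = 1.56, K = 3.84, yield_pressure = 65,
                      P_alpha = 1, rho_alpha = 0.42)
lactose <- material_model("lactose", rho0 = 1.54, K = 6.90,
                          yield_pressure = 131, P_alpha = 1, rho_alpha = 0.58)

scf_grid <- list(MCC = c(2.9, 4.0, 5.8, 7.6),
                 lactose = c(3.5, 5.2, 7.0, 8.6, 10.3))
rs_grid <- c(1.0, 1.2, 1.5, 2.0, 3.0, 6.0, 10.0)

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
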