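#!/usr/bin/env Rscript
# Binding enhancement in the static chamber: the headline result.
#
# Runs the full coupled pipeline (electrostatics -> slip -> Stokes ->
# transport/reaction) in drive-on/off pairs and reports the enhancement
# factor Be = B/B0 at t = 100 s:
#   - the headline condition 4 V, 10 Hz, Da = 1000;
#   - Be vs Damkohler number (k_on rescaled, k_off fixed);
#   - Be vs drive voltage at 100 Hz.
# Writes: results/enhancement_headline.csv, results/enhancement_da.csv,
#         results/enhancement_voltage.csv

suppressPackageStartupMessages(library(iceobind))
dir.create("results", showWarnings = FALSE)

k_on_da1000 <- 1e3 * 1000 / 660

## headline: 4 V, 10 Hz, Da = 1000
sc <- make_scenario("static_chamber",
                    overrides = list(params.k_on = k_on_da1000))
sc$mesh_resolution <- 1
ef <- enhancement_factor(sc, t_eval = 100)
cat(sprintf("Headline (4 V, 10 Hz, Da = 1000, t = 100 s): Be = %.3f\n", ef$Be))
cat(sprintf("  B_on = %.3e, B_off = %.3e mol/m^2 (B_on/R_T = %.2e)\n",
            ef$B_on, ef$B_off, ef$B_on / sc$params$R_T))
write.csv(data.frame(Be = ef$Be, B_on = ef$B_on, B_off = ef$B_off,
                     V0 = 4, freq = 10, Da = 1000, t_eval = 100),
          "results/enhancement_headline.csv", row.names = FALSE)

## Be vs Da at 4 V, 10 Hz
base <- make_scenario("static_chamber")
base$mesh_resolution <- 0.7
sw_da <- run_sweep(base, "Da", c(10, 100, 660, 1000, 10000), t_eval = 100)
write.csv(sw_da$table, "results/enhancement_da.csv", row.names = FALSE)
cat("\nBe vs Damkohler number (4 V, 10 Hz):\n")
print(sw_da$table[, c("value", "Be", "B_on", "B_off")], row.names = FALSE,
      digits = 4)
cat("Binding enhancement grows with Da: stirring pays off once transport,\n")
cat("not reaction, limits the assay.\n")

## Be vs voltage at 100 Hz, Da = 1000
vb <- make_scenario("static_chamber",
                    overrides = list(params.k_on = k_on_da1000,
                                     drive.freq = 100))
vb$mesh_resolution <- 1  # >= 16 V needs the finer mesh to keep the
# depletion front resolved
sw_v <- run_sweep(vb, "voltage", c(2, 4, 8, 16), t_eval = 100)
write.csv(sw_v$table, "results/enhancement_voltage.csv", row.names = FALSE)
cat("\nBe vs drive amplitude (100 Hz, Da = 1000):\n")
print(sw_v$table[, c("value", "Be", "slip_avg")], row.names = FALSE, digits = 4)
cat("Be rises steeply while transport limits the assay; the gain per volt\n")
cat("shrinks once convection outruns the reaction. (32 V needs a finer\n")
cat("mesh than used here: the depletion front steepens with the slip.)\n")
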