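#!/usr/bin/env Rscript
# Continuous-flow operation: ICEO stirring against a pressure-driven base
# flow in a 1000 x 50 um channel (parabolic inlet, mean 50 um/s, t = 17 s).
#
#   - base condition at 8 V (ICEO speed vs base flow);
#   - Be vs Peclet number (inlet velocity rescaled) at Da = 1000.
# Writes: results/continuous_flow_pe.csv

suppressPackageStartupMessages(library(iceobind))
dir.create("results", showWarnings = FALSE)

k_on_da1000 <- 1e3 * 1000 / 660

sc8 <- make_scenario("continuous_flow",
                     overrides = list(drive.V0 = 8,
                                      params.k_on = k_on_da1000))
sc8$mesh_resolution <- 1
ef8 <- enhancement_factor(sc8, t_eval = 17)
u_iceo <- max(sqrt(ef8$on_run$flow$ux^2 + ef8$on_run$flow$uy^2))
cat(sprintf("Continuous flow, 8 V, Pe = %.0f: Be = %.3f at t = 17 s\n",
            peclet(50e-6, 50e-6, 1e-11), ef8$Be))
cat(sprintf("  peak ICEO-driven speed %.0f um/s vs 50 um/s mean base flow\n",
            u_iceo * 1e6))

base <- make_scenario("continuous_flow",
                      overrides = list(drive.V0 = 8,
                                       params.k_on = k_on_da1000))
base$mesh_resolution <- 0.7
sw <- run_sweep(base, "Pe", c(100, 300, 1000), t_eval = 17)
write.csv(sw$table, "results/continuous_flow_pe.csv", row.names = FALSE)
cat("\nBe vs Peclet number (8 V, Da = 1000):\n")
print(sw$table[, c("value", "Be", "B_on", "B_off")], row.names = FALSE,
      digits = 4)
cat("Faster through-flow replenishes analyte on its own, so the relative\n")
cat("payoff of ICEO stirring shrinks as Pe grows.\n")
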