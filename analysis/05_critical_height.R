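#!/usr/bin/env Rscript
# Critical landing height at which cartilage damage initiates.
#
# Sweeps the full surrogate pipeline over landing heights (load, contact
# pressure, depth-resolved damage indicator), then runs the iterative
# search: start at 1 m and refine with the shrinking increments
# 20, 10, 5, 1 cm until the first damaged integer height is isolated.

library(landingmech)

dir.create("results/critical", recursive = TRUE, showWarnings = FALSE)
cfg <- knee_config()

sweep <- NULL
for (h in seq(20, 150, 10)) {
  d <- damage_scan(h, cfg)
  sweep <- rbind(sweep, data.frame(
    height_cm = h, joint_load_BW = attr(d, "load_bw"),
    pf_load_BW = attr(d, "pf_load_bw"),
    peak_pressure_MPa = attr(d, "peak_pressure"),
    max_damage_indicator = attr(d, "max_damage"),
    damaged = as.logical(d)))
}
write.csv(sweep, "results/critical/height_sweep.csv", row.names = FALSE)
print(round(sweep, 3), row.names = FALSE)

res <- critical_height_search(100, c(20, 10, 5, 1), cfg)
write.csv(res$search_trace, "results/critical/search_trace.csv",
          row.names = FALSE)
cat(sprintf("\ncritical landing height: %d cm (%d pipeline evaluations)\n",
            res$critical_height, res$n_evaluations))

# where does damage start? inspect the field at the critical height
d <- damage_scan(res$critical_height, cfg, detail = TRUE)
fld <- attr(d, "field_tf")
dam <- fld[fld$damaged, ]
cat(sprintf("damaged points at %d cm: %d, all at depth z >= %.2f (superficial layer)\n",
            res$critical_height, nrow(dam), min(dam$z)))
by_z <- aggregate(damage ~ z, fld, max)
write.csv(by_z, "results/critical/damage_by_depth.csv", row.names = FALSE)
print(by_z, row.names = FALSE)
summary <- data.frame(critical_height_cm = res$critical_height,
                      evaluations = res$n_evaluations,
                      peak_pressure_MPa = attr(d, "peak_pressure"),
                      joint_load_BW = attr(d, "load_bw"))
write.csv(summary, "results/critical/summary.csv", row.names = FALSE)
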