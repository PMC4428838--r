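#!/usr/bin/env Rscript
# Stage 3 — per-organoid morphometrics and per-well medians.
#
# Fits the robust log(P) ~ log(A) reference line per cell line (Theil-Sen,
# intercept lowered to the most circle-like object), then derives each
# organoid's log-area, residual shape complexity, dead-cell ratio and
# roundness, and aggregates wells by the median.

suppressPackageStartupMessages(library(organoscreen))

objects <- read.csv("results/objects.csv")
layout <- read.csv("results/layout.csv")

line_of <- layout$cell_line[match(objects$well_id, layout$well_id)]
fits <- lapply(split(objects, line_of), fit_complexity_model)
for (cl in names(fits)) print(fits[[cl]])

records <- do.call(rbind, lapply(names(fits), function(cl)
  morphometric_records(objects[line_of == cl, ], fits[[cl]])))
wells <- aggregate_wells(records, layout)

write.csv(records, "results/records.csv", row.names = FALSE)
write.csv(wells, "results/wells.csv", row.names = FALSE)

veh <- wells[wells$role == "vehicle_control", ]
cat(sprintf("%d wells usable; vehicle wells: median log-area %.2f, median log-complexity %.2f, median dead-ratio %.3f\n",
            nrow(wells), median(veh$med_a), median(veh$med_kappa),
            median(veh$med_rho)))
cat("wrote results/records.csv, results/wells.csv\n")
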