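#!/usr/bin/env Rscript
# Stage 1 — simulate a 96-well organotypic screen with known ground truth.
#
# 20 compounds at 0.03/0.1/0.3/1 uM plus 8 DMSO vehicle and 8 paclitaxel
# positive-control wells. Three compounds carry planted effects: C01 is
# purely anti-invasive (emax 1, EC50 0.3 uM, Hill 2), C02 is cytotoxic
# (growth suppression + death induction), C03 is weakly anti-invasive;
# the rest are inactive. Images go to scratch/ (large, binary), tables to
# results/.

suppressPackageStartupMessages(library(organoscreen))

seed <- 101
layout <- plate_layout(n_compounds = 20)
spec <- synthetic_spec(
  canvas_px = 512, n_organoids_per_well = 6, log_area_mu = 7.6,
  dose_responses = list(
    C01 = list(dose_response(1.0, 0.3, 2, "invasiveness")),
    C02 = list(dose_response(0.7, 0.1, 2, "growth"),
               dose_response(0.5, 0.1, 2, "death")),
    C03 = list(dose_response(0.5, 0.3, 2, "invasiveness"))))

plate <- suppressWarnings(generate_plate(layout, spec, seed = seed,
                                         dir = "scratch/plate"))
dir.create("results", showWarnings = FALSE)
write.csv(plate$layout, "results/layout.csv", row.names = FALSE)
write.csv(plate$truth, "results/truth.csv", row.names = FALSE)

cat(sprintf("simulated %d wells (%d organoids placed) with seed %d\n",
            nrow(layout), nrow(plate$truth), seed))
cat(sprintf("ground-truth median area %d px, mean branch count %.1f, baseline dead fraction %.3f\n",
            round(median(plate$truth$area_px)),
            mean(plate$truth$n_branches),
            median(plate$truth$death_fraction)))
cat("images: scratch/plate/<well>_{green,red}.tif; tables: results/{layout,truth}.csv\n")
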