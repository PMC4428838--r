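#!/usr/bin/env Rscript
# Stage 4 — anchor the well medians to the plate controls.
#
# DMSO vehicle maps to 0 and the paclitaxel positive control to -100
# (area, complexity; it lowers both) or +100 (dead-cell ratio; it raises
# it). Treatments are pooled over replicate wells by median before scaling.

suppressPackageStartupMessages(library(organoscreen))

wells <- read.csv("results/wells.csv")
anchors <- compute_anchors(wells)
profiles <- build_profiles(wells, anchors)

write.csv(anchors, "results/anchors.csv", row.names = FALSE)
write.csv(profiles, "results/profiles.csv", row.names = FALSE)

print(anchors)
pos <- profiles[profiles$role == "positive_control", ]
cat(sprintf("positive control scores: area %.1f, complexity %.1f, death %.1f\n",
            pos$s_area, pos$s_complexity, pos$s_death))
top <- profiles[order(profiles$s_complexity), ][1:5, ]
cat("five most invasion-suppressing conditions:\n")
print(top[, c("compound_id", "concentration_uM", "s_area", "s_complexity",
              "s_death")], row.names = FALSE)
cat("wrote results/anchors.csv, results/profiles.csv\n")
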