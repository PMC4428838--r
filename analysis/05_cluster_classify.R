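#!/usr/bin/env Rscript
# Stage 5 — cluster the anchored profiles and call compound classes.
#
# Ward/Euclidean dendrogram over (s_area, s_complexity, s_death), cut into
# three clusters, plus the rule-based classification into
# growth-inhibitory / anti-invasive (strong, weak) / inactive.

suppressPackageStartupMessages(library(organoscreen))

profiles <- read.csv("results/profiles.csv")
cl <- cluster_profiles(profiles, k = 3)
calls <- classify_compounds(profiles, cluster_ids = cl$assignments)

write.csv(calls, "results/calls.csv", row.names = FALSE)
export_heatmap(profiles, png_file = "results/heatmap.png",
               csv_file = "results/heatmap_matrix.csv")
jsonlite::write_json(organoscreen:::hclust_to_list(cl$hc),
                     "results/dendrogram.json", auto_unbox = TRUE,
                     digits = NA)

cat("class frequencies over compound x concentration conditions:\n")
print(table(calls$class))
active <- calls[calls$class != "inactive" &
                  !(calls$compound_id %in% c("DMSO", "paclitaxel")), ]
cat("active treatment conditions:\n")
print(active[order(active$compound_id, active$concentration_uM), ],
      row.names = FALSE)
cat("wrote results/calls.csv, results/heatmap.png, results/heatmap_matrix.csv, results/dendrogram.json\n")
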