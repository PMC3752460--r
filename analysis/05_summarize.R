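#!/usr/bin/env Rscript
# Difference-map summary table (voxel counts, peak location, t statistics
# within the significant mask) and the adjacency of significant voxels to the
# planted atrophy sphere.

library(rsndr)

cohort <- readRDS("scratch/cohort.rds")
inf <- readRDS("scratch/inference.rds")

tab <- difference_map_table(inf$joint, keep_empty = TRUE)
write.csv(tab, "results/difference_maps.csv", row.names = FALSE)
message("difference-map table (joint correction):")
print(tab)

atro <- truth_atrophy_mask(cohort)
vols <- split_blocks(inf$joint)
sig_any <- Reduce(`|`, lapply(vols, function(v) v$sig))
if (!is.null(atro) && any(sig_any)) {
  adj <- atrophy_adjacency(sig_any, atro$data, d_list = c(0, 1, 2, 3, 5))
  print(adj)
  jsonlite::write_json(unclass(adj), "results/adjacency.json",
                       auto_unbox = TRUE, digits = NA)
} else {
  message("no significant voxels or no planted atrophy; adjacency skipped")
}
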