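#!/usr/bin/env Rscript
# Two-stage dual regression of every subject against the selected group maps,
# run both with and without time-course variance normalization: with it the
# subject maps carry amplitude differences, without it only spatial shape.

library(rsndr)

cohort <- readRDS("scratch/cohort.rds")
ica <- readRDS("scratch/ica.rds")

dr <- list()
for (dn in c(TRUE, FALSE)) {
  dr[[if (dn) "desnorm1" else "desnorm0"]] <-
    dual_regression(cohort$subjects, ica$selected, des_norm = dn,
                    mask = cohort$mask)
  message(sprintf("des_norm=%d: %d subject map sets x %d components",
                  as.integer(dn), length(cohort$subjects), ica$selected$order))
}
saveRDS(dr, "scratch/dualreg.rds")
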