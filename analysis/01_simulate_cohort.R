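#!/usr/bin/env Rscript
# Simulate the study cohort the downstream stages analyse: two groups on a
# common 4 mm grid, BOLD = networks x band-limited time courses + noise, with
# a planted amplitude increase on one network and focal atrophy on another.
# Desk-scale geometry (24x24x16, T = 150) keeps the full workflow minutes-fast;
# the group structure (19 + 19 is the study default; 10 + 10 here) and the
# signal model are unchanged by the scaling.

library(rsndr)

out <- "results/cohort"
cfg <- cohort_config(
  n_patients = 10, n_controls = 10,
  grid = c(24, 24, 16), n_networks = 6, t_points = 150, tr = 1.8,
  noise_std = 0.7, width_range = c(1.4, 2), min_center_separation = 6,
  mask_semiaxes = c(9, 9, 6.5),
  effects = list(
    # a genuine connectivity-amplitude increase on network 1
    effect_spec(1, amplitude_ratio = 2),
    # and a purely structural confound on network 2: atrophy reduces GM and
    # attenuates BOLD there, creating a group difference the voxel-wise GM
    # covariate should absorb
    effect_spec(2, atrophy = list(center = NULL, radius = 3,
                                  gm_reduction = 0.3,
                                  bold_attenuation = 0.3))))

cohort <- simulate_cohort(cfg, seed = 11)
write_cohort(cohort, out)
dir.create("scratch", showWarnings = FALSE)
saveRDS(cohort, file.path("scratch", "cohort.rds"))   # binary intermediates stay in scratch/

message(sprintf("wrote %d subjects (%d patients, %d controls) to %s",
                length(cohort$subjects),
                sum(cohort$design$group == "patient"),
                sum(cohort$design$group == "control"), out))
message(sprintf("analysis mask: %d voxels; networks at:", sum(cohort$mask$data)))
print(cohort$atlas$centers)
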