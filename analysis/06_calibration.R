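#!/usr/bin/env Rscript
# Error-control and power calibration of the inference machinery on
# replicated synthetic cohorts. A reduced replicate count keeps this driver
# quick; scripts/acceptance.R runs the full 200-cohort null harness.

library(rsndr)

message("null calibration (50 cohorts) ...")
fw <- fwer_null_experiment(n_cohorts = 50, n_perm = 250, seed = 61)
message(sprintf("joint FWER %.3f, single-map FWER %.3f (nominal 0.05)",
                mean(fw$joint_sig), mean(fw$single_sig)))
write.csv(fw, "results/fwer_null.csv", row.names = FALSE)

message("power at amplitude ratio 2, n = 10+10 (20 replicates) ...")
pw <- power_experiment(n_reps = 20, amplitude_ratio = 2, seed = 62)
message(sprintf("planted network detected in %.0f%% of replicates",
                100 * mean(pw$detected)))
write.csv(pw, "results/power.csv", row.names = FALSE)

message("gray-matter confound adjustment (10 replicates) ...")
cf <- confound_experiment(n_reps = 10, seed = 63)
message(sprintf("significant voxels: %.1f without covariate vs %.1f with",
                mean(cf$n_sig_without_cov), mean(cf$n_sig_with_cov)))
write.csv(cf, "results/confound.csv", row.names = FALSE)
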