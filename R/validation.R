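# Replicated-simulation experiments used to validate the error control and
# power of the whole pipeline. These run the same path a real analysis runs
# (simulate -> dual regression -> joint permutation inference); the analysis
# drivers, the test suite and the acceptance script all call them.

#' Family-wise error rate under the global null
#'
#' Generates replicated null cohorts (no planted group effect, so the two
#' groups are exchangeable), runs dual regression against the ground-truth
#' atlas as template and the joint inter-component TFCE permutation test, and
#' records for each cohort whether any voxel in any block is significant at
#' the corrected threshold. The same dual-regression output also feeds a
#' single-block (voxel-level-only) test, so both corrections are calibrated
#' on one simulation stream.
#'
#' @param n_cohorts number of replicated null cohorts.
#' @param n_perm permutations per cohort.
#' @param seed master seed; cohort and permutation seeds are derived from it.
#' @param n_per_group subjects per group.
#' @param grid,n_networks,t_points cohort geometry (defaults: 24 x 24 x 16
#'   grid, 6 networks, T = 100).
#' @param alpha corrected significance threshold.
#' @param des_norm dual-regression variance-normalization switch.
#' @return `data.frame` with one row per cohort: `cohort`, `joint_sig` (any
#'   significant voxel across all blocks), `single_sig` (any significant
#'   voxel in the single-block test), `joint_min_p`, `single_min_p`.
#' @export
fwer_null_experiment <- function(n_cohorts = 200, n_perm = 250, seed = 1L,
                                 n_per_group = 8, grid = c(24, 24, 16),
                                 n_networks = 6, t_points = 100,
                                 alpha = 0.05, des_norm = TRUE) {
  cfg <- cohort_config(n_patients = n_per_group, n_controls = n_per_group,
                       grid = grid, n_networks = n_networks,
                       t_points = t_points)
  out <- data.frame(cohort = seq_len(n_cohorts), joint_sig = NA,
                    single_sig = NA, joint_min_p = NA_real_,
                    single_min_p = NA_real_)
  for (i in seq_len(n_cohorts)) {
    ch <- simulate_cohort(cfg, seed = derive_seed(seed, i))
    tpl <- as_template(ch$atlas, ch$mask)
    dr <- dual_regression(ch$subjects, tpl, des_norm = des_norm, mask = ch$mask)
    blocks <- dualreg_blocks(dr)
    pseed <- derive_seed(seed, 500000L + i)
    joint <- suppressWarnings(
      permutation_test(yconcat(blocks, ch$design, ch$mask),
                       n_perm = n_perm, seed = pseed, alpha = alpha))
    single <- suppressWarnings(
      per_map_test(blocks[[1]], ch$design, ch$mask,
                   n_perm = n_perm, seed = pseed, alpha = alpha))
    out$joint_sig[i] <- n_significant_ics(joint) > 0
    out$single_sig[i] <- n_significant_ics(single) > 0
    out$joint_min_p[i] <- min(vapply(joint$blocks, function(b) min(b$p), 1.0))
    out$single_min_p[i] <- min(single$blocks[[1]]$p)
  }
  out
}

#' One-sided lower binomial confidence bound on a proportion
#'
#' Clopper-Pearson lower bound; used to compare an empirical family-wise
#' error rate against its nominal level allowing for simulation error.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return Lower bound on the proportion.
#' @export
binom_lower_bound <- function(x, n, level = 0.95) {
  if (x == 0) return(0)
  qbeta(1 - level, x, n - x + 1)
}

#' Detection power for a planted amplitude difference
#'
#' Replicated cohorts in which one network's time-course amplitude is
#' multiplied by `amplitude_ratio` in patients. Each replicate runs dual
#' regression (variance-normalized, so amplitude differences reach the betas)
#' and the joint inter-component permutation test; detection means at least
#' one significant voxel of the affected network's block overlaps the
#' network's truth blob (map weight >= `blob_cut`).
#'
#' @param n_reps replicates.
#' @param amplitude_ratio patient/control amplitude ratio on the affected
#'   network.
#' @param network index of the affected network.
#' @param n_per_group subjects per group (default 10).
#' @param n_perm,seed,grid,n_networks,t_points,alpha as in
#'   [fwer_null_experiment()].
#' @param blob_cut truth-blob threshold on the network map.
#' @return `data.frame` with `rep`, `detected`, `n_sig_voxels` (in the
#'   affected block), `n_overlap`.
#' @export
power_experiment <- function(n_reps = 50, amplitude_ratio = 2, network = 1L,
                             n_per_group = 10, n_perm = 250, seed = 1L,
                             grid = c(24, 24, 16), n_networks = 6,
                             t_points = 100, alpha = 0.05, blob_cut = 0.5) {
  cfg <- cohort_config(n_patients = n_per_group, n_controls = n_per_group,
                       grid = grid, n_networks = n_networks,
                       t_points = t_points,
                       effects = list(effect_spec(network,
                                                  amplitude_ratio = amplitude_ratio)))
  out <- data.frame(rep = seq_len(n_reps), detected = NA,
                    n_sig_voxels = NA_integer_, n_overlap = NA_integer_)
  for (i in seq_len(n_reps)) {
    ch <- simulate_cohort(cfg, seed = derive_seed(seed, i))
    tpl <- as_template(ch$atlas, ch$mask)
    dr <- dual_regression(ch$subjects, tpl, des_norm = TRUE, mask = ch$mask)
    res <- suppressWarnings(
      permutation_test(yconcat(dualreg_blocks(dr), ch$design, ch$mask),
                       n_perm = n_perm,
                       seed = derive_seed(seed, 500000L + i),
                       alpha = alpha, direction = "patient>control"))
    blob <- array(ch$atlas$maps[network, ] >= blob_cut, dim = grid)
    sig <- split_blocks(res)[[as.character(network)]]$sig
    out$n_sig_voxels[i] <- sum(sig)
    out$n_overlap[i] <- sum(sig & blob)
    out$detected[i] <- out$n_overlap[i] > 0
  }
  out
}

#' Gray-matter confound adjustment experiment
#'
#' Replicated cohorts whose only group difference is planted focal atrophy:
#' inside a sphere centred on one network, patient gray matter is reduced and
#' the BOLD network weights attenuated by the same fraction. The resulting
#' group difference in dual-regression betas is anatomically confounded —
#' adding the voxel-wise (smoothed) GM covariate via Freedman-Lane
#' permutation should remove it, while omitting the covariate should not.
#' Both tests run on the same dual-regression output and simulation stream.
#'
#' @param n_reps replicates.
#' @param gm_reduction,bold_attenuation atrophy fractions.
#' @param radius atrophy sphere radius (voxels).
#' @param network affected network index.
#' @param gm_sigma_mm Gaussian smoothing applied to the GM covariate maps.
#' @param n_per_group,n_perm,seed,grid,n_networks,t_points,alpha as in
#'   [fwer_null_experiment()].
#' @return `data.frame` with per-replicate significant-voxel counts
#'   `n_sig_with_cov`, `n_sig_without_cov` and any-significant flags.
#' @export
confound_experiment <- function(n_reps = 25, gm_reduction = 0.4,
                                bold_attenuation = 0.4, radius = 3,
                                network = 1L, gm_sigma_mm = 3,
                                n_per_group = 10, n_perm = 250, seed = 1L,
                                grid = c(24, 24, 16), n_networks = 6,
                                t_points = 100, alpha = 0.05) {
  cfg <- cohort_config(
    n_patients = n_per_group, n_controls = n_per_group, grid = grid,
    n_networks = n_networks, t_points = t_points,
    effects = list(effect_spec(network, amplitude_ratio = 1,
                               atrophy = list(center = NULL, radius = radius,
                                              gm_reduction = gm_reduction,
                                              bold_attenuation = bold_attenuation))))
  out <- data.frame(rep = seq_len(n_reps),
                    n_sig_with_cov = NA_integer_, n_sig_without_cov = NA_integer_,
                    any_with_cov = NA, any_without_cov = NA)
  for (i in seq_len(n_reps)) {
    ch <- simulate_cohort(cfg, seed = derive_seed(seed, i))
    tpl <- as_template(ch$atlas, ch$mask)
    dr <- dual_regression(ch$subjects, tpl, des_norm = TRUE, mask = ch$mask)
    blocks <- dualreg_blocks(dr)
    gm_sm <- lapply(ch$gm_maps, smooth_volume, sigma_mm = gm_sigma_mm)
    gm_cov <- do.call(rbind, lapply(mask_to_matrix(gm_sm, ch$mask)$mats,
                                    function(m) m[1, ]))
    pseed <- derive_seed(seed, 500000L + i)
    res_no <- suppressWarnings(
      permutation_test(yconcat(blocks, ch$design, ch$mask),
                       n_perm = n_perm, seed = pseed, alpha = alpha,
                       direction = "control>patient"))
    res_cov <- suppressWarnings(
      permutation_test(yconcat(blocks, ch$design, ch$mask, covariate = gm_cov),
                       n_perm = n_perm, seed = pseed, alpha = alpha,
                       direction = "control>patient"))
    count <- function(r) sum(vapply(r$blocks, function(b) sum(b$p < alpha), 1L))
    out$n_sig_with_cov[i] <- count(res_cov)
    out$n_sig_without_cov[i] <- count(res_no)
    out$any_with_cov[i] <- out$n_sig_with_cov[i] > 0
    out$any_without_cov[i] <- out$n_sig_without_cov[i] > 0
  }
  out
}
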