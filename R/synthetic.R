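#' Gaussian-blob network atlas
#'
#' Builds a ground-truth set of spatial network maps: `n_networks` isotropic
#' Gaussian blobs with unit peak, centres drawn inside the analysis region
#' with a minimum pairwise separation. These play the role the classical
#' resting-state networks play in a real cohort: each map, multiplied by a
#' band-limited time course, contributes one coherent signal source.
#'
#' @param n_networks number of networks (>= 1; configurations up to 70 are
#'   supported, matching high-model-order group ICA).
#' @param grid 3-vector of grid dimensions.
#' @param width_range range of Gaussian sigma, in voxels, sampled per network.
#' @param min_center_separation minimum Euclidean distance between centres
#'   (voxels).
#' @param seed RNG seed; stored with the atlas.
#' @param within optional [brain_mask()]; centres are restricted to its TRUE
#'   voxels (with a 1-sigma margin to the mask border where possible).
#' @param affine affine shared by the atlas maps.
#' @param max_tries placement retries before giving up.
#' @return Object of class `network_atlas`: `maps` (n x V_grid matrix over the
#'   full grid, each row max 1), `centers`, `widths`, `grid`, `affine`, `seed`.
#' @export
make_network_atlas <- function(n_networks, grid = c(24, 24, 16),
                               width_range = c(1.8, 3.2),
                               min_center_separation = 6,
                               seed = 1L, within = NULL,
                               affine = diag(c(4, 4, 4, 1)),
                               max_tries = 20000L) {
  stopifnot(n_networks >= 1, length(grid) == 3)
  if (n_networks > 70) stop("n_networks above 70 is not supported")
  candidates <- if (is.null(within)) {
    which(array(TRUE, grid))
  } else {
    stopifnot(all(dim(within$data) == grid))
    which(within$data)
  }
  coords_all <- arrayInd(candidates, grid)
  with_seed(seed, {
    centers <- matrix(NA_real_, n_networks, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n_networks) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(paste0("could not place %d network centres with separation %g ",
                            "after %d tries; reduce n_networks or the separation"),
                     n_networks, min_center_separation, max_tries))
      }
      if (tries %% 1000L == 0L) placed <- 0L   # restart a stuck packing
      cand <- coords_all[sample.int(nrow(coords_all), 1L), ]
      if (placed > 0L) {
        d <- sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                             matrix(cand, placed, 3, byrow = TRUE))^2))
        if (min(d) < min_center_separation) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    widths <- stats::runif(n_networks, width_range[1], width_range[2])
    ii <- slice.index(array(0, grid), 1)
    jj <- slice.index(array(0, grid), 2)
    kk <- slice.index(array(0, grid), 3)
    maps <- matrix(0, n_networks, prod(grid))
    for (k in seq_len(n_networks)) {
      d2 <- (ii - centers[k, 1])^2 + (jj - centers[k, 2])^2 + (kk - centers[k, 3])^2
      maps[k, ] <- exp(-d2 / (2 * widths[k]^2))
    }
    structure(list(maps = maps, centers = centers, widths = widths,
                   grid = grid, affine = affine, seed = seed),
              class = "network_atlas")
  })
}

#' @export
print.network_atlas <- function(x, ...) {
  cat(sprintf("<network_atlas> %d networks on a %s grid (seed %d)\n",
              nrow(x$maps), paste(x$grid, collapse = " x "), x$seed))
  invisible(x)
}

#' Planted group-effect specification
#'
#' Describes how patients differ from controls on one network: a multiplicative
#' change in time-course amplitude, an optional extra spatial blob (changing
#' the network's extent), and an optional focal atrophy sphere that reduces
#' gray-matter density and attenuates the BOLD weights inside it. Atrophy's
#' two knobs are deliberately separable so that confound-adjustment behaviour
#' can be probed with either alone.
#'
#' @param network index of the affected network in the atlas.
#' @param amplitude_ratio patient/control ratio of the network time-course
#'   standard deviation (> 0; 1 = no amplitude effect).
#' @param spatial_shift optional list `(center, sigma, weight)`: an extra
#'   Gaussian blob added to the patient version of the network map.
#' @param atrophy optional list `(center, radius, gm_reduction,
#'   bold_attenuation)`: inside the sphere, patient GM is multiplied by
#'   `1 - gm_reduction` and patient network weights by `1 - bold_attenuation`
#'   (both fractions in `[0, 1]`). A `NULL` center resolves to the affected
#'   network's centre at simulation time (so does a `NULL` `spatial_shift`
#'   center).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(network, amplitude_ratio = 1,
                        spatial_shift = NULL, atrophy = NULL) {
  stopifnot(amplitude_ratio > 0)
  if (!is.null(atrophy)) {
    stopifnot(atrophy$gm_reduction >= 0, atrophy$gm_reduction <= 1,
              atrophy$bold_attenuation >= 0, atrophy$bold_attenuation <= 1,
              atrophy$radius > 0)
  }
  structure(list(network = as.integer(network),
                 amplitude_ratio = amplitude_ratio,
                 spatial_shift = spatial_shift, atrophy = atrophy),
            class = "effect_spec")
}

# Band-limited unit-variance time courses: white Gaussian noise whose Fourier
# coefficients above the cutoff are zeroed, then exactly rescaled.
bandlimited_timecourse <- function(t_points, tr, lowpass_hz, n = 1L) {
  if (lowpass_hz >= 1 / (2 * tr)) {
    stop(sprintf("lowpass (%g Hz) must be below the Nyquist frequency %g Hz",
                 lowpass_hz, 1 / (2 * tr)))
  }
  k <- 0:(t_points - 1)
  freq <- pmin(k, t_points - k) / (t_points * tr)
  keep <- freq <= lowpass_hz & k != 0L
  if (!any(keep)) stop("no frequency bins below the lowpass cutoff; increase T or the cutoff")
  out <- matrix(0, t_points, n)
  for (j in seq_len(n)) {
    w <- rnorm(t_points)
    coef <- fft(w)
    coef[!keep] <- 0
    x <- Re(fft(coef, inverse = TRUE)) / t_points
    x <- x - mean(x)
    s <- sqrt(mean(x^2))
    out[, j] <- if (s > 0) x / s else x
  }
  out
}

apply_sphere <- function(vals, grid, center, radius, factor) {
  ii <- slice.index(array(0, grid), 1)
  jj <- slice.index(array(0, grid), 2)
  kk <- slice.index(array(0, grid), 3)
  inside <- (ii - center[1])^2 + (jj - center[2])^2 + (kk - center[3])^2 <= radius^2
  vals[inside] <- vals[inside] * factor
  vals
}

sphere_mask <- function(grid, center, radius, affine = diag(c(4, 4, 4, 1))) {
  ii <- slice.index(array(0, grid), 1)
  jj <- slice.index(array(0, grid), 2)
  kk <- slice.index(array(0, grid), 3)
  brain_mask((ii - center[1])^2 + (jj - center[2])^2 + (kk - center[3])^2 <= radius^2,
             affine = affine)
}

#' Simulate one subject's BOLD volume and gray-matter map
#'
#' Voxel signal is `sum_k map_k(v) * c_k(t) + noise(v, t)`: each network map
#' weighted by a band-limited (`< lowpass_hz`) time course scaled to the
#' requested standard deviation, plus i.i.d. Gaussian noise. Effects (for
#' patient subjects) modify the amplitude, the map, or apply atrophy: inside
#' the atrophy sphere the GM map is multiplied by `1 - gm_reduction` and the
#' network weights by `1 - bold_attenuation`.
#'
#' The GM map is a smooth baseline (0.7 inside a brain ellipsoid) plus small
#' per-subject Gaussian jitter (sd 0.02), minus any atrophy.
#'
#' @param atlas a [make_network_atlas()] atlas.
#' @param effects `NULL` (control) or list of [effect_spec()] (patient).
#' @param t_points number of time points (study default 285).
#' @param tr repetition time in seconds (study default 1.8).
#' @param amp_std per-network time-course standard deviation (recycled).
#' @param noise_std i.i.d. noise standard deviation.
#' @param lowpass_hz time-course band limit in Hz (default 0.08).
#' @param seed RNG seed.
#' @return List with `bold` ([volume4d()]), `gm` (3D [volume4d()] in `[0,1]`),
#'   and `timecourses` (T x n_networks matrix of the planted `c_k`).
#' @export
simulate_subject <- function(atlas, effects = NULL, t_points = 285, tr = 1.8,
                             amp_std = 1, noise_std = 1, lowpass_hz = 0.08,
                             seed = 1L) {
  stopifnot(inherits(atlas, "network_atlas"))
  n_net <- nrow(atlas$maps)
  amp_std <- rep_len(amp_std, n_net)
  grid <- atlas$grid
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  with_seed(seed, {
    tcs <- bandlimited_timecourse(t_points, tr, lowpass_hz, n = n_net)
    maps <- atlas$maps
    amps <- amp_std
    gm <- 0.7 * as.numeric(ellipsoid_mask(grid, semiaxes = grid * 0.30,
                                          affine = atlas$affine)$data)
    for (ef in effects) {
      k <- ef$network
      amps[k] <- amps[k] * ef$amplitude_ratio
      if (!is.null(ef$spatial_shift)) {
        ss <- ef$spatial_shift
        if (is.null(ss$center)) ss$center <- atlas$centers[k, ]
        ii <- slice.index(array(0, grid), 1)
        jj <- slice.index(array(0, grid), 2)
        kk <- slice.index(array(0, grid), 3)
        d2 <- (ii - ss$center[1])^2 + (jj - ss$center[2])^2 + (kk - ss$center[3])^2
        maps[k, ] <- pmin(maps[k, ] + ss$weight * exp(-d2 / (2 * ss$sigma^2)), 1)
      }
      if (!is.null(ef$atrophy)) {
        at <- ef$atrophy
        if (is.null(at$center)) at$center <- atlas$centers[k, ]
        maps[k, ] <- apply_sphere(maps[k, ], grid, at$center, at$radius,
                                  1 - at$bold_attenuation)
        gm <- apply_sphere(gm, grid, at$center, at$radius, 1 - at$gm_reduction)
      }
    }
    for (k in seq_len(n_net)) tcs[, k] <- tcs[, k] * amps[k]
    signal <- tcs %*% maps                       # T x V_grid
    noise <- matrix(rnorm(t_points * prod(grid), sd = noise_std), t_points)
    bold <- array(t(signal + noise), dim = c(grid, t_points))
    gm <- pmin(pmax(gm + rnorm(prod(grid), sd = 0.02), 0), 1)
    list(bold = volume4d(bold, affine = atlas$affine, tr = tr),
         gm = volume4d(array(gm, grid), affine = atlas$affine, tr = tr),
         timecourses = tcs)
  })
}

#' Cohort configuration defaults
#'
#' Study-scale defaults: 19 patients and 19 controls, 285 time points at
#' TR 1.8 s, fluctuations band-limited below 0.08 Hz. Grid and network count
#' default to a compact desk-scale geometry.
#'
#' @param n_patients,n_controls group sizes.
#' @param grid 3-vector of grid dimensions.
#' @param n_networks number of planted networks.
#' @param t_points,tr,amp_std,noise_std,lowpass_hz see [simulate_subject()].
#' @param effects list of [effect_spec()] applied to patients only.
#' @param width_range,min_center_separation atlas parameters.
#' @param mask_semiaxes semi-axes of the analysis ellipsoid mask (voxels).
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 19, n_controls = 19,
                          grid = c(24, 24, 16), n_networks = 6,
                          t_points = 285, tr = 1.8, amp_std = 1,
                          noise_std = 1, lowpass_hz = 0.08,
                          effects = list(),
                          width_range = c(1.8, 3.2),
                          min_center_separation = 4,
                          mask_semiaxes = grid * c(0.23, 0.23, 0.25)) {
  cfg <- list(n_patients = n_patients, n_controls = n_controls, grid = grid,
              n_networks = n_networks, t_points = t_points, tr = tr,
              amp_std = amp_std, noise_std = noise_std,
              lowpass_hz = lowpass_hz, effects = effects,
              width_range = width_range,
              min_center_separation = min_center_separation,
              mask_semiaxes = mask_semiaxes)
  problems <- character(0)
  if (n_patients < 1 || n_controls < 1) problems <- c(problems, "both groups must be non-empty")
  if (n_networks < 1) problems <- c(problems, "n_networks must be >= 1")
  if (t_points < 2) problems <- c(problems, "t_points must be >= 2")
  if (tr <= 0) problems <- c(problems, "tr must be positive")
  if (lowpass_hz >= 1 / (2 * tr)) problems <- c(problems, "lowpass_hz must be below Nyquist")
  if (noise_std < 0) problems <- c(problems, "noise_std must be non-negative")
  for (ef in effects) {
    if (!inherits(ef, "effect_spec")) problems <- c(problems, "effects must be effect_spec objects")
    else if (ef$network > n_networks) problems <- c(problems, sprintf("effect network %d exceeds n_networks", ef$network))
  }
  if (length(problems)) stop("invalid cohort config:\n  - ", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "cohort_config")
}

#' Simulate a two-group cohort
#'
#' Per-subject seeds are derived deterministically from the cohort seed, so
#' identical config + seed reproduces the cohort bit-identically. Patients
#' receive the configured effects; controls never do, so a cohort with no
#' effects is an exchangeable global null.
#'
#' @param config a [cohort_config()].
#' @param seed cohort seed.
#' @return Object of class `synthetic_cohort`: `subjects` (list of
#'   [volume4d()]), `gm_maps`, `design` (in-memory [design_table()] with
#'   placeholder paths), `mask`, `atlas`, `truth` (per-subject planted
#'   time courses and the effect list), `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- config$grid
  mask <- ellipsoid_mask(grid, semiaxes = config$mask_semiaxes)
  atlas <- make_network_atlas(config$n_networks, grid = grid,
                              width_range = config$width_range,
                              min_center_separation = config$min_center_separation,
                              seed = derive_seed(seed, 0L),
                              within = mask)
  n <- config$n_patients + config$n_controls
  groups <- rep(c("patient", "control"), c(config$n_patients, config$n_controls))
  subjects <- vector("list", n)
  gm_maps <- vector("list", n)
  truth_tcs <- vector("list", n)
  for (i in seq_len(n)) {
    ef <- if (groups[i] == "patient") config$effects else NULL
    sub <- simulate_subject(atlas, effects = ef, t_points = config$t_points,
                            tr = config$tr, amp_std = config$amp_std,
                            noise_std = config$noise_std,
                            lowpass_hz = config$lowpass_hz,
                            seed = derive_seed(seed, i))
    subjects[[i]] <- sub$bold
    gm_maps[[i]] <- sub$gm
    truth_tcs[[i]] <- sub$timecourses
  }
  ids <- sprintf("sub%02d", seq_len(n))
  design <- design_table(data.frame(subject_id = ids, group = groups,
                                    bold_path = sprintf("%s_bold.nii", ids),
                                    gm_path = sprintf("%s_gm.nii", ids),
                                    stringsAsFactors = FALSE))
  structure(list(subjects = subjects, gm_maps = gm_maps, design = design,
                 mask = mask, atlas = atlas,
                 truth = list(timecourses = truth_tcs, effects = config$effects),
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients + %d controls, %s grid, T=%d (seed %d)\n",
              sum(x$design$group == "patient"), sum(x$design$group == "control"),
              paste(x$config$grid, collapse = "x"), x$config$t_points, x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes per-subject BOLD and GM volumes as NIfTI, the mask, the design TSV
#' (with real paths) and a JSON truth sidecar recording the generation seed,
#' network centres/widths and effect list.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The design-table path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- cohort$design
  for (i in seq_len(nrow(design))) {
    bp <- sprintf("%s_bold.nii", design$subject_id[i])
    gp <- sprintf("%s_gm.nii", design$subject_id[i])
    write_volume(file.path(dir, bp), cohort$subjects[[i]])
    write_volume(file.path(dir, gp), cohort$gm_maps[[i]])
    # paths relative to the design file keep the cohort relocatable (and its
    # checksums reproducible across output directories)
    design$bold_path[i] <- bp
    design$gm_path[i] <- gp
  }
  write_volume(file.path(dir, "mask.nii"), cohort$mask)
  dpath <- file.path(dir, "design.tsv")
  write_design(design, dpath)
  truth <- list(seed = cohort$seed,
                centers = cohort$atlas$centers,
                widths = cohort$atlas$widths,
                effects = lapply(cohort$truth$effects, unclass))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dpath)
}
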