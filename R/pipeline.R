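#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate -> group ICA -> dual regression -> permutation
#' inference -> summaries, writing every stage's artifacts under `out_dir`
#' and a JSON run manifest (seeds, parameters, per-file checksums). Rerunning
#' with the same configuration reproduces identical checksums.
#'
#' The configuration is a YAML file or an equivalent nested list with blocks:
#' \describe{
#'   \item{simulate}{[cohort_config()] fields plus `seed`; `effects` is a list
#'     of [effect_spec()] field sets. Alternatively `data: (design, mask)`
#'     paths to an existing cohort.}
#'   \item{ica}{`template: truth` to use the generator's atlas directly, or
#'     `order`, `source_group` (default `control`), `seed`, and optionally
#'     `keep` (component labels) or `match_truth: yes` with `min_cor`.}
#'   \item{dualreg}{`des_norm`: `1`, `0`, or `both`.}
#'   \item{infer}{`n_perm`, `alpha`, `seed`, `direction`
#'     (`patient>control`, `control>patient`), `gm_covariate` (logical),
#'     `gm_sigma_mm` (smoothing of the covariate maps, default 3).}
#'   \item{summarize}{`d_list` for [atrophy_adjacency()].}
#' }
#'
#' @param config path to a YAML file, or a nested list.
#' @param out_dir output directory (created).
#' @return The manifest, invisibly; written as `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg, stages = list())
  t_all <- Sys.time()
  stage <- function(name, code) {
    t0 <- Sys.time()
    message(sprintf("[rsndr] stage %-9s started", name))
    res <- tryCatch(code, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[rsndr] stage %-9s done in %.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # --- simulate (or load) -------------------------------------------------
  sim_dir <- file.path(out_dir, "cohort")
  env <- stage("simulate", {
    if (!is.null(cfg$simulate$data)) {
      design <- read_design(cfg$simulate$data$design)
      mask <- read_mask(cfg$simulate$data$mask)
      subjects <- lapply(design$bold_path, read_volume4d)
      gm <- if (all(!is.na(design$gm_path))) lapply(design$gm_path, read_volume4d)
      list(design = design, mask = mask, subjects = subjects, gm = gm,
           atlas = NULL, cohort = NULL)
    } else {
      sc <- cfg$simulate
      effects <- lapply(sc$effects, function(e) do.call(effect_spec, e))
      cc <- cohort_config(
        n_patients = sc$n_per_group %||% sc$n_patients %||% 19,
        n_controls = sc$n_per_group %||% sc$n_controls %||% 19,
        grid = unlist(sc$grid %||% c(24, 24, 16)),
        n_networks = sc$n_networks %||% 6,
        t_points = sc$t_points %||% 285, tr = sc$tr %||% 1.8,
        amp_std = sc$amp_std %||% 1, noise_std = sc$noise_std %||% 1,
        lowpass_hz = sc$lowpass_hz %||% 0.08, effects = effects)
      cohort <- simulate_cohort(cc, seed = sc$seed %||% 1L)
      write_cohort(cohort, sim_dir)
      list(design = cohort$design, mask = cohort$mask,
           subjects = cohort$subjects, gm = cohort$gm_maps,
           atlas = cohort$atlas, cohort = cohort)
    }
  })
  cohort <- env$cohort

  # --- group ICA / template ----------------------------------------------
  template <- stage("groupica", {
    ic <- cfg$ica
    if (isTRUE(ic$template == "truth")) {
      if (is.null(env$atlas)) stop("template 'truth' requires a simulated cohort")
      as_template(env$atlas, env$mask)
    } else {
      src <- ic$source_group %||% "control"
      subs <- if (src == "all") env$subjects else env$subjects[env$design$group == src]
      maps <- run_group_ica(subs, env$mask, order = ic$order,
                            seed = ic$seed %||% 1L)
      mix <- lapply(seq_len(maps$order), function(k) {
        fit_mixture_threshold(maps$zmaps[k, ], local_fdr_cut = ic$local_fdr_cut %||% 0.5)$fit
      })
      write_volume(file.path(out_dir, "group_maps.nii"),
                   volume4d(unmask(maps$zmaps, env$mask), affine = env$mask$affine, tr = 1))
      jsonlite::write_json(
        list(order = maps$order, seed = maps$seed,
             mixture = lapply(mix, function(f) f[c("weight_null", "weight_pos",
                                                   "weight_neg", "null_mean", "null_sd")]),
             converged = vapply(mix, function(f) f$converged, logical(1))),
        file.path(out_dir, "group_maps.json"), auto_unbox = TRUE, digits = NA)
      if (!is.null(ic$keep)) {
        select_components(maps, keep = unlist(ic$keep))
      } else if (isTRUE(ic$match_truth)) {
        select_components(maps, atlas = env$atlas, min_cor = ic$min_cor %||% 0.5)
      } else {
        maps
      }
    }
  })

  des_norms <- switch(as.character(cfg$dualreg$des_norm %||% "both"),
                      "both" = c(TRUE, FALSE), "1" = TRUE, "0" = FALSE,
                      "TRUE" = TRUE, "FALSE" = FALSE,
                      stop("dualreg$des_norm must be 1, 0 or 'both'"))
  gm_cov <- NULL
  if (isTRUE(cfg$infer$gm_covariate)) {
    if (is.null(env$gm)) stop("gm_covariate requested but no GM maps available")
    sig <- cfg$infer$gm_sigma_mm %||% 3
    gm_sm <- lapply(env$gm, smooth_volume, sigma_mm = sig)
    gm_cov <- do.call(rbind, lapply(mask_to_matrix(gm_sm, env$mask)$mats,
                                    function(m) m[1, ]))
  }

  results <- list()
  for (dn in des_norms) {
    tag <- if (dn) "desnorm1" else "desnorm0"
    dr <- stage(paste0("dualreg/", tag), {
      dual_regression(env$subjects, template, des_norm = dn, mask = env$mask)
    })
    res <- stage(paste0("infer/", tag), {
      ds <- yconcat(dualreg_blocks(dr), env$design, env$mask, covariate = gm_cov)
      permutation_test(ds, n_perm = cfg$infer$n_perm %||% 5000,
                       seed = cfg$infer$seed %||% 1L,
                       direction = cfg$infer$direction %||% "patient>control",
                       alpha = cfg$infer$alpha %||% 0.05)
    })
    stage(paste0("summarize/", tag), {
      tab <- difference_map_table(res, keep_empty = TRUE)
      write.csv(tab, file.path(out_dir, sprintf("difference_maps_%s.csv", tag)),
                row.names = FALSE)
      vols <- split_blocks(res)
      for (lbl in names(vols)) {
        write_volume(file.path(out_dir, sprintf("tmap_%s_ic%s.nii", tag, lbl)),
                     volume4d(vols[[lbl]]$t, affine = env$mask$affine, tr = 1))
      }
      atro <- truth_atrophy_mask(cohort)
      if (!is.null(atro)) {
        sig_any <- Reduce(`|`, lapply(vols, function(v) v$sig))
        adj <- atrophy_adjacency(sig_any, atro$data,
                                 d_list = unlist(cfg$summarize$d_list %||% c(0, 1, 2, 3, 5)))
        jsonlite::write_json(unclass(adj),
                             file.path(out_dir, sprintf("adjacency_%s.json", tag)),
                             auto_unbox = TRUE, digits = NA)
      }
      NULL
    })
    manifest$stages[[tag]] <- list(
      des_norm = as.integer(dn),
      n_perm = res$n_perm, seed = res$seed, direction = res$direction,
      alpha = res$alpha, exhaustive = res$exhaustive,
      n_significant_ics = n_significant_ics(res))
    results[[tag]] <- res
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$checksums) <- files
  manifest$elapsed_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  mpath <- file.path(out_dir, "manifest.json")
  save <- manifest
  save$elapsed_seconds <- NULL     # keep the file itself reproducible
  jsonlite::write_json(save, mpath, auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("[rsndr] pipeline complete in %.1f s; manifest at %s",
                  manifest$elapsed_seconds, mpath))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Union of the atrophy spheres planted in a simulated cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return A [brain_mask()] of all planted atrophy spheres, or `NULL` when
#'   the cohort has none.
#' @export
truth_atrophy_mask <- function(cohort) {
  if (is.null(cohort)) return(NULL)
  effects <- cohort$truth$effects
  grid <- cohort$config$grid
  acc <- array(FALSE, grid)
  found <- FALSE
  for (ef in effects) {
    at <- ef$atrophy
    if (is.null(at)) next
    if (is.null(at$center)) at$center <- cohort$atlas$centers[ef$network, ]
    acc <- acc | sphere_mask(grid, at$center, at$radius)$data
    found <- TRUE
  }
  if (!found) return(NULL)
  brain_mask(acc, affine = cohort$mask$affine)
}

validate_run_config <- function(cfg) {
  problems <- character(0)
  if (is.null(cfg$simulate)) problems <- c(problems, "missing 'simulate' block (or simulate$data paths)")
  if (!is.null(cfg$ica) && is.null(cfg$ica$order) && !isTRUE(cfg$ica$template == "truth")) {
    problems <- c(problems, "ica block needs 'order' (or template: truth)")
  }
  if (is.null(cfg$ica)) problems <- c(problems, "missing 'ica' block")
  np <- cfg$infer$n_perm %||% 5000
  if (np < 100) problems <- c(problems, "infer$n_perm must be >= 100")
  al <- cfg$infer$alpha %||% 0.05
  if (al <= 0 || al >= 1) problems <- c(problems, "infer$alpha must be in (0,1)")
  if (length(problems)) {
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  cfg
}
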