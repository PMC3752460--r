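#' Stage A: subject time courses from group template maps
#'
#' One multiple regression per time point: the subject's voxel pattern at
#' time t is regressed on all template maps simultaneously (maps demeaned
#' over the mask), yielding a T x C time-course matrix.
#'
#' @param subject a [volume4d()] on the mask's grid.
#' @param template a `spatial_map_set` (the group-ICA or truth-atlas maps).
#' @param mask a [brain_mask()].
#' @return Object of class `timecourse_matrix`: `values` (T x C), `labels`.
#' @export
stage_a_timecourses <- function(subject, template, mask) {
  stop_if_grid_mismatch(subject, mask, "subject and mask")
  Y <- mask_to_matrix(subject, mask)$mats[[1]]      # T x V
  G <- t(template$zmaps)                            # V x C
  G <- sweep(G, 2, colMeans(G))
  qrG <- qr(G)
  if (qrG$rank < ncol(G)) {
    cors <- abs(stats::cor(G))
    diag(cors) <- 0
    worst <- sort(arrayInd(which.max(cors), dim(cors)))
    stop(sprintf("template maps are rank deficient (rank %d < %d); most collinear pair: components %d and %d (|r| = %.3f)",
                 qrG$rank, ncol(G), worst[1], worst[2], max(cors)))
  }
  A <- t(qr.coef(qrG, t(Y)))                        # T x C
  structure(list(values = unname(A), labels = template$labels),
            class = "timecourse_matrix")
}

#' Stage B: subject spatial maps from stage-A time courses
#'
#' Each voxel's time series (demeaned over time) is regressed on the stage-A
#' time-course columns (demeaned; and, when `des_norm` is TRUE, scaled to
#' unit standard deviation so that the resulting betas carry amplitude as
#' well as shape information). Zero-variance time-course columns produce
#' all-zero betas and are flagged.
#'
#' @param subject a [volume4d()].
#' @param tcs a `timecourse_matrix` from [stage_a_timecourses()].
#' @param des_norm logical; variance-normalize the design columns.
#' @param mask a [brain_mask()].
#' @return Object of class `subject_maps`: `betas` (C x V), `labels`,
#'   `des_norm`, `zero_variance` flags.
#' @export
stage_b_maps <- function(subject, tcs, des_norm = TRUE, mask) {
  A <- tcs$values
  stopifnot(nrow(A) == dim(subject$data)[4])
  Y <- mask_to_matrix(subject, mask)$mats[[1]]      # T x V
  Y <- sweep(Y, 2, colMeans(Y))
  X <- sweep(A, 2, colMeans(A))
  s <- sqrt(colSums(X^2) / (nrow(X) - 1))
  zero <- s < 1e-12
  if (des_norm) {
    sc <- ifelse(zero, 1, s)
    X <- sweep(X, 2, sc, "/")
  }
  X[, zero] <- 0
  Xok <- X[, !zero, drop = FALSE]
  B <- matrix(0, ncol(A), ncol(Y))
  if (ncol(Xok) > 0) {
    B[!zero, ] <- qr.coef(qr(Xok), Y)
  }
  B[!is.finite(B)] <- 0
  structure(list(betas = unname(B), labels = tcs$labels,
                 des_norm = des_norm, zero_variance = zero),
            class = "subject_maps")
}

#' Two-stage dual regression over a cohort
#'
#' Applies [stage_a_timecourses()] then [stage_b_maps()] independently to each
#' subject; there is no cross-subject coupling, so output order follows input
#' order and duplicated inputs give identical outputs.
#'
#' @param subjects list of [volume4d()], or a [design_table()] whose
#'   `bold_path`s are loaded on demand.
#' @param template a `spatial_map_set`.
#' @param des_norm logical; see [stage_b_maps()].
#' @param mask a [brain_mask()].
#' @return Object of class `dualreg_result`: `timecourses` and `maps` (lists,
#'   one entry per subject), `labels`, `des_norm`.
#' @export
dual_regression <- function(subjects, template, des_norm = TRUE, mask) {
  paths <- NULL
  if (inherits(subjects, "design_table")) {
    paths <- subjects$bold_path
    subjects <- NULL
  }
  n <- if (is.null(paths)) length(subjects) else length(paths)
  tcs_list <- vector("list", n)
  maps_list <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    sub <- if (is.null(paths)) subjects[[i]] else read_volume4d(paths[i])
    res <- tryCatch({
      tc <- stage_a_timecourses(sub, template, mask)
      mp <- stage_b_maps(sub, tc, des_norm = des_norm, mask = mask)
      list(tc = tc, mp = mp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("subject %d: %s", i, conditionMessage(res)))
    } else {
      tcs_list[[i]] <- res$tc
      maps_list[[i]] <- res$mp
    }
  }
  if (length(failures)) {
    stop("dual regression failed for ", length(failures), " subject(s):\n  - ",
         paste(failures, collapse = "\n  - "))
  }
  structure(list(timecourses = tcs_list, maps = maps_list,
                 labels = template$labels, des_norm = des_norm),
            class = "dualreg_result")
}

#' Stack stage-B maps into per-component subject-by-voxel blocks
#'
#' @param dr a `dualreg_result`.
#' @return Named list of subjects x voxel matrices, one per component label.
#' @export
dualreg_blocks <- function(dr) {
  stopifnot(inherits(dr, "dualreg_result"))
  C <- length(dr$labels)
  out <- vector("list", C)
  for (c in seq_len(C)) {
    out[[c]] <- do.call(rbind, lapply(dr$maps, function(m) m$betas[c, ]))
  }
  names(out) <- as.character(dr$labels)
  out
}
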