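#' Difference-map statistics for one component
#'
#' The per-component summary reported for significant group-difference maps:
#' number of surviving voxels, the voxel coordinates of the peak t value, and
#' min/max/mean/std of t within the significant mask. The standard deviation
#' is the population form (divide by n), so a single-voxel region reports
#' std 0.
#'
#' @param tmap 3D t-statistic array.
#' @param sigmask 3D logical array of significant voxels (same grid).
#' @param ic_label component label for the output row.
#' @return One-row `data.frame` with columns `ic`, `n_voxels`, `max_x`,
#'   `max_y`, `max_z` (0-based voxel indices of the peak), `t_min`, `t_max`,
#'   `t_mean`, `t_std`; location and t columns are `NA` when the mask is
#'   empty.
#' @export
difference_map_stats <- function(tmap, sigmask, ic_label) {
  stopifnot(all(dim(tmap) == dim(sigmask)))
  sigmask <- sigmask > 0
  n <- sum(sigmask)
  if (n == 0L) {
    return(data.frame(ic = ic_label, n_voxels = 0L,
                      max_x = NA_integer_, max_y = NA_integer_, max_z = NA_integer_,
                      t_min = NA_real_, t_max = NA_real_,
                      t_mean = NA_real_, t_std = NA_real_))
  }
  vals <- tmap[sigmask]
  idx <- which(sigmask)
  peak <- arrayInd(idx[which.max(vals)], dim(tmap))
  data.frame(ic = ic_label, n_voxels = n,
             max_x = peak[1] - 1L, max_y = peak[2] - 1L, max_z = peak[3] - 1L,
             t_min = min(vals), t_max = max(vals), t_mean = mean(vals),
             t_std = sqrt(mean((vals - mean(vals))^2)))
}

#' Difference-map table over all components of a result
#'
#' @param result a `permutation_result`.
#' @param alpha significance threshold (strict; defaults to the stored one).
#' @param keep_empty keep rows for components with no significant voxels.
#' @return `data.frame` with one row per component, [difference_map_stats()]
#'   columns.
#' @export
difference_map_table <- function(result, alpha = result$alpha, keep_empty = FALSE) {
  vols <- split_blocks(result, alpha = alpha)
  rows <- lapply(names(vols), function(lbl) {
    difference_map_stats(vols[[lbl]]$t, vols[[lbl]]$sig, lbl)
  })
  out <- do.call(rbind, rows)
  if (!keep_empty) out <- out[out$n_voxels > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjacency of significant voxels to an atrophy region
#'
#' Characterizes whether significant connectivity changes sit inside or
#' around an atrophic area: the fraction of significant voxels overlapping
#' the atrophy mask, and for each distance `d` the fraction within `d` voxels
#' (Euclidean, voxel units) of the atrophy mask. `near_fraction` is monotone
#' non-decreasing in `d` by construction.
#'
#' @param sigmask 3D logical array of significant voxels.
#' @param atrophy_mask 3D logical array (non-empty) of atrophic voxels.
#' @param d_list distances in voxels at which to evaluate the near fraction.
#' @return Object of class `adjacency_report`: `overlap_fraction`,
#'   `near_fraction` (named by distance), `d_list`, `n_sig`.
#' @export
atrophy_adjacency <- function(sigmask, atrophy_mask, d_list = c(0, 1, 2, 3, 5)) {
  stopifnot(all(dim(sigmask) == dim(atrophy_mask)))
  sigmask <- sigmask > 0
  atrophy_mask <- atrophy_mask > 0
  if (!any(atrophy_mask)) stop("atrophy mask is empty")
  n_sig <- sum(sigmask)
  if (n_sig == 0L) {
    nf <- rep(NA_real_, length(d_list))
    names(nf) <- as.character(d_list)
    return(structure(list(overlap_fraction = NA_real_, near_fraction = nf,
                          d_list = d_list, n_sig = 0L),
                     class = "adjacency_report"))
  }
  sc <- arrayInd(which(sigmask), dim(sigmask))
  ac <- arrayInd(which(atrophy_mask), dim(atrophy_mask))
  # distance of each significant voxel to the nearest atrophy voxel
  dmin <- vapply(seq_len(nrow(sc)), function(i) {
    sqrt(min(colSums((t(ac) - sc[i, ])^2)))
  }, 1.0)
  nf <- vapply(d_list, function(d) mean(dmin <= d), 1.0)
  names(nf) <- as.character(d_list)
  structure(list(overlap_fraction = mean(sigmask & atrophy_mask) * prod(dim(sigmask)) / n_sig,
                 near_fraction = nf, d_list = d_list, n_sig = n_sig),
            class = "adjacency_report")
}

#' @export
print.adjacency_report <- function(x, ...) {
  cat(sprintf("<adjacency_report> %d significant voxels; overlap %.3f\n",
              x$n_sig, x$overlap_fraction))
  cat("  near fraction:",
      paste(sprintf("d<=%s: %.3f", names(x$near_fraction), x$near_fraction),
            collapse = ", "), "\n")
  invisible(x)
}
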