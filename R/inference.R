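#' TFCE parameters
#'
#' Standard threshold-free cluster enhancement settings: height exponent
#' H = 2, extent exponent E = 0.5, 100 integration steps (step size
#' `max(stat)/n_steps`), 26-connectivity.
#'
#' @param H height exponent (>= 0).
#' @param E extent exponent (>= 0).
#' @param n_steps number of integration steps (>= 10).
#' @param connectivity neighbourhood: 6, 18 or 26.
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 0.5, n_steps = 100, connectivity = 26) {
  stopifnot(H >= 0, E >= 0, n_steps >= 10, connectivity %in% c(6, 18, 26))
  structure(list(H = H, E = E, n_steps = n_steps,
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel, integrates `extent(h)^E * h^H dh` over thresholds
#' `h = dh, 2dh, ..., max(stat)`, where `extent(h)` is the size of the
#' supra-threshold connected component containing the voxel. Positive values
#' are enhanced; with `both_signs = TRUE` the negated map is enhanced
#' separately and subtracted, so negative statistics get negative enhanced
#' values.
#'
#' @param stat 3D numeric array (finite values).
#' @param params a [tfce_params()].
#' @param both_signs enhance the negative tail too.
#' @return 3D array of enhanced values, same shape as `stat`.
#' @export
tfce <- function(stat, params = tfce_params(), both_signs = FALSE) {
  stopifnot(length(dim(stat)) == 3L, all(is.finite(stat)))
  pos <- tfce_enhance_cpp(as.numeric(stat), dim(stat), params$H, params$E,
                          params$n_steps, params$connectivity)
  out <- array(pos, dim = dim(stat))
  if (both_signs) {
    neg <- tfce_enhance_cpp(as.numeric(-stat), dim(stat), params$H, params$E,
                            params$n_steps, params$connectivity)
    out <- out - array(neg, dim = dim(stat))
  }
  out
}

#' Concatenate per-component blocks into a joint dataset
#'
#' The statistical analogue of stacking the per-component 4D files in the
#' y-direction: blocks share the subject axis and are tested jointly, so a
#' single max-statistic null corrects across components as well as voxels.
#' Blocks are joined statistically, not geometrically — clusters can never
#' bridge two components.
#'
#' @param blocks named list of subjects x voxel matrices (one per component),
#'   e.g. from [dualreg_blocks()].
#' @param groups character vector (`"patient"` / `"control"`), one per
#'   subject, or a [design_table()].
#' @param mask the [brain_mask()] the voxel axis refers to.
#' @param covariate optional subjects x voxel matrix (e.g. gray-matter
#'   density at each voxel), shared across blocks, or a list matching
#'   `blocks` block-for-block.
#' @return Object of class `concat_dataset`.
#' @export
yconcat <- function(blocks, groups, mask, covariate = NULL) {
  if (inherits(groups, "design_table")) groups <- groups$group
  if (is.null(names(blocks))) names(blocks) <- as.character(seq_along(blocks))
  n <- unique(vapply(blocks, nrow, 1L))
  if (length(n) != 1L) stop("all blocks must share the subject axis")
  if (length(groups) != n) stop("groups length must equal the subject axis")
  if (!all(groups %in% c("patient", "control"))) {
    stop("groups must be 'patient' or 'control'")
  }
  nv <- sum(mask$data)
  if (!all(vapply(blocks, ncol, 1L) == nv)) {
    stop("block voxel axis must match the mask")
  }
  if (!is.null(covariate)) {
    if (is.list(covariate)) {
      stopifnot(length(covariate) == length(blocks),
                all(vapply(covariate, nrow, 1L) == n),
                all(vapply(covariate, ncol, 1L) == nv))
    } else {
      stopifnot(nrow(covariate) == n, ncol(covariate) == nv)
      covariate <- rep(list(covariate), length(blocks))
      names(covariate) <- names(blocks)
    }
  }
  structure(list(blocks = blocks, covariate_blocks = covariate,
                 groups = groups, mask = mask),
            class = "concat_dataset")
}

#' @export
print.concat_dataset <- function(x, ...) {
  cat(sprintf("<concat_dataset> %d block(s) x %d voxels, %d patients + %d controls%s\n",
              length(x$blocks), ncol(x$blocks[[1]]),
              sum(x$groups == "patient"), sum(x$groups == "control"),
              if (is.null(x$covariate_blocks)) "" else ", with voxel-wise covariate"))
  invisible(x)
}

#' Two-sample voxel-wise t-map
#'
#' Pooled-variance two-sample t per voxel; with a voxel-wise covariate the
#' statistic is the group coefficient's t in the per-voxel regression of the
#' data on intercept, group and covariate. Voxels with zero residual variance
#' get t = 0.
#'
#' @param block subjects x voxel matrix.
#' @param groups character vector (`"patient"` / `"control"`) or
#'   [design_table()].
#' @param covariate optional subjects x voxel matrix.
#' @param direction `"patient>control"` (positive t means patients higher) or
#'   `"control>patient"`.
#' @return Numeric vector of t values, one per voxel.
#' @export
two_sample_tmap <- function(block, groups, covariate = NULL,
                            direction = c("patient>control", "control>patient")) {
  direction <- match.arg(direction)
  if (inherits(groups, "design_table")) groups <- groups$group
  g <- as.numeric(groups == "patient")
  if (sum(g) < 2 || sum(1 - g) < 2) stop("need at least 2 subjects per group")
  t <- if (is.null(covariate)) {
    drop(tmaps_by_label(block, matrix(g, nrow = 1)))
  } else {
    fl <- fl_precompute(block, covariate, g)
    drop(tmap_with_covariate(sweep(block, 2, colMeans(block)), fl))
  }
  if (direction == "control>patient") t <- -t
  t
}

# t-maps for many label arrangements at once (no covariate).
# X: n x V data; G: m x n matrix of 0/1 patient indicators (one row per
# arrangement). Returns m x V matrix of pooled-variance t values.
tmaps_by_label <- function(X, G) {
  n <- nrow(X)
  n1 <- rowSums(G)
  n2 <- n - n1
  X2 <- X^2
  S <- colSums(X)
  Ssq <- colSums(X2)
  S1 <- G %*% X
  S1sq <- G %*% X2
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2, S, "+") / n2
  ss1 <- S1sq - S1^2 / n1
  ss2 <- sweep(-S1sq, 2, Ssq, "+") - sweep(-S1, 2, S, "+")^2 / n2
  sp2 <- (ss1 + ss2) / (n - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[!is.finite(t) | se < 1e-12] <- 0
  t
}

# Precompute the Freedman-Lane pieces for a voxel-wise covariate:
# residualize the data on [1, covariate_v] per voxel; permuting these
# residuals and refitting the full model gives the null stream.
fl_precompute <- function(X, Z, g) {
  n <- nrow(X)
  Zc <- sweep(Z, 2, colMeans(Z))
  Szz <- colSums(Zc^2)
  gc <- g - mean(g)
  Sgg <- sum(gc^2)
  Sgz <- colSums(gc * Zc)
  det <- Sgg * Szz - Sgz^2
  Xc <- sweep(X, 2, colMeans(X))
  bz <- colSums(Zc * Xc) / pmax(Szz, 1e-300)
  E <- Xc - sweep(Zc, 2, bz, "*")          # residuals of X on [1, z_v]
  list(n = n, Zc = Zc, Szz = Szz, gc = gc, Sgg = Sgg, Sgz = Sgz, det = det,
       E = E, Syy_perm = colSums(E^2))
}

# Full-model group t given (possibly permuted) centred data Yc and the
# precomputed design sums. Closed-form per-voxel regression on
# [1, group, covariate_v].
tmap_with_covariate <- function(Yc, fl, Syy = NULL) {
  if (is.null(Syy)) Syy <- colSums(Yc^2)
  Sgy <- drop(crossprod(fl$gc, Yc))
  Szy <- colSums(fl$Zc * Yc)
  det <- fl$det
  ok <- det > 1e-10 * pmax(fl$Sgg * fl$Szz, 1e-300)
  b1 <- (fl$Szz * Sgy - fl$Sgz * Szy) / det
  b2 <- (fl$Sgg * Szy - fl$Sgz * Sgy) / det
  rss <- pmax(Syy - b1 * Sgy - b2 * Szy, 0)
  sigma2 <- rss / (fl$n - 3)
  varb <- sigma2 * fl$Szz / det
  t <- b1 / sqrt(varb)
  t[!ok | !is.finite(t) | varb < 1e-24] <- 0
  matrix(t, nrow = 1)
}

#' Joint max-statistic permutation test with TFCE
#'
#' Computes the observed group-difference t-map and its TFCE enhancement for
#' every block, then builds a single null distribution from the maximum TFCE
#' value across all blocks and voxels under permutation of the group labels
#' (Freedman-Lane residual permutation when a voxel-wise covariate is
#' present). Corrected `p(v) = (1 + #\{null_max >= tfce(v)\}) / (1 + n_perm)`,
#' so p is never 0 and correction is family-wise across components and
#' voxels jointly. When the number of distinct label arrangements is at most
#' `n_perm` (and there is no covariate), the null is enumerated exhaustively.
#'
#' @param data a [yconcat()] dataset.
#' @param n_perm number of permutations (default 5000; a warning is issued
#'   below 1000 and an error below 100).
#' @param seed RNG seed for the permutation stream.
#' @param params a [tfce_params()].
#' @param direction one-sided contrast direction.
#' @param alpha significance threshold applied by [split_blocks()]
#'   (default 0.05; strict inequality).
#' @param exhaustive `"auto"` (enumerate when feasible), `"never"`, or
#'   `"always"` (error if infeasible).
#' @return Object of class `permutation_result`: per-block `t`, `tfce`, `p`
#'   vectors over masked voxels, the shared `null_max` distribution, `n_perm`,
#'   `seed`, `direction`, `alpha`, `params`, `mask`, `exhaustive` flag.
#' @export
permutation_test <- function(data, n_perm = 5000, seed = 1L,
                             params = tfce_params(),
                             direction = c("patient>control", "control>patient"),
                             alpha = 0.05, exhaustive = c("auto", "never", "always")) {
  stopifnot(inherits(data, "concat_dataset"))
  direction <- match.arg(direction)
  exhaustive <- match.arg(exhaustive)
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (n_perm < 1000) warning("n_perm below 1000 gives a coarse null; consider 5000")
  g <- as.numeric(data$groups == "patient")
  n <- length(g)
  n1 <- sum(g)
  if (n1 < 1 || n - n1 < 1) stop("degenerate design: one group is empty")
  has_cov <- !is.null(data$covariate_blocks)
  n_arr <- choose(n, n1)
  use_exhaustive <- switch(exhaustive,
    auto = !has_cov && n_arr <= n_perm,
    never = FALSE,
    always = {
      if (has_cov) stop("exhaustive enumeration is not available with a covariate")
      if (n_arr > n_perm) stop(sprintf("exhaustive enumeration needs %d arrangements > n_perm", n_arr))
      TRUE
    })
  blocks <- data$blocks
  B <- length(blocks)
  mask <- data$mask
  dims <- dim(mask$data)
  vox <- which(mask$data)
  sgn <- if (direction == "control>patient") -1 else 1

  enhance <- function(tvec) {
    vol <- array(0, dims)
    vol[vox] <- tvec
    as.numeric(tfce(vol, params))[vox]
  }

  obs_t <- vector("list", B)
  obs_tfce <- vector("list", B)
  if (use_exhaustive) {
    sets <- combn(n, n1)
    G <- matrix(0, ncol(sets), n)
    for (i in seq_len(ncol(sets))) G[i, sets[, i]] <- 1
    null_max <- rep(-Inf, nrow(G))
    for (b in seq_len(B)) {
      tm <- sgn * tmaps_by_label(blocks[[b]], G)
      obs_row <- which(apply(G, 1, function(r) all(r == g)))[1]
      obs_t[[b]] <- tm[obs_row, ]
      for (i in seq_len(nrow(G))) {
        e <- enhance(tm[i, ])
        if (i == obs_row) obs_tfce[[b]] <- e
        null_max[i] <- max(null_max[i], max(e), 0)
      }
    }
    p <- lapply(seq_len(B), function(b) {
      vapply(obs_tfce[[b]], function(v) mean(null_max >= v), 1.0)
    })
    n_perm_eff <- nrow(G)
  } else {
    null_max <- rep(-Inf, n_perm)
    perms <- with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
    for (b in seq_len(B)) {
      X <- blocks[[b]]
      if (!has_cov) {
        Gmat <- rbind(g, t(vapply(perms, function(p) g[p], numeric(n))))
        tm <- sgn * tmaps_by_label(X, Gmat)
        obs_t[[b]] <- tm[1, ]
        obs_tfce[[b]] <- enhance(tm[1, ])
        for (i in seq_len(n_perm)) {
          null_max[i] <- max(null_max[i], max(enhance(tm[i + 1, ])), 0)
        }
      } else {
        fl <- fl_precompute(X, data$covariate_blocks[[b]], g)
        Xc <- sweep(X, 2, colMeans(X))
        t_obs <- sgn * drop(tmap_with_covariate(Xc, fl))
        obs_t[[b]] <- t_obs
        obs_tfce[[b]] <- enhance(t_obs)
        for (i in seq_len(n_perm)) {
          Yp <- fl$E[perms[[i]], , drop = FALSE]
          tp <- sgn * drop(tmap_with_covariate(Yp, fl, Syy = fl$Syy_perm))
          null_max[i] <- max(null_max[i], max(enhance(tp)), 0)
        }
      }
    }
    p <- lapply(seq_len(B), function(b) {
      vapply(obs_tfce[[b]], function(v) (1 + sum(null_max >= v)) / (1 + n_perm), 1.0)
    })
    n_perm_eff <- n_perm
  }
  res_blocks <- lapply(seq_len(B), function(b) {
    list(t = obs_t[[b]], tfce = obs_tfce[[b]], p = p[[b]])
  })
  names(res_blocks) <- names(blocks)
  structure(list(blocks = res_blocks, null_max = null_max,
                 n_perm = n_perm_eff, seed = seed, direction = direction,
                 alpha = alpha, params = params, mask = mask,
                 exhaustive = use_exhaustive, covariate = has_cov),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  nsig <- vapply(x$blocks, function(b) sum(b$p < x$alpha), 1L)
  cat(sprintf("<permutation_result> %d block(s), %s null draws (%s), direction %s\n",
              length(x$blocks), x$n_perm,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$direction))
  cat(sprintf("  significant voxels at alpha %.3g per block: %s\n",
              x$alpha, paste(nsig, collapse = ", ")))
  invisible(x)
}

#' Single-map permutation test
#'
#' The voxel-level-only correction: identical to [permutation_test()] on a
#' dataset holding one block, so its null maximum ranges over one component's
#' voxels only and is therefore less conservative than the joint correction.
#'
#' @param block subjects x voxel matrix.
#' @param groups,mask,covariate see [yconcat()].
#' @param ... passed to [permutation_test()].
#' @return A `permutation_result` with one block.
#' @export
per_map_test <- function(block, groups, mask, covariate = NULL, ...) {
  if (is.matrix(block)) block <- list(map = block)
  permutation_test(yconcat(block, groups, mask, covariate = covariate), ...)
}

#' Split a joint result back into per-component volumes
#'
#' Restores each block's t, TFCE and corrected-p maps to the 3D grid and
#' thresholds at `alpha` (strict inequality: voxels with p exactly equal to
#' alpha are not significant).
#'
#' @param result a `permutation_result`.
#' @param alpha threshold; defaults to the one stored in the result.
#' @return Named list, one entry per block, each with 3D arrays `t`, `tfce`,
#'   `p` (1 outside the mask) and logical `sig`.
#' @export
split_blocks <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "permutation_result"))
  mask <- result$mask
  lapply(result$blocks, function(b) {
    list(t = unmask(b$t, mask),
         tfce = unmask(b$tfce, mask),
         p = unmask(b$p, mask, fill = 1),
         sig = unmask(b$p < alpha, mask) > 0)
  })
}

#' Count components with any significant voxel
#'
#' @param result a `permutation_result`.
#' @param alpha threshold; defaults to the stored one.
#' @return Integer count of blocks containing at least one voxel with
#'   corrected p below alpha.
#' @export
n_significant_ics <- function(result, alpha = result$alpha) {
  sum(vapply(result$blocks, function(b) any(b$p < alpha), logical(1)))
}
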