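#' Variance-normalize a time-by-voxel matrix
#'
#' Each voxel column is demeaned and scaled to unit variance. Zero-variance
#' columns are set to all-zero and flagged in the `"zero_variance"` attribute.
#' Idempotent.
#'
#' @param mat T x V numeric matrix (T >= 2).
#' @return Normalized matrix with a logical `"zero_variance"` attribute.
#' @export
variance_normalize <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  mu <- colMeans(mat)
  ctr <- sweep(mat, 2, mu)
  s <- sqrt(colSums(ctr^2) / (nrow(mat) - 1))
  zero <- s < 1e-12
  s[zero] <- 1
  out <- sweep(ctr, 2, s, "/")
  out[, zero] <- 0
  attr(out, "zero_variance") <- zero
  out
}

# Symmetric fixed-point ICA with tanh contrast on whitened data Z (C x V,
# rows uncorrelated, unit variance over voxels). Returns the orthogonal
# unmixing matrix W such that S = W Z.
fastica_symm <- function(Z, seed, max_iter = 1000L, tol = 1e-6,
                         restarts = 5L) {
  C <- nrow(Z)
  V <- ncol(Z)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), C) %*% t(e$vectors) %*% W
  }
  last_delta <- NA_real_
  for (attempt in seq_len(restarts)) {
    W <- with_seed(if (attempt == 1L) seed else derive_seed(seed, attempt),
                   matrix(rnorm(C * C), C, C))
    W <- sym_decorrelate(W)
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      G <- tanh(WZ)
      gprime <- rowMeans(1 - G^2)
      W_new <- (G %*% t(Z)) / V - diag(gprime, C) %*% W
      W_new <- sym_decorrelate(W_new)
      last_delta <- 1 - min(abs(diag(W_new %*% t(W))))
      W <- W_new
      if (last_delta < tol) {
        attr(W, "iterations") <- it
        attr(W, "converged") <- TRUE
        return(W)
      }
    }
  }
  stop(sprintf("ICA did not converge within %d iterations over %d restarts (last delta %.3g)",
               max_iter, restarts, last_delta))
}

#' Temporal-concatenation group spatial ICA
#'
#' Per-subject variance normalization, temporal concatenation across subjects,
#' dimensionality reduction to `order` by economy SVD, then fixed-point
#' spatial ICA (tanh contrast, symmetric decorrelation). Component maps are
#' z-scored over the mask (zero mean, unit variance) and sign-flipped so each
#' map's spatial skewness is positive.
#'
#' @param subjects list of [volume4d()] on the mask's grid (typically the
#'   control group, which gives template maps free of patient alterations).
#' @param mask a [brain_mask()].
#' @param order number of components C (<= min(total timepoints, voxels)).
#' @param seed RNG seed for the ICA initialization; stored in the result and
#'   sufficient to reproduce the maps bit-identically.
#' @param max_iter,tol fixed-point iteration controls.
#' @return Object of class `spatial_map_set`: `zmaps` (C x V matrix over
#'   masked voxels), `group_timecourses` (sum(T) x C), `labels` (component
#'   labels), `mask`, `order`, `seed`.
#' @export
run_group_ica <- function(subjects, mask, order, seed = 1L,
                          max_iter = 1000L, tol = 1e-6) {
  mm <- mask_to_matrix(subjects, mask)
  X <- do.call(rbind, lapply(mm$mats, variance_normalize))
  V <- ncol(X)
  if (order > min(nrow(X), V)) {
    stop(sprintf("order %d exceeds min(total timepoints %d, voxels %d)",
                 order, nrow(X), V))
  }
  sv <- svd(X, nu = order, nv = order)
  Z <- sqrt(V) * t(sv$v[, seq_len(order), drop = FALSE])   # whitened spatial data
  W <- fastica_symm(Z, seed = seed, max_iter = max_iter, tol = tol)
  S <- W %*% Z                                             # C x V spatial sources
  A <- X %*% t(S) %*% solve(S %*% t(S))                    # sum(T) x C time courses
  zmaps <- row_zscore(S)                                   # zero mean, unit var per map
  skew <- rowMeans(zmaps^3)
  flip <- ifelse(skew < 0, -1, 1)
  zmaps <- zmaps * flip
  A <- sweep(A, 2, flip, "*")
  structure(list(zmaps = unname(zmaps), group_timecourses = A,
                 labels = seq_len(order), mask = mask, order = order,
                 seed = seed,
                 ica_iterations = attr(W, "iterations")),
            class = "spatial_map_set")
}

#' @export
print.spatial_map_set <- function(x, ...) {
  cat(sprintf("<spatial_map_set> %d component map(s) over %d masked voxels (labels %s)\n",
              nrow(x$zmaps), ncol(x$zmaps),
              paste(utils::head(x$labels, 8), collapse = ",")))
  invisible(x)
}

#' Build a template map set from known spatial maps
#'
#' Wraps externally known maps (e.g. a ground-truth atlas) in the same
#' container [run_group_ica()] produces, z-scored over the mask, so they can
#' be used directly as a dual-regression template.
#'
#' @param maps a `network_atlas` or an n x V_grid / n x V_mask numeric matrix.
#' @param mask a [brain_mask()].
#' @return A `spatial_map_set`.
#' @export
as_template <- function(maps, mask) {
  if (inherits(maps, "network_atlas")) maps <- maps$maps
  idx <- which(mask$data)
  m <- if (ncol(maps) == prod(dim(mask$data))) maps[, idx, drop = FALSE] else maps
  stopifnot(ncol(m) == length(idx))
  z <- row_zscore(m)
  structure(list(zmaps = unname(z), group_timecourses = NULL,
                 labels = seq_len(nrow(m)), mask = mask, order = nrow(m),
                 seed = NA_integer_),
            class = "spatial_map_set")
}

# Demean and scale each row to unit (n-1) variance.
row_zscore <- function(m) {
  ctr <- m - rowMeans(m)
  s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1))
  unname(ctr / ifelse(s < 1e-12, 1, s))
}

# Weighted gamma maximum-likelihood M-step: shape via Newton iterations on
# log(k) - digamma(k) = log(wmean(x)) - wmean(log x); shape constrained >= 1
# so the density stays bounded at the offset.
gamma_mle_weighted <- function(x, w) {
  wsum <- sum(w)
  m <- sum(w * x) / wsum
  mlog <- sum(w * log(x)) / wsum
  s <- log(m) - mlog
  if (!is.finite(s) || s <= 0) return(list(shape = 1, scale = max(m, 1e-8)))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:8) {
    num <- log(k) - digamma(k) - s
    den <- 1 / k - trigamma(k)
    k_new <- k - num / den
    if (!is.finite(k_new) || k_new <= 0) break
    k <- k_new
  }
  k <- max(k, 1)
  list(shape = k, scale = m / k)
}

#' Gaussian/gamma mixture-model thresholding of a component z-map
#'
#' Fits a three-component mixture to the voxel intensity distribution of a
#' z-scored spatial map — a Gaussian null plus a positive gamma (activation)
#' and a mirrored negative gamma (deactivation), both offset at the initial
#' robust null-mean estimate — by expectation-maximization. A voxel survives
#' when its local false-discovery rate (the posterior probability of the null
#' component) is below `local_fdr_cut`.
#'
#' @param z numeric vector of map values (>= 1000 voxels recommended for a
#'   stable fit).
#' @param local_fdr_cut keep voxels with posterior null probability below
#'   this value (default 0.5).
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return List with `fit` (class `mixture_fit`: weights, null mean/sd, gamma
#'   shape/scale/offset per tail, `converged`, `loglik` trace) and `keep`
#'   (logical vector marking surviving voxels).
#' @export
fit_mixture_threshold <- function(z, local_fdr_cut = 0.5,
                                  max_iter = 500L, tol = 1e-8) {
  z <- as.numeric(z)
  n <- length(z)
  if (n < 1000) warning("fewer than 1000 voxels; mixture fit may be unstable")
  mu0 <- median(z)
  s0 <- max(stats::IQR(z) / 1.349, 1e-3)
  off_pos <- mu0
  off_neg <- mu0
  tail_p <- mean(z > mu0 + 2.5 * s0)
  tail_n <- mean(z < mu0 - 2.5 * s0)
  w <- c(null = 1 - 2 * (tail_p + tail_n), pos = 2 * tail_p, neg = 2 * tail_n)
  w <- pmax(w, 1e-4); w <- w / sum(w)
  init_gamma <- function(x) {
    x <- x[x > 0.05]
    if (length(x) < 10) return(list(shape = 3, scale = 1))
    m <- mean(x); v <- var(x)
    if (!is.finite(v) || v <= 0) return(list(shape = 3, scale = 1))
    list(shape = max(m^2 / v, 1), scale = max(v / m, 1e-3))
  }
  gp <- init_gamma(z[z > mu0 + 2 * s0] - off_pos)
  gn <- init_gamma(off_neg - z[z < mu0 - 2 * s0])
  mu <- mu0; sg <- s0
  dens <- function() {
    f0 <- dnorm(z, mu, sg)
    fp <- ifelse(z > off_pos, dgamma(pmax(z - off_pos, 1e-300), gp$shape, scale = gp$scale), 0)
    fn <- ifelse(z < off_neg, dgamma(pmax(off_neg - z, 1e-300), gn$shape, scale = gn$scale), 0)
    cbind(w[1] * f0, w[2] * fp, w[3] * fn)
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- dens()
    tot <- rowSums(d) + 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <= tol * abs(ll_trace[it - 1])) {
      converged <- TRUE
      break
    }
    r <- d / tot
    w <- pmax(colMeans(r), 0)
    w <- w / sum(w)
    mu <- sum(r[, 1] * z) / sum(r[, 1])
    sg <- sqrt(sum(r[, 1] * (z - mu)^2) / sum(r[, 1]))
    sg <- max(sg, 1e-4)
    if (sum(r[, 2]) > 1e-6) {
      sel <- z > off_pos
      gp <- gamma_mle_weighted(z[sel] - off_pos + 1e-12, r[sel, 2])
    }
    if (sum(r[, 3]) > 1e-6) {
      sel <- z < off_neg
      gn <- gamma_mle_weighted(off_neg - z[sel] + 1e-12, r[sel, 3])
    }
  }
  d <- dens()
  post_null <- d[, 1] / (rowSums(d) + 1e-300)
  keep <- post_null < local_fdr_cut
  fit <- structure(list(weight_null = w[[1]], weight_pos = w[[2]],
                        weight_neg = w[[3]], null_mean = mu, null_sd = sg,
                        pos_shape = gp$shape, pos_scale = gp$scale,
                        pos_offset = off_pos,
                        neg_shape = gn$shape, neg_scale = gn$scale,
                        neg_offset = off_neg,
                        converged = converged, loglik = ll_trace),
                   class = "mixture_fit")
  list(fit = fit, keep = keep)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> weights null/pos/neg = %.3f/%.3f/%.3f, null N(%.3f, %.3f); %s\n",
              x$weight_null, x$weight_pos, x$weight_neg, x$null_mean, x$null_sd,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Greedy maximum-|correlation| one-to-one assignment of recovered maps to
# reference maps; returns for each reference row the matched map row, the
# signed correlation and |correlation|.
match_components <- function(maps, reference) {
  cors <- stats::cor(t(reference), t(maps))      # n_ref x n_maps
  a <- abs(cors)
  n_ref <- nrow(a)
  match <- integer(n_ref)
  rho <- numeric(n_ref)
  avail_r <- rep(TRUE, n_ref)
  avail_c <- rep(TRUE, ncol(a))
  for (i in seq_len(min(n_ref, ncol(a)))) {
    sub <- a
    sub[!avail_r, ] <- -Inf
    sub[, !avail_c] <- -Inf
    best <- arrayInd(which.max(sub), dim(a))
    match[best[1]] <- best[2]
    rho[best[1]] <- cors[best[1], best[2]]
    avail_r[best[1]] <- FALSE
    avail_c[best[2]] <- FALSE
  }
  data.frame(reference = seq_len(n_ref), component = match,
             correlation = rho, abs_correlation = abs(rho))
}

#' Select a subset of components
#'
#' Either keeps an explicit index list (the analogue of keeping the visually
#' classified resting-state networks from a larger decomposition — e.g. 36 of
#' 70), or automatically keeps every component whose best spatial correlation
#' with a truth atlas reaches `min_cor`.
#'
#' @param maps a `spatial_map_set`.
#' @param keep integer vector of component labels to keep, or `NULL`.
#' @param atlas a `network_atlas` used for automatic matching when `keep` is
#'   `NULL`.
#' @param min_cor minimum |spatial correlation| for automatic matching.
#' @return A `spatial_map_set` subset; original component labels are
#'   preserved in `labels`.
#' @export
select_components <- function(maps, keep = NULL, atlas = NULL, min_cor = 0.5) {
  stopifnot(inherits(maps, "spatial_map_set"))
  if (is.null(keep)) {
    if (is.null(atlas)) stop("provide either `keep` indices or a truth `atlas`")
    ref <- as_template(atlas, maps$mask)$zmaps
    cors <- abs(stats::cor(t(maps$zmaps), t(ref)))   # C x n_ref
    keep <- which(apply(cors, 1, max) >= min_cor)
    if (!length(keep)) stop("no component matches the atlas at min_cor")
  } else {
    if (!all(keep %in% maps$labels)) stop("keep contains unknown component labels")
    keep <- match(keep, maps$labels)
  }
  out <- maps
  out$zmaps <- maps$zmaps[keep, , drop = FALSE]
  out$labels <- maps$labels[keep]
  if (!is.null(maps$group_timecourses)) {
    out$group_timecourses <- maps$group_timecourses[, keep, drop = FALSE]
  }
  out$order <- length(keep)
  out
}
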