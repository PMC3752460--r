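# Independent oracles, deliberately implemented with none of the package's
# machinery: brute-force TFCE via explicit per-threshold component labelling
# (igraph), and closed-form least squares.

neighbour_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  nn <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  if (connectivity == 6) off <- off[nn == 1, ]
  if (connectivity == 18) off <- off[nn <= 2, ]
  off
}

# Explicit TFCE: loop over thresholds, label supra-threshold components with
# igraph, accumulate size^E * h^H * dh per member voxel.
tfce_bruteforce <- function(stat, H = 2, E = 0.5, n_steps = 100,
                            connectivity = 26) {
  d <- dim(stat)
  mx <- max(stat)
  out <- array(0, d)
  if (mx <= 0) return(out)
  dh <- mx / n_steps
  off <- neighbour_offsets(connectivity)
  coords_of <- function(idx) arrayInd(idx, d)
  for (s in seq_len(n_steps)) {
    h <- (s - 0.5) * dh    # midpoint rule, matching the integral convention
    supra <- which(stat >= h)
    if (!length(supra)) next
    pos <- coords_of(supra)
    key <- match(supra, supra)
    edges <- NULL
    lut <- integer(prod(d))
    lut[supra] <- seq_along(supra)
    for (r in seq_len(nrow(off))) {
      nb <- cbind(pos[, 1] + off$dx[r], pos[, 2] + off$dy[r], pos[, 3] + off$dz[r])
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nbidx <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
      tgt <- lut[nbidx]
      src <- seq_along(supra)[ok]
      keep <- tgt > 0
      edges <- rbind(edges, cbind(src[keep], tgt[keep]))
    }
    g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
    if (!is.null(edges) && nrow(edges) > 0) {
      g <- igraph::add_edges(g, as.vector(t(edges)))
    }
    comp <- igraph::components(g)
    sizes <- comp$csize[comp$membership]
    out[supra] <- out[supra] + sizes^E * h^H * dh
  }
  out
}

# Pooled-variance two-sample t by hand.
pooled_t <- function(a, b) {
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
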