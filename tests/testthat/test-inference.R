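test_that("two-sample t matches hand and lm oracles", {
  # pooled-variance hand computation: {1,2,3} vs {2,3,4}, se = sqrt(2/3)
  block <- matrix(c(1, 2, 3, 2, 3, 4), ncol = 1)
  groups <- c(rep("patient", 3), rep("control", 3))
  t_cp <- two_sample_tmap(block, groups, direction = "control>patient")
  expect_equal(t_cp, 1 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(two_sample_tmap(block, groups, direction = "patient>control"),
               -t_cp)

  # identical distributions in both groups -> t = 0
  same <- matrix(rep(c(5, 6, 7), 2), ncol = 1)
  expect_equal(two_sample_tmap(same, groups), 0)

  # voxel-wise covariate: against R's lm, per voxel
  set.seed(31)
  n <- 14
  g <- rep(c("patient", "control"), each = 7)
  X <- matrix(rnorm(n * 6), n)
  Z <- matrix(rnorm(n * 6), n)
  tt <- two_sample_tmap(X, g, covariate = Z)
  for (v in 1:6) {
    fit <- summary(lm(X[, v] ~ I(g == "patient") + Z[, v]))
    expect_equal(tt[v], fit$coefficients[2, "t value"], tolerance = 1e-8)
  }
})

test_that("a covariate orthogonal to group and data leaves the group estimate unchanged", {
  set.seed(8)
  n <- 12
  g <- rep(c("patient", "control"), each = 6)
  gnum <- as.numeric(g == "patient")
  X <- matrix(rnorm(n * 4), n)
  # orthogonalize one covariate column against [1, g, each data column]
  raw <- rnorm(n)
  basis <- cbind(1, gnum, X)
  z <- drop(raw - basis %*% qr.coef(qr(basis), raw))
  Z <- matrix(rep(z, 4), n)
  t_plain <- two_sample_tmap(X, g)
  t_cov <- two_sample_tmap(X, g, covariate = Z)
  # same group coefficient; only the residual df changes (n-2 -> n-3)
  expect_equal(t_cov * sqrt((n - 2) / (n - 3)), t_plain, tolerance = 1e-8)
})

test_that("TFCE matches its closed form and a brute-force fine-step oracle", {
  z <- array(0, c(5, 5, 5))
  expect_true(all(tfce(z) == 0))

  # isolated voxel of height 3: integral of h^2 dh = 9 as dh -> 0
  z[3, 3, 3] <- 3
  expect_equal(tfce(z)[3, 3, 3], 9, tolerance = 0.02)

  skip_if_not_installed("igraph")
  set.seed(12)
  for (rep in 1:5) {
    m <- array(rnorm(125), c(5, 5, 5))
    mine <- tfce(m, tfce_params(n_steps = 100))
    # equal step count isolates the labelling/accumulation logic: exact match
    expect_lt(max(abs(mine - tfce_bruteforce(m, n_steps = 100))), 1e-10)
    # against a 10x finer integration only the quadrature differs: <= 1%
    # in the integrated enhancement
    fine <- tfce_bruteforce(m, n_steps = 1000)
    expect_lt(abs(sum(mine) - sum(fine)) / sum(fine), 0.01)
    expect_lt(max(abs(mine - fine)) / max(fine), 0.02)
  }
  # other connectivities agree with the oracle too
  m <- array(rnorm(125), c(5, 5, 5))
  for (conn in c(6, 18)) {
    mine <- tfce(m, tfce_params(n_steps = 100, connectivity = conn))
    expect_lt(max(abs(mine - tfce_bruteforce(m, n_steps = 100,
                                             connectivity = conn))), 1e-10)
  }
})

test_that("TFCE is monotone under pointwise scaling and handles both signs", {
  set.seed(3)
  m <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  e1 <- tfce(m)
  e2 <- tfce(1.7 * m)
  expect_true(all(e2 >= e1 - 1e-12))
  both <- tfce(m, both_signs = TRUE)
  expect_true(any(both < 0))
  neg_only <- -tfce(-m)
  expect_equal(both[m < 0 & both < 0], neg_only[m < 0 & both < 0])
})

test_that("y-concatenation preserves blocks and round-trips through split_blocks", {
  ch <- fixture_cohort()
  tpl <- as_template(ch$atlas, ch$mask)
  dr <- dual_regression(ch$subjects, tpl, des_norm = TRUE, mask = ch$mask)
  blocks <- dualreg_blocks(dr)
  ds <- yconcat(blocks, ch$design, ch$mask)
  expect_equal(length(ds$blocks), 4)
  expect_identical(ds$blocks, blocks)

  ds1 <- yconcat(blocks[1], ch$design, ch$mask)
  expect_identical(ds1$blocks[[1]], blocks[[1]])

  # 36 blocks are carried intact
  b36 <- replicate(36, blocks[[1]], simplify = FALSE)
  names(b36) <- as.character(1:36)
  expect_equal(length(yconcat(b36, ch$design, ch$mask)$blocks), 36)

  # subject-axis mismatch is refused
  bad <- blocks
  bad[[2]] <- bad[[2]][-1, ]
  expect_error(yconcat(bad, ch$design, ch$mask), "subject axis")

  res <- suppressWarnings(permutation_test(ds, n_perm = 120, seed = 5))
  vols <- split_blocks(res)
  expect_equal(names(vols), names(blocks))
  for (b in names(blocks)) {
    expect_identical(vols[[b]]$t[ch$mask$data], res$blocks[[b]]$t)
    expect_identical(vols[[b]]$p[ch$mask$data], res$blocks[[b]]$p)
    expect_true(all(vols[[b]]$p[!ch$mask$data] == 1))
  }
})

test_that("constant data gives zero t and corrected p of 1 everywhere", {
  mask <- brain_mask(array(TRUE, c(6, 6, 4)), affine = tiny_affine)
  block <- matrix(3.14, nrow = 8, ncol = sum(mask$data))
  groups <- rep(c("patient", "control"), each = 4)
  res <- suppressWarnings(per_map_test(block, groups, mask, n_perm = 120, seed = 2))
  expect_true(all(res$blocks[[1]]$t == 0))
  expect_true(all(res$blocks[[1]]$p == 1))
})

test_that("corrected p-values are valid probabilities monotone in the TFCE statistic", {
  ch <- fixture_cohort()
  tpl <- as_template(ch$atlas, ch$mask)
  dr <- dual_regression(ch$subjects, tpl, des_norm = TRUE, mask = ch$mask)
  ds <- yconcat(dualreg_blocks(dr), ch$design, ch$mask)
  res <- suppressWarnings(permutation_test(ds, n_perm = 150, seed = 9))
  for (b in res$blocks) {
    expect_true(all(b$p >= 1 / (res$n_perm + 1) & b$p <= 1))
    o <- order(b$tfce)
    expect_true(all(diff(b$p[o]) <= 1e-12))
  }
})

test_that("per-map test equals a single-block joint test and is less conservative", {
  ch <- fixture_cohort()
  tpl <- as_template(ch$atlas, ch$mask)
  dr <- dual_regression(ch$subjects, tpl, des_norm = TRUE, mask = ch$mask)
  blocks <- dualreg_blocks(dr)

  single <- suppressWarnings(per_map_test(blocks[[2]], ch$design, ch$mask,
                                          n_perm = 150, seed = 4))
  joint1 <- suppressWarnings(permutation_test(
    yconcat(blocks[2], ch$design, ch$mask), n_perm = 150, seed = 4))
  expect_identical(single$blocks[[1]]$p, joint1$blocks[[1]]$p)
  expect_identical(single$null_max, joint1$null_max)

  # shared permutation stream: per-map p <= joint p voxel-wise, and the
  # number of significant components under joint correction can only drop
  joint <- suppressWarnings(permutation_test(
    yconcat(blocks, ch$design, ch$mask), n_perm = 150, seed = 4))
  n_sig_per_map <- 0L
  for (b in seq_along(blocks)) {
    pm <- suppressWarnings(per_map_test(blocks[[b]], ch$design, ch$mask,
                                        n_perm = 150, seed = 4))
    expect_true(all(pm$blocks[[1]]$p <= joint$blocks[[b]]$p + 1e-12))
    n_sig_per_map <- n_sig_per_map + (any(pm$blocks[[1]]$p < 0.05))
  }
  expect_lte(n_significant_ics(joint), n_sig_per_map)
})

test_that("small designs are enumerated exhaustively and match Monte-Carlo sampling", {
  cfg <- cohort_config(n_patients = 4, n_controls = 4, grid = c(16, 16, 12),
                       n_networks = 2, t_points = 40)
  ch <- simulate_cohort(cfg, seed = 61)
  tpl <- as_template(ch$atlas, ch$mask)
  dr <- dual_regression(ch$subjects, tpl, des_norm = TRUE, mask = ch$mask)
  block <- dualreg_blocks(dr)[1]
  ds <- yconcat(block, ch$design, ch$mask)

  ex <- suppressWarnings(permutation_test(ds, n_perm = 200, seed = 1))  # 70 arrangements
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, choose(8, 4))
  expect_true(all(ex$blocks[[1]]$p >= 1 / 70))

  mc <- permutation_test(ds, n_perm = 5000, seed = 2, exhaustive = "never")
  expect_false(mc$exhaustive)
  expect_lt(max(abs(mc$blocks[[1]]$p - ex$blocks[[1]]$p)), 0.02)
})

test_that("voxels with corrected p exactly at alpha are not significant", {
  mask <- brain_mask(array(TRUE, c(4, 4, 2)), affine = tiny_affine)
  res <- structure(list(
    blocks = list(m = list(t = rep(1, 32), tfce = rep(1, 32),
                           p = rep(c(0.05, 0.04), 16))),
    null_max = numeric(0), n_perm = 100, seed = 1,
    direction = "patient>control", alpha = 0.05,
    params = tfce_params(), mask = mask, exhaustive = FALSE,
    covariate = FALSE), class = "permutation_result")
  sig <- split_blocks(res)$m$sig
  expect_equal(sum(sig), 16)          # only the p = 0.04 voxels
  expect_equal(n_significant_ics(res), 1L)
})

test_that("degenerate designs and tiny permutation counts are refused", {
  mask <- brain_mask(array(TRUE, c(3, 3, 2)), affine = tiny_affine)
  block <- matrix(rnorm(4 * 18), 4)
  expect_error(per_map_test(block, rep("patient", 4), mask),
               "one group is empty")
  expect_error(suppressWarnings(
    per_map_test(block, c("patient", "patient", "control", "control"), mask,
                 n_perm = 50)), "at least 100")
  expect_warning(
    per_map_test(block, c("patient", "patient", "control", "control"), mask,
                 n_perm = 150, seed = 1), "coarse null")
})
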