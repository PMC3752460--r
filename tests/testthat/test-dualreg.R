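ortho_template <- function(n_maps, mask, seed = 3) {
  # orthogonal, mask-demeaned maps: the exact-design case for stage A
  set.seed(seed)
  V <- sum(mask$data)
  m <- qr.Q(qr(matrix(rnorm(V * (n_maps + 1)), V)))[, 2:(n_maps + 1)]
  m <- t(m) - rowMeans(t(m))
  tpl <- as_template(m, mask)
  tpl$zmaps <- m      # keep exact orthogonality (skip z-scoring)
  tpl
}

test_that("stage A recovers exact time courses from data in the template span", {
  mask <- brain_mask(array(TRUE, c(8, 7, 5)), affine = tiny_affine)
  tpl <- ortho_template(3, mask)
  set.seed(4)
  a <- matrix(rnorm(12 * 3), 12)
  Y <- a %*% tpl$zmaps                       # T x V, noise free
  vol <- volume4d(unmask(Y, mask), affine = tiny_affine, tr = 1.8)
  tc <- stage_a_timecourses(vol, tpl, mask)
  expect_lt(max(abs(tc$values - a)), 1e-8)
})

test_that("stage A equals the closed-form normal-equations solution", {
  mask <- brain_mask(array(TRUE, c(5, 4, 3)), affine = tiny_affine)
  tpl <- fake_template(3, mask, seed = 6)
  vol <- random_volume(c(5, 4, 3), t_points = 10, seed = 7)
  tc <- stage_a_timecourses(vol, tpl, mask)
  # independent oracle: per-timepoint beta = (G'G)^-1 G'y
  G <- t(tpl$zmaps)
  G <- sweep(G, 2, colMeans(G))
  Y <- t(matrix(vol$data, prod(dim(mask$data))))
  oracle <- t(solve(crossprod(G), crossprod(G, t(Y))))
  expect_lt(max(abs(tc$values - oracle)), 1e-10)
})

test_that("a 36-map template yields T x 36 time-course matrices", {
  mask <- brain_mask(array(TRUE, c(8, 8, 6)), affine = tiny_affine)
  tpl <- fake_template(36, mask, seed = 2)
  vol <- random_volume(c(8, 8, 6), t_points = 20, seed = 3)
  tc <- stage_a_timecourses(vol, tpl, mask)
  expect_equal(dim(tc$values), c(20, 36))
})

test_that("rank-deficient templates are refused naming the collinear pair", {
  mask <- brain_mask(array(TRUE, c(5, 4, 3)), affine = tiny_affine)
  tpl <- fake_template(3, mask, seed = 6)
  tpl$zmaps[3, ] <- 2 * tpl$zmaps[1, ]
  vol <- random_volume(c(5, 4, 3), t_points = 8, seed = 1)
  expect_error(stage_a_timecourses(vol, tpl, mask), "components 1 and 3")
})

test_that("stage B inverts a known map/time-course factorization at zero noise", {
  mask <- brain_mask(array(TRUE, c(8, 7, 5)), affine = tiny_affine)
  tpl <- ortho_template(3, mask)
  set.seed(8)
  a <- matrix(rnorm(30 * 3), 30)
  Y <- a %*% tpl$zmaps
  vol <- volume4d(unmask(Y, mask), affine = tiny_affine, tr = 1.8)
  tc <- stage_a_timecourses(vol, tpl, mask)
  mp <- stage_b_maps(vol, tc, des_norm = FALSE, mask = mask)
  expect_lt(max(abs(mp$betas - tpl$zmaps)), 1e-6)
})

test_that("des_norm rescales betas exactly by the stage-A column standard deviations", {
  mask <- brain_mask(array(TRUE, c(6, 6, 4)), affine = tiny_affine)
  tpl <- fake_template(4, mask, seed = 5)
  vol <- random_volume(c(6, 6, 4), t_points = 25, seed = 9)
  tc <- stage_a_timecourses(vol, tpl, mask)
  m0 <- stage_b_maps(vol, tc, des_norm = FALSE, mask = mask)
  m1 <- stage_b_maps(vol, tc, des_norm = TRUE, mask = mask)
  s <- apply(tc$values, 2, sd)
  expect_lt(max(abs(m1$betas - m0$betas * s)), 1e-8)
})

test_that("zero-variance time-course columns give zero betas and a flag", {
  mask <- brain_mask(array(TRUE, c(6, 6, 4)), affine = tiny_affine)
  vol <- random_volume(c(6, 6, 4), t_points = 25, seed = 9)
  tc <- structure(list(values = cbind(rnorm(25), 0), labels = 1:2),
                  class = "timecourse_matrix")
  mp <- stage_b_maps(vol, tc, des_norm = TRUE, mask = mask)
  expect_true(all(mp$betas[2, ] == 0))
  expect_identical(mp$zero_variance, c(FALSE, TRUE))
})

test_that("with variance normalization betas track planted amplitude; without, they do not", {
  # one subject whose planted network time course is doubled in amplitude
  at <- make_network_atlas(3, grid = c(14, 14, 10), seed = 6,
                           min_center_separation = 4,
                           within = ellipsoid_mask(c(14, 14, 10)))
  mask <- ellipsoid_mask(c(14, 14, 10), semiaxes = c(5.5, 5.5, 4))
  tpl <- as_template(at, mask)
  base <- simulate_subject(at, t_points = 285, amp_std = 1, noise_std = 0.2,
                           seed = 301)
  amp2 <- simulate_subject(at, effects = effect_spec(1, amplitude_ratio = 2),
                           t_points = 285, amp_std = 1, noise_std = 0.2,
                           seed = 301)
  blob <- at$maps[1, which(mask$data)] >= 0.5
  mean_beta <- function(sub, dn) {
    tc <- stage_a_timecourses(sub$bold, tpl, mask)
    mp <- stage_b_maps(sub$bold, tc, des_norm = dn, mask = mask)
    mean(mp$betas[1, blob])
  }
  # des_norm on: amplitude information reaches the betas
  expect_equal(mean_beta(amp2, TRUE) / mean_beta(base, TRUE), 2, tolerance = 0.05)
  # des_norm off: betas reflect only the (unchanged) spatial shape
  expect_equal(mean_beta(amp2, FALSE) / mean_beta(base, FALSE), 1, tolerance = 0.05)
})

test_that("dual regression is subject-wise independent and order-equivariant", {
  ch <- fixture_cohort()
  tpl <- as_template(ch$atlas, ch$mask)
  dr <- dual_regression(ch$subjects, tpl, des_norm = TRUE, mask = ch$mask)
  expect_length(dr$maps, 12)
  expect_length(dr$timecourses, 12)

  perm <- c(3, 1, 2, 7, 12, 4:6, 8:11)
  drp <- dual_regression(ch$subjects[perm], tpl, des_norm = TRUE, mask = ch$mask)
  for (i in seq_along(perm)) {
    expect_identical(drp$maps[[i]]$betas, dr$maps[[perm[i]]]$betas)
  }

  # duplicated subjects give bit-identical outputs
  dup <- dual_regression(ch$subjects[c(1, 1)], tpl, des_norm = TRUE, mask = ch$mask)
  expect_identical(dup$maps[[1]]$betas, dup$maps[[2]]$betas)
})

test_that("per-subject dual-regression failures are collected and reported together", {
  ch <- fixture_cohort()
  tpl <- as_template(ch$atlas, ch$mask)
  bad <- ch$subjects[1:3]
  bad[[2]] <- random_volume(c(5, 5, 4), t_points = 6)
  err <- tryCatch(dual_regression(bad, tpl, des_norm = TRUE, mask = ch$mask),
                  error = function(e) conditionMessage(e))
  expect_match(err, "1 subject")
  expect_match(err, "subject 2")
})

test_that("stage A then stage B is the identity on template-span data", {
  mask <- brain_mask(array(TRUE, c(8, 7, 5)), affine = tiny_affine)
  tpl <- ortho_template(4, mask, seed = 10)
  set.seed(11)
  a <- matrix(rnorm(40 * 4), 40)
  vol <- volume4d(unmask(a %*% tpl$zmaps, mask), affine = tiny_affine, tr = 1.8)
  tc <- stage_a_timecourses(vol, tpl, mask)
  mp <- stage_b_maps(vol, tc, des_norm = FALSE, mask = mask)
  expect_lt(max(abs(mp$betas - tpl$zmaps)), 1e-6)
})

test_that("planted amplitude effects separate groups only under variance normalization", {
  # low sensor noise: the contrast between the two normalization modes is
  # about where amplitude information goes, and stage-A estimation noise
  # attenuates betas by amp^2/(amp^2 + sigma_e^2) -- a group-dependent bias
  # at high noise that is a property of dual regression itself
  cfg <- cohort_config(n_patients = 10, n_controls = 10, grid = c(16, 16, 12),
                       n_networks = 4, t_points = 100, noise_std = 0.05,
                       effects = list(effect_spec(1, amplitude_ratio = 2)))
  ch <- simulate_cohort(cfg, seed = 77)
  tpl <- as_template(ch$atlas, ch$mask)
  blob <- ch$atlas$maps[1, which(ch$mask$data)] >= 0.5
  pat <- ch$design$group == "patient"
  tstat <- function(dn) {
    dr <- dual_regression(ch$subjects, tpl, des_norm = dn, mask = ch$mask)
    mb <- sapply(dr$maps, function(m) mean(m$betas[1, blob]))
    pooled_t(mb[pat], mb[!pat])
  }
  expect_gt(abs(tstat(TRUE)), 3)
  expect_lt(abs(tstat(FALSE)), 2)
})
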