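test_that("atlas blobs sit where requested and separate cleanly", {
  a1 <- make_network_atlas(1, grid = c(12, 12, 10), seed = 4)
  m <- array(a1$maps[1, ], c(12, 12, 10))
  expect_equal(as.integer(arrayInd(which.max(m), dim(m))),
               as.integer(a1$centers[1, ]))
  expect_equal(max(a1$maps), 1)
  expect_true(all(a1$maps >= 0))

  # centres >= 4 sigma apart -> nearly uncorrelated maps
  at <- make_network_atlas(4, grid = c(24, 24, 16), width_range = c(1.5, 1.5),
                           min_center_separation = 6, seed = 8)
  cors <- cor(t(at$maps))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.2)
})

test_that("atlas supports the study's model-order scale and fails loudly when packing is impossible", {
  a <- make_network_atlas(70, grid = c(24, 24, 16), width_range = c(1, 1.5),
                          min_center_separation = 2, seed = 2)
  expect_equal(nrow(a$maps), 70)
  expect_error(make_network_atlas(10, grid = c(6, 6, 4),
                                  min_center_separation = 10, seed = 1,
                                  max_tries = 200),
               "reduce n_networks")
})

test_that("pure-noise subjects have the configured variance", {
  at <- make_network_atlas(2, grid = c(10, 10, 8), seed = 3)
  s <- simulate_subject(at, t_points = 285, amp_std = 0, noise_std = 1, seed = 5)
  v <- apply(s$bold$data, 1:3, var)
  expect_equal(mean(v), 1, tolerance = 0.02)
  expect_equal(median(v), 1, tolerance = 0.1)
})

test_that("network time courses are band-limited below the cutoff", {
  at <- make_network_atlas(3, grid = c(10, 10, 8), seed = 3)
  s <- simulate_subject(at, t_points = 285, tr = 1.8, lowpass_hz = 0.08, seed = 6)
  for (k in 1:3) {
    x <- s$timecourses[, k]
    spec <- Mod(fft(x))^2
    f <- pmin(0:284, 285 - (0:284)) / (285 * 1.8)
    frac_below <- sum(spec[f <= 0.08]) / sum(spec)
    expect_gte(frac_below, 0.9)   # in fact ~1 by construction
  }
  expect_error(simulate_subject(at, tr = 1.8, lowpass_hz = 0.3, seed = 1),
               "Nyquist")
})

test_that("subject simulation is bit-deterministic in the seed", {
  at <- make_network_atlas(2, grid = c(8, 8, 6), seed = 3)
  s1 <- simulate_subject(at, t_points = 20, seed = 77)
  s2 <- simulate_subject(at, t_points = 20, seed = 77)
  expect_identical(s1$bold$data, s2$bold$data)
  expect_identical(s1$gm$data, s2$gm$data)
  s3 <- simulate_subject(at, t_points = 20, seed = 78)
  expect_false(identical(s1$bold$data, s3$bold$data))
})

test_that("cohorts default to the study's two 19-subject groups and regenerate identically", {
  cfg <- cohort_config()
  expect_equal(cfg$n_patients, 19)
  expect_equal(cfg$n_controls, 19)
  expect_equal(cfg$t_points, 285)
  expect_equal(cfg$tr, 1.8)

  small <- cohort_config(n_patients = 3, n_controls = 3, grid = c(12, 12, 10),
                         n_networks = 2, t_points = 15)
  c1 <- simulate_cohort(small, seed = 31)
  c2 <- simulate_cohort(small, seed = 31)
  for (i in seq_along(c1$subjects)) {
    expect_identical(c1$subjects[[i]]$data, c2$subjects[[i]]$data)
  }
  expect_identical(c1$atlas$maps, c2$atlas$maps)
  expect_equal(sum(c1$design$group == "patient"), 3)
})

test_that("a null cohort plants no group difference; amplitude effects scale the truth time courses", {
  small <- cohort_config(n_patients = 4, n_controls = 4, grid = c(12, 12, 10),
                         n_networks = 2, t_points = 285)
  nullc <- simulate_cohort(small, seed = 12)
  expect_length(nullc$truth$effects, 0)

  eff <- cohort_config(n_patients = 4, n_controls = 4, grid = c(12, 12, 10),
                       n_networks = 2, t_points = 285,
                       effects = list(effect_spec(1, amplitude_ratio = 2)))
  ch <- simulate_cohort(eff, seed = 12)
  pat <- ch$design$group == "patient"
  sd_pat <- sapply(ch$truth$timecourses[pat], function(m) sd(m[, 1]))
  sd_con <- sapply(ch$truth$timecourses[!pat], function(m) sd(m[, 1]))
  expect_equal(mean(sd_pat) / mean(sd_con), 2, tolerance = 0.1)
  # network 2 untouched
  r2 <- mean(sapply(ch$truth$timecourses[pat], function(m) sd(m[, 2]))) /
    mean(sapply(ch$truth$timecourses[!pat], function(m) sd(m[, 2])))
  expect_equal(r2, 1, tolerance = 0.1)
})

test_that("atrophy reduces patient GM inside the sphere and attenuates BOLD weights", {
  at <- make_network_atlas(1, grid = c(12, 12, 10), seed = 9,
                           within = ellipsoid_mask(c(12, 12, 10)))
  ef <- effect_spec(1, atrophy = list(center = NULL, radius = 2.5,
                                      gm_reduction = 0.5, bold_attenuation = 1))
  ctr <- at$centers[1, ]
  pat <- simulate_subject(at, effects = ef, t_points = 30, amp_std = 5,
                          noise_std = 0, seed = 21)
  con <- simulate_subject(at, effects = NULL, t_points = 30, amp_std = 5,
                          noise_std = 0, seed = 21)
  # full BOLD attenuation kills the signal at the network centre
  expect_lt(max(abs(pat$bold$data[ctr[1], ctr[2], ctr[3], ])), 1e-10)
  expect_gt(max(abs(con$bold$data[ctr[1], ctr[2], ctr[3], ])), 0.5)
  # GM halved at the centre relative to the control's
  expect_equal(mean(pat$gm$data[ctr[1], ctr[2], ctr[3], ]),
               0.5 * 0.7, tolerance = 0.1)
  expect_true(all(pat$gm$data >= 0 & pat$gm$data <= 1))
})

test_that("invalid cohort configurations report all problems at once", {
  err <- tryCatch(cohort_config(n_patients = 0, t_points = 1, tr = -1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "non-empty")
  expect_match(err, "t_points")
  expect_match(err, "tr must be positive")
})

test_that("cohorts round-trip through disk with design, mask and truth sidecar", {
  dir <- withr::local_tempdir()
  small <- cohort_config(n_patients = 2, n_controls = 2, grid = c(10, 10, 8),
                         n_networks = 2, t_points = 8)
  ch <- simulate_cohort(small, seed = 55)
  write_cohort(ch, dir)
  des <- read_design(file.path(dir, "design.tsv"))
  expect_equal(nrow(des), 4)
  b1 <- read_volume4d(des$bold_path[1])
  expect_identical(b1$data, ch$subjects[[1]]$data)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 55)
  m <- read_mask(file.path(dir, "mask.nii"))
  expect_identical(m$data, ch$mask$data)
})
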