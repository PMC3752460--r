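# Small in-code fixtures shared across test files.

tiny_affine <- diag(c(4, 4, 4, 1))

# A small ellipsoid-masked cohort at desk scale; memoised per parameter set
# so several test files can share one simulation.
.fixture_cache <- new.env(parent = emptyenv())

fixture_cohort <- function(key = "default", ...) {
  if (!exists(key, .fixture_cache)) {
    args <- modifyList(list(n_patients = 6, n_controls = 6,
                            grid = c(16, 16, 12), n_networks = 4,
                            t_points = 60), list(...))
    cfg <- do.call(cohort_config, args)
    assign(key, simulate_cohort(cfg, seed = 901), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# A fabricated spatial_map_set with well-conditioned random maps.
fake_template <- function(n_maps, mask, seed = 7) {
  set.seed(seed)
  m <- matrix(rnorm(n_maps * sum(mask$data)), n_maps)
  as_template(m, mask)
}

random_volume <- function(grid = c(6, 5, 4), t_points = 3, seed = 1,
                          tr = 1.8) {
  set.seed(seed)
  volume4d(array(rnorm(prod(grid) * t_points), dim = c(grid, t_points)),
           affine = tiny_affine, tr = tr)
}
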