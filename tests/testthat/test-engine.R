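test_that("the propagation rule matches the overdamped update formula", {
  cfg <- engine_config(n_steps = 1)
  # drift under a constant force, no noise: (D/kBT) F dt
  x <- step_update(matrix(c(0, 0, 50), 1, 3), matrix(c(0, 0, -5), 1, 3),
                   cfg, matrix(0, 1, 3))
  expect_equal(x[1, 3] - 50, 0.6 / (0.0019872 * 300) * (-5) * 0.01,
               tolerance = 1e-12)
  # zero force, zero noise: unchanged
  x0 <- matrix(c(3, 4, 5), 1, 3)
  expect_equal(step_update(x0, matrix(0, 1, 3), cfg, matrix(0, 1, 3)), x0)
  # wall reflection: z that would become -0.3 is mirrored to +0.3
  xr <- step_update(matrix(c(0, 0, 0.1), 1, 3), matrix(0, 1, 3), cfg,
                    matrix(c(0, 0, -0.4 / sqrt(2 * 0.6 * 0.01)), 1, 3))
  expect_equal(xr[1, 3], 0.3, tolerance = 1e-9)
  # periodic wrapping in x
  xw <- step_update(matrix(c(59.9, 0, 50), 1, 3), matrix(0, 1, 3), cfg,
                    matrix(c(0.3 / sqrt(2 * 0.6 * 0.01), 0, 0), 1, 3))
  expect_equal(xw[1, 1], -59.8, tolerance = 1e-9)
})

test_that("the compiled propagator agrees with the exposed step rule", {
  st <- fixture_system()$structure
  cfg <- engine_config(n_steps = 1, stride = 1, seed = 99, well_depth = 0)
  r <- run_simulation(st, cfg)
  set.seed(99)
  noise <- matrix(rnorm(3), 1, 3)   # draw order: particle-major, axis-minor
  xr <- step_update(matrix(r$trajectory$coords[1, 1, ], 1, 3),
                    matrix(0, 1, 3), cfg, noise)
  expect_equal(matrix(r$trajectory$coords[2, 1, ], 1, 3), xr, tolerance = 1e-12)
})

test_that("simulations are deterministic for a fixed seed and honour steps = 0", {
  st <- fixture_system()$structure
  cfg <- engine_config(n_steps = 5000, seed = 42, stride = 50)
  r1 <- run_simulation(st, cfg, bias = steering_config())
  r2 <- run_simulation(st, cfg, bias = steering_config())
  expect_identical(r1$trajectory$coords, r2$trajectory$coords)
  expect_identical(r1$reasons, r2$reasons)

  r0 <- run_simulation(st, engine_config(n_steps = 0, stride = 1, seed = 1))
  expect_equal(length(r0$trajectory$times), 1L)
  expect_equal(r0$trajectory$coords[1, 1, ],
               atom_coords(st, "ARG:397:CZ") + c(0, 0, 18))
  # all recorded z stay above the membrane wall
  expect_true(all(r1$trajectory$coords[, , 3] >= 0))
})

test_that("uniform ligand placement fills the extracellular slab at the requested separation", {
  box <- periodic_box()
  pos <- place_ligands_uniform(76, box, min_sep = 6, seed = 8)
  expect_equal(nrow(pos), 76L)
  expect_true(all(pos[, 3] > 0))
  dmin <- min(apply(utils::combn(76, 2), 2, function(ij) {
    minimum_image_distance(pos[ij[1], ], pos[ij[2], ], box)
  }))
  expect_gte(dmin, 6)
  expect_equal(nrow(place_ligands_uniform(1, box, seed = 1)), 1L)
  small <- periodic_box(c(15, 15, 30), c(TRUE, TRUE, FALSE))
  expect_error(place_ligands_uniform(500, small, z_range = c(5, 10),
                                     min_sep = 6, max_attempts = 50),
               "smaller separation")
})

test_that("first-binding time requires a sustained sub-threshold dwell", {
  d <- c(10, 8, 6, 5, 5, 5, 5)
  expect_equal(first_binding_time(d, threshold = 7, dwell = 2, times = 0:6), 2)
  expect_true(is.na(first_binding_time(rep(8, 10), threshold = 7, dwell = 1)))
  expect_equal(first_binding_time(c(5, 5, 5), threshold = 7, dwell = 1,
                                  times = c(10, 20, 30)), 10)
  expect_error(first_binding_time(d, threshold = -1), "positive")
})

test_that("binding-well occupancy increases with well depth", {
  st <- fixture_system()$structure
  occ <- sapply(c(0, 2, 5), function(eps) {
    cfg <- engine_config(n_steps = 2e5, stride = 20, seed = 5, well_depth = eps,
                         initial_distance = 6)
    r <- run_simulation(st, cfg, bias = flatbottom_config(cutoff = 12))
    mean(binding_distances(r)[, 1] < 4)
  })
  expect_true(all(diff(occ) > 0))
})

test_that("steering makes binding nearly certain where unbiased diffusion mostly fails", {
  st <- fixture_system()$structure
  bound <- function(seed, bias) {
    r <- run_simulation(st, engine_config(n_steps = 2e5, seed = seed), bias = bias)
    !is.na(r$first_binding[1])
  }
  seeds <- 101:120
  steer_frac <- mean(vapply(seeds, bound, logical(1), bias = steering_config()))
  unb_frac <- mean(vapply(seeds, bound, logical(1), bias = NULL))
  expect_gte(steer_frac, 0.9)
  expect_lt(unb_frac, steer_frac)
  pv <- stats::prop.test(c(sum(steer_frac * 20), sum(unb_frac * 20)), c(20, 20),
                         alternative = "greater")$p.value
  expect_lt(pv, 0.05)
})

test_that("high ligand concentration raises the chance of at least one binding event", {
  st <- fixture_system()$structure
  box <- periodic_box()
  any_bound <- function(seed, n) {
    init <- place_ligands_uniform(n, box, seed = seed)
    r <- run_simulation(st, engine_config(n_steps = 2e4, seed = seed, n_ligands = n),
                        initial_positions = init)
    any(!is.na(r$first_binding))
  }
  hi <- vapply(1:30, any_bound, logical(1), n = 76)
  lo <- vapply(1:30, any_bound, logical(1), n = 1)
  expect_gt(sum(hi), sum(lo))
  tab <- matrix(c(sum(hi), 30 - sum(hi), sum(lo), 30 - sum(lo)), 2, byrow = TRUE)
  expect_lt(stats::fisher.test(tab, alternative = "greater")$p.value, 0.05)
})

test_that("an oversized time step triggers the drift warning", {
  st <- fixture_system()$structure
  cfg <- engine_config(n_steps = 20, dt = 1, stride = 1, seed = 2)
  expect_warning(run_simulation(st, cfg, bias = steering_config()), "dt too large")
})
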