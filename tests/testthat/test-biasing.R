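test_that("cone membership implements the extracellular selection region", {
  reg <- cone_region()
  expect_true(cone_contains(c(0, 0, 5), reg))        # on-axis point
  expect_false(cone_contains(c(16, 0, 0.5), reg))    # 256 >= (15.5)^2 = 240.25
  expect_false(cone_contains(c(0, 0, -1), reg))      # below the membrane
  expect_false(cone_contains(c(0, 0, 0), reg))       # z > 0 is strict

  # equals brute-force evaluation of the two inequalities
  set.seed(13)
  pts <- cbind(runif(300, -40, 40), runif(300, -40, 40), runif(300, -20, 60))
  brute <- pts[, 3] > 0 & pts[, 1]^2 + pts[, 2]^2 < (pts[, 3] + 15)^2
  expect_identical(cone_contains(pts, reg), brute)
})

test_that("steering controller applies a constant-magnitude force only beyond the cut-off inside the cone", {
  cfg <- steering_config()  # f0 = 5, cutoff = 7
  d1 <- steering_decision(c(0, 0, 20), c(0, 0, 10), cfg)
  expect_true(d1$active)
  expect_equal(d1$force, c(0, 0, -5))
  expect_equal(d1$reason, "beyond_cutoff_in_region")

  d2 <- steering_decision(c(0, 0, 14), c(0, 0, 10), cfg)
  expect_false(d2$active)
  expect_identical(d2$force, c(0, 0, 0))
  expect_equal(d2$reason, "within_cutoff")

  d3 <- steering_decision(c(0, 0, -5), c(0, 0, 10), cfg)
  expect_false(d3$active)
  expect_equal(d3$reason, "outside_region")

  # active force always has magnitude f0 and points towards the reference
  set.seed(31)
  for (i in 1:50) {
    lig <- c(runif(1, -20, 20), runif(1, -20, 20), runif(1, 1, 60))
    ref <- c(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0, 5))
    d <- steering_decision(lig, ref, cfg)
    if (d$active) {
      expect_equal(sqrt(sum(d$force^2)), cfg$f0, tolerance = 1e-10)
      expect_lt(sum(d$force * (lig - ref)), 0)
    } else {
      expect_identical(d$force, c(0, 0, 0))
    }
  }
  expect_error(steering_config(f0 = -1), "positive")
  expect_error(steering_config(update_period = 3), "1 or 2")
})

test_that("flat-bottom potential is zero inside the cut-off and harmonic beyond it", {
  cfg <- flatbottom_config(k = 0.1, cutoff = 12)
  expect_equal(flat_bottom(5, flatbottom_config(cutoff = 7)),
               list(energy = 0, force = 0))
  expect_equal(flat_bottom(12, cfg), list(energy = 0, force = 0))
  fb <- flat_bottom(13, cfg)
  expect_equal(fb$energy, 0.05)
  expect_equal(fb$force, 0.1)
  expect_error(flat_bottom(-1, cfg), "non-negative")

  # non-decreasing, convex beyond dc, and force = -dU/dd (finite differences)
  d <- seq(0, 25, by = 0.05)
  U <- flat_bottom(d, cfg)$energy
  expect_true(all(diff(U) >= 0))
  out <- d > 12.1
  expect_true(all(diff(diff(U[out])) >= -1e-12))
  h <- 1e-6
  for (dd in c(12.5, 15, 20)) {
    num <- (flat_bottom(dd + h, cfg)$energy - flat_bottom(dd - h, cfg)$energy) / (2 * h)
    expect_equal(flat_bottom(dd, cfg)$force, num, tolerance = 1e-6)
  }

  # vector decision form: inactive inside, restoring and towards ref outside
  dec_in <- flatbottom_decision(c(0, 0, 10), c(0, 0, 2), cfg)
  expect_false(dec_in$active)
  expect_equal(dec_in$reason, "inside_flat_region")
  dec_out <- flatbottom_decision(c(0, 0, 20), c(0, 0, 2), cfg)
  expect_true(dec_out$active)
  expect_equal(dec_out$force, c(0, 0, -0.1 * 6))
  expect_equal(dec_out$reason, "in_harmonic_region")
})

test_that("bias configs are buildable from flat YAML-style keys", {
  lst <- list(`bias.kind` = "steer", `bias.f0` = 3, `bias.cutoff` = 10,
              `bias.update_period` = 2, `bias.cone_apex_offset` = 12,
              `bias.reference` = "ARG:397:CG", `bias.target_label` = "CA")
  cfg <- bias_config_from_list(lst)
  expect_s3_class(cfg, "steering_config")
  expect_equal(cfg$f0, 3)
  expect_equal(cfg$cutoff, 10)
  expect_equal(cfg$update_period, 2L)
  expect_equal(cfg$region$apex_offset, 12)
  expect_equal(cfg$reference, "ARG:397:CG")

  nested <- list(bias = list(kind = "flatbottom", k = 0.2, cutoff = 7))
  fb <- bias_config_from_list(nested)
  expect_s3_class(fb, "flatbottom_config")
  expect_equal(fb$k, 0.2)
  expect_null(bias_config_from_list(list(bias = list(kind = "none"))))
})
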