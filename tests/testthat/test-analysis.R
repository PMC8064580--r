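test_that("distance series handles static and mobile endpoints", {
  st <- fixture_system()$structure
  tr <- make_traj(list(matrix(c(3, 4, 0), 1, 3)), "CA")
  # 3-4-5 against an origin reference atom:
  toy <- read_pdb_subset(write_toy_pdb(
    "ATOM      1  CZ  ARG A 397       0.000   0.000   0.000  1.00  0.00           C"))
  ds <- distance_series(tr, "ARG:397:CZ", "CA", toy)
  expect_equal(ds$distance, 5)

  # static-static pair: constant crystal-like gate distance on the fixture
  tr3 <- make_traj(replicate(3, matrix(c(0, 0, 30), 1, 3), simplify = FALSE), "CA")
  gate <- distance_series(tr3, "SER:277:CA", "PRO:356:CA", st)
  expect_equal(gate$distance, rep(5.6, 3), tolerance = 1e-9)

  expect_error(distance_series(tr3, "ARG:397:CZ", "XX", st), "closest|label")
})

test_that("RDF concentrates mass in the occupied bin and counts cumulatively", {
  # single ligand pinned at 3.0 A for every frame
  tr <- make_traj(replicate(4, matrix(c(3, 0, 0), 1, 3), simplify = FALSE), "CA")
  g <- rdf(tr, c(0, 0, 0), r_max = 10, bin_width = 0.1)
  hot <- g$g > 0
  expect_equal(sum(hot), 1L)
  expect_equal(g$r[hot], 3.05)
  expect_equal(utils::tail(g$N, 1), 1)
  expect_true(all(diff(g$N) >= 0))

  # no ligand within r_max: g and N identically zero
  far <- make_traj(list(matrix(c(50, 0, 0), 1, 3)), "CA")
  g0 <- rdf(far, c(0, 0, 0), r_max = 10, bin_width = 0.5)
  expect_true(all(g0$g == 0) && all(g0$N == 0))

  expect_error(rdf(tr, c(0, 0, 0), r_max = -1), "positive")
  expect_error(rdf(tr, c(0, 0, 0), r_max = 10, bin_width = 11), "bin width")
})

test_that("RDF normalisation is flat for uniform sampling in the analysis sphere", {
  set.seed(5)
  n <- 2e5
  r <- 10 * runif(n)^(1 / 3)
  cth <- runif(n, -1, 1); sth <- sqrt(1 - cth^2); ph <- runif(n, 0, 2 * pi)
  co <- array(0, c(1, n, 3))
  co[1, , 1] <- r * sth * cos(ph); co[1, , 2] <- r * sth * sin(ph); co[1, , 3] <- r * cth
  tr <- trajectory(0, co, sprintf("P%d", seq_len(n)))
  g <- rdf(tr, c(0, 0, 0), r_max = 10, bin_width = 0.5)
  expect_lt(max(abs(g$g[g$r > 2] - 1)), 0.05)
  expect_equal(utils::tail(g$N, 1), n)
})

test_that("conformer classification recovers syn/anti occupancies", {
  sched <- synth_dihedral_trajectory(list(c(10, 70)))
  expect_equal(unname(conformer_classify(sched)$occupancy["syn"]), 1)
  sched <- synth_dihedral_trajectory(list(c(10, 180)))
  expect_equal(unname(conformer_classify(sched)$occupancy["anti"]), 1)
  mix <- synth_dihedral_trajectory(list(c(7, 170), c(3, 60)))
  occ <- conformer_classify(mix)$occupancy
  expect_equal(unname(occ["anti"]), 0.7)
  expect_equal(unname(occ["syn"]), 0.3)
  # three-state windows: 120 degrees falls in neither mode window
  tri <- conformer_classify(synth_dihedral_trajectory(list(c(2, 120), c(2, 70))),
                            three_state = TRUE)
  expect_equal(unname(tri$occupancy["other"]), 0.5)
})

test_that("conformer occupancy is invariant under rigid motion of the ligand", {
  mix <- synth_dihedral_trajectory(list(c(4, 165), c(6, -60)))
  occ0 <- conformer_classify(mix)$occupancy
  set.seed(3)
  co <- mix$coords
  for (f in seq_len(dim(co)[1])) {
    ax <- rnorm(3); ang <- runif(1, 0, 360); shift <- rnorm(3, sd = 10)
    for (p in 1:4) co[f, p, ] <- rotate_about_axis(co[f, p, ], ax, ang) + shift
  }
  moved <- trajectory(mix$times, co, mix$labels)
  expect_equal(conformer_classify(moved)$occupancy, occ0)
})

test_that("binding-event detection applies dwell and hysteresis", {
  ds <- data.frame(time = 0:7, distance = c(10, 8, 6, 5, 5, 6, 9, 10))
  ev <- detect_binding_events(ds, bind = 7, unbind = 9, dwell = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 2)
  expect_equal(ev$end, 7)
  expect_equal(ev$residency, 5)

  none <- detect_binding_events(data.frame(time = 0:5, distance = rep(8, 6)),
                                bind = 7, unbind = 9, dwell = 2)
  expect_equal(nrow(none), 0L)

  two <- detect_binding_events(
    data.frame(time = 0:11, distance = c(10, 5, 5, 10, 10, 10, 5, 5, 5, 10, 10, 10)),
    bind = 7, unbind = 9, dwell = 2)
  expect_equal(nrow(two), 2L)
  expect_true(all(two$end[1] <= two$start[2]))
  expect_true(all(two$end >= two$start))

  expect_error(detect_binding_events(ds, bind = 7, unbind = 5), "unbind")
})

test_that("with equal thresholds and dwell 1 event detection reduces to threshold crossing", {
  set.seed(19)
  for (i in 1:10) {
    d <- runif(40, 2, 12)
    ds <- data.frame(time = seq_along(d) - 1, distance = d)
    ev <- detect_binding_events(ds, bind = 7, unbind = 7, dwell = 1)
    below <- d < 7
    runs <- rle(below)
    starts_oracle <- (cumsum(c(1, runs$lengths))[-(length(runs$lengths) + 1)] - 1)[runs$values]
    expect_equal(ev$start, ds$time[starts_oracle + 1])
    # residencies can never exceed the trajectory duration
    expect_lte(sum(ev$residency), max(ds$time) - min(ds$time))
  }
})

test_that("bias fraction is the mean of the per-frame flags", {
  expect_equal(bias_fraction(c(TRUE, TRUE, rep(FALSE, 8))), 0.2)
  expect_equal(bias_fraction(rep(FALSE, 5)), 0)
  expect_equal(bias_fraction(rep(TRUE, 4)), 1)
  expect_error(bias_fraction(logical(0)), "no frames")
})
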