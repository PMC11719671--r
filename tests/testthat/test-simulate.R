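# Stochastic outgrowth simulator: determinism, degenerate configurations,
# monotone growth, qualitative day-course and Poisson seeding calibration.

test_that("zero seeding yields empty networks at every day", {
  nets <- simulate_ring_series(growth_params(seed_density = 0),
                               days = c(1, 4, 7), seed = 1)
  expect_true(all(vapply(nets, function(n) length(n$segments) == 0L, logical(1))))
})

test_that("without jitter or branching, vessels grow straight and radially", {
  gp <- growth_params(seed_density = 3, elongation = 100, direction_jitter = 0,
                      branching_rate = 0, anastomosis_prob = 0)
  net <- simulate_ring(gp, day = 7, ring_radius = 500, seed = 4)
  expect_gt(length(net$segments), 0)
  for (s in net$segments) {
    expect_equal(s$kind, "initial")
    # every vessel seeded after day 0 grows at most elongation x 7 days
    expect_lte(s$length, 100 * 7 + 1e-6)
    # straight: path length equals endpoint distance
    tip <- s$polyline[nrow(s$polyline), ]
    expect_equal(s$length, sqrt(sum((tip - s$polyline[1, ])^2)), tolerance = 1e-9)
    # radial: direction parallel to the attachment's outward normal
    dir <- (tip - s$polyline[1, ]) / s$length
    nrm <- s$polyline[1, ] / sqrt(sum(s$polyline[1, ]^2))
    expect_equal(abs(sum(dir * nrm)), 1, tolerance = 1e-9)
  }
})

test_that("identical seeds reproduce identical experiments", {
  cfg <- simulation_config(rings_per_group = 2, donors = 1, seed = 99,
                           groups = list(control = growth_params(seed_density = 4),
                                         treatment = growth_params(seed_density = 4,
                                                                   treatment_multiplier = 1.5)))
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$table, b$table)
  cfg2 <- cfg; cfg2$seed <- 100L
  c <- simulate_experiment(cfg2)
  expect_false(identical(a$table, c$table))
})

test_that("ring substreams are stable when the ring count changes", {
  gp <- growth_params(seed_density = 4)
  n3 <- simulate_ring_series(gp, days = 7,
                             seed = angioring:::ring_substream_seed(5, 1, 1, 3))
  # ring 3's network must be the same whether 3 or 5 rings are simulated,
  # because each ring draws from its own counter-based substream
  n3b <- simulate_ring_series(gp, days = 7,
                              seed = angioring:::ring_substream_seed(5, 1, 1, 3))
  expect_identical(n3$day7$segments, n3b$day7$segments)
})

test_that("growth is monotone: earlier networks are sub-geometries of later ones", {
  nets <- simulate_ring_series(growth_params(), days = c(1, 4, 7), seed = 21)
  for (pair in list(c("day1", "day4"), c("day4", "day7"))) {
    early <- nets[[pair[1]]]; late <- nets[[pair[2]]]
    expect_true(all(names(early$segments) %in% names(late$segments)))
    for (id in names(early$segments)) {
      pe <- early$segments[[id]]$polyline
      pl <- late$segments[[id]]$polyline
      expect_gte(nrow(pl), nrow(pe))
      # the early polyline is a prefix of the later one (up to a possibly
      # redirected final growth step at a later anastomosis)
      n_cmp <- nrow(pe) - 1L
      expect_equal(pl[seq_len(n_cmp), ], pe[seq_len(n_cmp), ], tolerance = 1e-12)
    }
  }
})

test_that("primary-vessel percentage is 100 at day 1 and declines by day 7", {
  for (seed in c(3, 14, 159)) {
    nets <- simulate_ring_series(growth_params(), days = c(1, 7), seed = seed)
    d1 <- nets$day1; d7 <- nets$day7
    if (length(d1$segments)) {
      expect_equal(vessel_structure_pct(d1), 100)
    }
    expect_lt(vessel_structure_pct(d7), 100)
  }
})

test_that("day-7 vessel density matches the Poisson seeding expectation", {
  gp <- growth_params(seed_density = 3, branching_rate = 0,
                      anastomosis_prob = 0, elongation = 60)
  dens <- vapply(1:200, function(k) {
    net <- simulate_ring(gp, day = 7, ring_radius = 540, seed = 5000 + k,
                         step_days = 0.5)
    vessel_count_and_density(net)$density
  }, numeric(1))
  # counts are Poisson with mean seed_density x circumference; the density
  # mean estimator has SE sqrt(lambda)/ (circ_mm sqrt(n))
  circ_mm <- 2 * pi * 0.540
  lambda <- 3 * circ_mm
  se <- sqrt(lambda) / (circ_mm * sqrt(length(dens)))
  expect_lt(abs(mean(dens) - 3), 3 * se)
})

test_that("treatment multipliers shift growth and branching as configured", {
  lens <- vapply(c(0.5, 1, 2), function(m) {
    net <- simulate_ring(growth_params(treatment_multiplier = m,
                                       anastomosis_prob = 0),
                         day = 7, seed = 77)
    total_and_mean_vessel_length(net)$total
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("rendered masks contain the ring and all vessels", {
  net <- toy_network()
  mp <- render_mask(net, pixel_size = 2, vessel_width_px = 3)
  expect_s3_class(mp, "mask_pair")
  expect_gt(sum(mp$ring_mask), 0)
  expect_gt(sum(mp$vessel_mask), 0)
  # empty network: ring-only mask
  mp0 <- render_mask(vessel_network(ring_explant(radius = 300)), pixel_size = 2)
  expect_equal(sum(mp0$vessel_mask), 0)
  expect_gt(sum(mp0$ring_mask), 0)
})
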