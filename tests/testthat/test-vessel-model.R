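# Domain types and the twelve per-network parameters.

test_that("ring circumference covers circles, polygons and degenerate input", {
  expect_equal(circumference(ring_explant(radius = 500)), 2 * pi * 500)
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  expect_equal(circumference(ring_explant(center = c(500, 500), boundary = sq)), 4000)
  # irregular pentagon against direct edge summation
  set.seed(42)
  th <- sort(runif(5, 0, 2 * pi))
  pent <- cbind(500 * cos(th), 500 * sin(th))
  expected <- sum(sqrt(rowSums((pent - pent[c(2:5, 1), ])^2)))
  expect_equal(circumference(ring_explant(boundary = pent)), expected)
  expect_error(ring_explant(boundary = pent[1:2, ]), class = "angioring_invalid_geometry")
  bow <- rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100))
  expect_error(ring_explant(boundary = bow), class = "angioring_invalid_geometry")
  expect_error(ring_explant(radius = -1), class = "angioring_invalid_geometry")
})

test_that("segment and network invariants are enforced", {
  expect_error(vessel_segment("x", rbind(c(0, 0)), "initial"),
               class = "angioring_invalid_geometry")
  expect_error(vessel_segment("x", rbind(c(0, 0), c(0, 0)), "initial"),
               class = "angioring_invalid_geometry")
  expect_error(vessel_segment("x", rbind(c(0, 0), c(1, 1)), "branch"),
               class = "angioring_invalid_network")
  expect_error(vessel_segment("x", rbind(c(0, 0), c(1, 1)), "initial",
                              parent_id = "y"),
               class = "angioring_invalid_network")
  ring <- ring_explant(radius = 500)
  i1 <- vessel_segment("i1", rbind(c(500, 0), c(700, 0)), "initial")
  orphan <- vessel_segment("b9", rbind(c(600, 0), c(600, 50)), "branch",
                           parent_id = "nope")
  expect_error(vessel_network(ring, list(i1, orphan)),
               class = "angioring_invalid_network")
  expect_error(vessel_network(ring, list(i1, i1)), class = "angioring_invalid_network")
})

test_that("vessel structure percentage matches definitions and edge cases", {
  net <- toy_network()
  expect_equal(vessel_structure_pct(net), 60)
  only_primary <- vessel_network(ring_explant(radius = 500),
                                 net$segments[1:3])
  expect_equal(vessel_structure_pct(only_primary), 100)
  empty <- vessel_network(ring_explant(radius = 500))
  expect_error(vessel_structure_pct(empty), class = "angioring_undefined_parameter")
})

test_that("loop counting distinguishes trees, triangles and short closures", {
  expect_equal(count_loops(toy_network()), 0L)
  expect_equal(count_loops(triangle_loop_network()), 1L)
  # two branches sharing both endpoints: a 2-segment closure, not a loop
  ring <- ring_explant(radius = 500)
  i1 <- vessel_segment("i1", rbind(c(500, 0), c(800, 0)), "initial")
  b1 <- vessel_segment("b1", rbind(c(600, 0), c(650, 100)), "branch", parent_id = "i1")
  b2 <- vessel_segment("b2", rbind(c(600, 0), c(650, 100)), "branch", parent_id = "i1")
  net2 <- vessel_network(ring, list(i1, b1, b2),
                         fusions = data.frame(segment_id = "b2", target_id = "b1",
                                              x = 650, y = 100))
  expect_equal(count_loops(net2), 0L)
})

test_that("maximum radial outgrowth is perpendicular distance, not path length", {
  ring <- ring_explant(radius = 500)
  straight <- vessel_network(ring, list(
    vessel_segment("i1", rbind(c(500, 0), c(700, 0)), "initial")))
  expect_equal(max_radial_outgrowth(straight), 200)
  # tangential arc: path length ~300 but the tip sits 150 um from the boundary
  th <- seq(0, 300 / 650, length.out = 30)
  arc <- cbind(650 * cos(th), 650 * sin(th))
  arc[1, ] <- c(500, 0) * 650 / 500  # start on a radial line
  curved <- vessel_network(ring, list(
    vessel_segment("i1", rbind(c(500, 0), arc), "initial")))
  expect_equal(max_radial_outgrowth(curved), 150, tolerance = 1e-6)
  expect_gt(max_initial_vessel_length(curved), 150)
  expect_error(max_radial_outgrowth(vessel_network(ring)),
               class = "angioring_undefined_parameter")
})

test_that("initial vessel length, totals and means match direct summation", {
  net <- toy_network()
  expect_equal(max_initial_vessel_length(net), 500)
  tl <- total_and_mean_vessel_length(net)
  expect_equal(tl$total, 1250)
  expect_equal(tl$mean, 250)
  one <- vessel_network(ring_explant(radius = 500), list(
    vessel_segment("i1", rbind(c(500, 0), c(777, 0)), "initial")))
  tl1 <- total_and_mean_vessel_length(one)
  expect_equal(tl1$total, tl1$mean)
})

test_that("growth speeds use exact elapsed time and flag bad intervals", {
  ring <- ring_explant(radius = 500)
  net_at <- function(mean_len) {
    vessel_network(ring, list(
      vessel_segment("i1", rbind(c(500, 0), c(500 + mean_len, 0)), "initial")))
  }
  o4 <- explant_observation("d1", "g", "r1", 4, imaging_time_h = 96,
                            network = net_at(250))
  o7 <- explant_observation("d1", "g", "r1", 7, imaging_time_h = 96 + 72,
                            network = net_at(400))
  sp <- growth_speeds(o4, o7)
  expect_equal(sp$mean_per_h, 150 / 72)
  expect_equal(sp$mean_per_day, 50)
  expect_equal(sp$max_per_day, 50)
  # no growth
  sp0 <- growth_speeds(o4, explant_observation("d1", "g", "r1", 7,
                                               imaging_time_h = 96 + 72,
                                               network = net_at(250)))
  expect_equal(sp0$mean_per_h, 0)
  # odd elapsed time, against direct arithmetic
  o7b <- explant_observation("d1", "g", "r1", 7, imaging_time_h = 96 + 70.5,
                             network = net_at(397))
  expect_equal(growth_speeds(o4, o7b)$mean_per_h, (397 - 250) / 70.5)
  expect_error(growth_speeds(o7, o4), class = "angioring_invalid_interval")
  o_other <- explant_observation("d1", "g", "r2", 7, imaging_time_h = 200,
                                 network = net_at(1))
  expect_error(growth_speeds(o4, o_other), class = "angioring_invalid_interval")
})

test_that("vessel count, density, branch and junction statistics agree with hand counts", {
  net <- toy_network()
  vc <- vessel_count_and_density(net)
  expect_equal(vc$count, 3L)
  expect_equal(vc$density, 3 / (2 * pi * 0.5))
  r3 <- 3000 / (2 * pi)
  net3 <- vessel_network(ring_explant(radius = r3), list(
    vessel_segment("i1", rbind(c(r3, 0), c(r3 + 100, 0)), "initial"),
    vessel_segment("i2", rbind(c(0, r3), c(0, r3 + 100)), "initial"),
    vessel_segment("i3", rbind(c(-r3, 0), c(-r3 - 100, 0)), "initial")))
  expect_equal(vessel_count_and_density(net3)$density, 1)
  expect_equal(vessel_count_and_density(vessel_network(ring_explant(radius = 500)))$count, 0L)

  bs <- branch_statistics(net)
  expect_equal(bs$n_branches, 2L)
  expect_equal(bs$mean_branch_length, 125)
  expect_equal(sum(bs$histogram$rel_freq), 1)
  bs0 <- branch_statistics(vessel_network(ring_explant(radius = 500)))
  expect_equal(bs0$n_branches, 0L)
  expect_true(is.na(bs0$mean_branch_length))
  # all branches equal -> all mass in one bin
  ring <- ring_explant(radius = 500)
  eq <- vessel_network(ring, list(
    vessel_segment("i1", rbind(c(500, 0), c(900, 0)), "initial"),
    vessel_segment("b1", rbind(c(600, 0), c(600, 120)), "branch", parent_id = "i1"),
    vessel_segment("b2", rbind(c(800, 0), c(800, 120)), "branch", parent_id = "i1")))
  expect_equal(max(branch_statistics(eq, 50)$histogram$rel_freq), 1)

  jc <- junction_counts(net)
  expect_equal(jc$n_junctions, 2L)
  expect_equal(jc$junctions_per_vessel, 2 / 3)
  expect_equal(junction_counts(toy_network()$segments[1:3] |>
                                 (\(s) vessel_network(ring_explant(radius = 500), s))())$n_junctions,
               0L)
})

test_that("junction merge tolerance unifies nearby attachment points", {
  ring <- ring_explant(radius = 500)
  i1 <- vessel_segment("i1", rbind(c(500, 0), c(900, 0)), "initial")
  b1 <- vessel_segment("b1", rbind(c(700, 0), c(700, 100)), "branch", parent_id = "i1")
  b2 <- vessel_segment("b2", rbind(c(703, 0), c(703, -100)), "branch", parent_id = "i1")
  net <- vessel_network(ring, list(i1, b1, b2))
  expect_equal(junction_counts(net, merge_tol = 5)$n_junctions, 1L)
  expect_equal(junction_counts(net, merge_tol = 1)$n_junctions, 2L)
})

test_that("ROI extrapolation and vessel area follow their closed forms", {
  expect_equal(roi_extrapolate_endpoints(50, 90), 200)
  expect_equal(roi_extrapolate_endpoints(123, 360), 123)
  set.seed(1)
  for (k in 1:20) {
    a <- runif(1, 1, 360); n <- rpois(1, 80)
    expect_equal(roi_extrapolate_endpoints(n, a), n * 360 / a)
  }
  expect_error(roi_extrapolate_endpoints(10, 0), class = "angioring_invalid_angle")
  expect_error(roi_extrapolate_endpoints(10, 400), class = "angioring_invalid_angle")

  expect_equal(vessel_area(1000, 360), pi, tolerance = 1e-9)
  expect_equal(vessel_area(1000, 90), 0.7854, tolerance = 1e-4)
  # annulus mode closed form
  expect_equal(vessel_area(1000, 180, mode = "annulus_sector", r_ring = 500),
               (pi / 2) * ((1500)^2 - 500^2) / 1e6)
  expect_error(vessel_area(1000, 90, mode = "annulus_sector"),
               class = "angioring_invalid_geometry")
  expect_error(vessel_area(-5, 90), class = "angioring_invalid_geometry")
})

test_that("quantify composes the per-operation values and flags non-migrated rings", {
  obs <- explant_observation("d1", "treated", "r1", 7, network = toy_network())
  q <- quantify(obs)
  v <- stats::setNames(q$value, q$parameter)
  expect_equal(unname(v["vessel_structure_pct"]), 60)
  expect_equal(unname(v["total_vessel_length"]), 1250)
  expect_equal(unname(v["mean_vessel_length"]), 250)
  expect_equal(unname(v["vessel_count"]), 3)
  expect_equal(unname(v["n_branches"]), 2)
  expect_equal(unname(v["mean_branch_length"]), 125)
  expect_equal(unname(v["n_junctions"]), 2)
  expect_equal(unname(v["migration"]), 100)
  expect_true(all(q$category %in% c("explant", "pattern", "network_properties", "sprouting")))
  # empty network: counts zero, lengths missing (not zero)
  empty <- explant_observation("d1", "treated", "r2", 7,
                               network = vessel_network(ring_explant(radius = 500)))
  qe <- quantify(empty)
  ve <- stats::setNames(qe$value, qe$parameter)
  expect_equal(unname(ve["migration"]), 0)
  expect_equal(unname(ve[c("vessel_count", "n_branches", "n_junctions", "n_loops")]),
               c(0, 0, 0, 0))
  expect_true(all(is.na(ve[c("total_vessel_length", "max_radial_outgrowth",
                             "mean_branch_length", "vessel_structure_pct")])))
})

test_that("metric invariants hold on random networks", {
  for (seed in 1:15) {
    net <- random_toy_network(seed)
    tl <- total_and_mean_vessel_length(net)
    expect_gte(tl$total, max_initial_vessel_length(net))
    expect_gte(tl$total + 1e-9, max_radial_outgrowth(net))
    # per initial vessel, path length dominates its tip's boundary distance
    for (s in net$segments) {
      if (s$kind != "initial") next
      tip <- s$polyline[nrow(s$polyline), ]
      expect_gte(s$length + 1e-9,
                 abs(sqrt(sum((tip - net$ring$center)^2)) - net$ring$radius))
    }
    # structure 100 <=> no branches <=> no junctions <=> no loops
    kinds <- vapply(net$segments, `[[`, character(1), "kind")
    if (all(kinds == "initial")) {
      expect_equal(vessel_structure_pct(net), 100)
      expect_equal(junction_counts(net)$n_junctions, 0L)
      expect_equal(count_loops(net), 0L)
    } else {
      expect_lt(vessel_structure_pct(net), 100)
      expect_gt(junction_counts(net)$n_junctions, 0L)
    }
    bs <- branch_statistics(net)
    if (bs$n_branches > 0) expect_equal(sum(bs$histogram$rel_freq), 1)
    # rigid motions leave every metric unchanged
    tr <- transform_network(net, angle = 0.7, shift = c(123, -456))
    expect_equal(total_and_mean_vessel_length(tr)$total, tl$total)
    expect_equal(max_radial_outgrowth(tr), max_radial_outgrowth(net), tolerance = 1e-9)
    expect_equal(count_loops(tr), count_loops(net))
    expect_equal(junction_counts(tr)$n_junctions, junction_counts(net)$n_junctions)
  }
  # density scales inversely with circumference
  r <- 500
  mk <- function(rr) vessel_network(ring_explant(radius = rr), list(
    vessel_segment("i1", rbind(c(rr, 0), c(rr + 100, 0)), "initial")))
  expect_equal(vessel_count_and_density(mk(2 * r))$density,
               vessel_count_and_density(mk(r))$density / 2)
})
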