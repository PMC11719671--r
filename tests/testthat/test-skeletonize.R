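# Mask handling, thinning and skeleton-to-network extraction.

disk_mask <- function(n, cx, cy, r) {
  outer(seq_len(n), seq_len(n), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

test_that("mask_pair validates shapes, pixel size and ring connectivity", {
  ring <- disk_mask(64, 32, 32, 10)
  vessel <- matrix(FALSE, 64, 64)
  expect_s3_class(mask_pair(vessel, ring, 2), "mask_pair")
  expect_error(mask_pair(vessel[1:32, ], ring, 2))
  expect_error(mask_pair(vessel, ring, 0))
  two <- ring | disk_mask(64, 10, 10, 3)
  expect_error(mask_pair(vessel, two, 2), class = "angioring_invalid_mask")
})

test_that("thinning reduces a thick bar to a one-pixel line and keeps protected pixels", {
  m <- matrix(FALSE, 40, 40)
  m[18:22, 5:35] <- TRUE  # 5-px-thick horizontal bar
  sk <- angioring:::thin_mask(m)
  # end caps erode by about half the stroke width; check the interior
  expect_true(all(colSums(sk[, 9:31]) == 1))
  expect_true(all(sk[20, 9:31]))
  prot <- matrix(FALSE, 40, 40); prot[18:22, 5] <- TRUE
  sk2 <- angioring:::thin_mask(m, protect = prot)
  expect_true(all(sk2[18:22, 5]))
})

test_that("a blank vessel mask yields an empty network and migrated = FALSE", {
  ring <- disk_mask(128, 64, 64, 30)
  mp <- mask_pair(matrix(FALSE, 128, 128), ring, 2)
  net <- extract_network(mp)
  expect_equal(length(net$segments), 0L)
  obs <- explant_observation("d", "g", "r", 7, network = net)
  expect_false(obs$migrated)
})

test_that("a rendered anastomotic loop survives the round trip", {
  net <- rendered_loop_network()
  expect_true(is_well_separated(net))
  expect_equal(count_loops(net), 1L)
  mp <- render_mask(net, pixel_size = 2)
  rec <- extract_network(mp, spur_min_length = 20)
  expect_equal(count_loops(rec), 1L)
  expect_equal(sum(vapply(rec$segments, function(s) s$kind == "initial", logical(1))), 1L)
  expect_equal(junction_counts(rec)$n_junctions, junction_counts(net)$n_junctions)
})

test_that("rendered toy network recovers counts exactly and lengths within 5%", {
  net <- toy_network()
  mp <- render_mask(net, pixel_size = 2)
  rec <- extract_network(mp, spur_min_length = 20)
  expect_equal(sum(vapply(rec$segments, function(s) s$kind == "initial", logical(1))), 3L)
  expect_equal(sum(vapply(rec$segments, function(s) s$kind == "branch", logical(1))), 2L)
  expect_equal(junction_counts(rec)$n_junctions, 2L)
  expect_equal(count_loops(rec), 0L)
  tv <- total_and_mean_vessel_length(net)$total
  rv <- total_and_mean_vessel_length(rec)$total
  expect_lt(abs(rv - tv) / tv, 0.05)
  expect_lt(abs(max_initial_vessel_length(rec) - 500) / 500, 0.05)
})

test_that("vessel components not touching the ring are discarded with a warning", {
  ring <- disk_mask(200, 100, 100, 30)
  vessel <- matrix(FALSE, 200, 200)
  vessel[99:101, 130:170] <- TRUE   # attached vessel
  vessel[20:22, 20:60] <- TRUE      # floating fragment
  mp <- mask_pair(vessel, ring, 2)
  expect_warning(net <- extract_network(mp), "not touching the ring")
  expect_equal(length(net$segments), 1L)
  expect_equal(net$segments[[1]]$kind, "initial")
})

test_that("spur pruning removes short thinning artifacts but keeps real branches", {
  ring <- disk_mask(200, 100, 100, 30)
  vessel <- matrix(FALSE, 200, 200)
  vessel[99:101, 130:190] <- TRUE     # initial vessel, ~120 um
  vessel[101:130, 159:161] <- TRUE    # real branch, ~60 um
  vessel[96:98, 174:176] <- TRUE      # 3-px nub (spur)
  mp <- mask_pair(vessel, ring, 2)
  net <- extract_network(mp, spur_min_length = 20)
  kinds <- vapply(net$segments, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "initial"), 1L)
  expect_equal(sum(kinds == "branch"), 1L)
})

test_that("mask PNG i/o round-trips and feeds extraction", {
  net <- toy_network()
  mp <- render_mask(net, pixel_size = 2)
  vp <- tempfile(fileext = ".png"); rp <- tempfile(fileext = ".png")
  write_mask_png(mp$vessel_mask, vp)
  write_mask_png(mp$ring_mask, rp)
  mp2 <- read_mask_pair(vp, rp, 2)
  expect_identical(mp2$vessel_mask, mp$vessel_mask)
  expect_identical(mp2$ring_mask, mp$ring_mask)
  rec <- extract_network(mp2)
  expect_equal(length(rec$segments), 5L)
})
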