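# The scoring core: per-parameter AAI, weighted subindices, final index,
# report assembly and the angiogenic profile.

test_that("per-parameter AAI hits its anchor points and is monotone", {
  # treatment change equal / double / absent relative to the control change
  expect_equal(parameter_aai(10, 20, 30, 40), 0)
  expect_equal(parameter_aai(10, 30, 30, 40), 1)
  expect_equal(parameter_aai(10, 10, 30, 40), -1)
  # orientation flips the sign
  expect_equal(parameter_aai(10, 30, 30, 40, orientation = -1), -1)
  # strictly increasing in the treatment change for fixed positive control change
  vals <- vapply(seq(0, 40, by = 5), function(dt) {
    parameter_aai(0, dt, 0, 10)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # invariant under affine unit rescaling (um -> mm)
  a <- parameter_aai(120, 260, 100, 180)
  b <- parameter_aai(0.120, 0.260, 0.100, 0.180)
  expect_equal(a, b)
})

test_that("degenerate control changes follow the configured policy", {
  expect_error(parameter_aai(0, 5, 10, 10, parameter = "n_loops"),
               class = "angioring_degenerate_control")
  expect_error(parameter_aai(0, 5, 10, 10), regexp = "control change is zero")
  eps <- parameter_aai(0, 5, 10, 10, degenerate_policy = "epsilon", epsilon = 1e-6)
  expect_equal(eps, (5 - 1e-6) / 1e-6)
  # both changes zero: the control-equals-treatment anchor, continuously
  expect_equal(parameter_aai(7, 7, 10, 10), 0)
  expect_true(is.na(parameter_aai(NA, 7, 10, 12)))
})

test_that("subindex aggregation implements literal and normalized weighting", {
  expect_equal(subindex_aai(c(1, 0.5), c(2, 1)), 1.25)
  expect_equal(subindex_aai(c(1, 0.5), c(2, 1), mode = "normalized"), 2.5 / 3)
  # all weights one: plain mean either way
  v <- c(-0.3, 0.9, 0.4)
  expect_equal(subindex_aai(v), mean(v))
  expect_equal(subindex_aai(v, mode = "normalized"), mean(v))
  set.seed(3)
  for (k in 1:10) {
    v <- rnorm(5); w <- runif(5, 0.5, 3)
    expect_equal(subindex_aai(v, w), sum(w * v) / 5)
    expect_equal(subindex_aai(v, w, mode = "normalized"), sum(w * v) / sum(w))
  }
  expect_error(subindex_aai(numeric(0), numeric(0)),
               class = "angioring_undefined_subindex")
})

test_that("final AAI is the mean of available subindices, order-free", {
  expect_equal(final_aai(c(explant = 0, pattern = 0, network_properties = 0,
                           sprouting = 0)), 0)
  x <- c(explant = 1, pattern = -1, network_properties = 0.5, sprouting = 0.5)
  expect_equal(final_aai(x), 0.25)
  expect_equal(final_aai(rev(x)), 0.25)
  expect_warning(res <- final_aai(c(explant = 1, pattern = NA,
                                    network_properties = 0, sprouting = 0.5)),
                 "excluding")
  expect_equal(res, 0.5)
  expect_error(suppressWarnings(final_aai(c(a = NA_real_))),
               class = "angioring_undefined_subindex")
})

test_that("compute_aai_report reproduces closed-form values on synthetic tables", {
  # treatment change = control change everywhere -> all AAI zero, final zero
  t0 <- synthetic_table(uplift = 1)
  rep0 <- compute_aai_report(t0, "treated", aai_config(aggregation = "pooled"))
  expect_true(all(abs(rep0$per_parameter_aai) < 1e-12))
  expect_equal(rep0$final_aai, 0)
  # treatment change = 2x control change -> every AAI 1, every subindex 1
  t2 <- synthetic_table(uplift = 2)
  rep2 <- compute_aai_report(t2, "treated", aai_config(aggregation = "pooled"))
  expect_true(all(abs(rep2$per_parameter_aai - 1) < 1e-12))
  expect_equal(unname(rep2$subindex_values), rep(1, 4))
  expect_equal(rep2$final_aai, 1)
  # fractional uplift u: AAI = u - 1 for every parameter
  t15 <- synthetic_table(uplift = 1.5)
  rep15 <- compute_aai_report(t15, "treated", aai_config(aggregation = "pooled"))
  expect_true(all(abs(rep15$per_parameter_aai - 0.5) < 1e-12))
  expect_equal(rep15$final_aai, 0.5, tolerance = 1e-12)
  # weights scale the subindex in literal mode
  cfgw <- aai_config(aggregation = "pooled",
                     weights = c(vessel_density = 2, n_loops = 2))
  repw <- compute_aai_report(t2, "treated", cfgw)
  # pattern: (2*1 + 1*1)/2 ; sprouting: (1 + 1 + 2*1 + 1)/4
  expect_equal(unname(repw$subindex_values["pattern"]), 1.5)
  expect_equal(unname(repw$subindex_values["sprouting"]), 1.25)
})

test_that("per-donor aggregation averages donor-level indices", {
  t1 <- synthetic_table(uplift = 2)
  t2 <- synthetic_table(uplift = 1)
  t2$donor <- "d2"
  t2$ring_id <- paste0(t2$ring_id, "_d2")
  tab <- rbind(t1, t2)
  rep_pd <- compute_aai_report(tab, "treated", aai_config(aggregation = "per_donor"))
  # donor 1 gives AAI 1, donor 2 gives 0 -> mean 0.5 per parameter
  expect_true(all(abs(rep_pd$per_parameter_aai - 0.5) < 1e-12))
  expect_equal(rep_pd$aggregation, "per_donor")
})

test_that("missing control rows and days raise classed errors", {
  tab <- synthetic_table(uplift = 2)
  no_ctrl <- tab[tab$group != "control", ]
  expect_error(compute_aai_report(no_ctrl, "treated", aai_config()),
               class = "angioring_missing_control")
  no_d7 <- tab[!(tab$group == "treated" & tab$day == 7), ]
  expect_error(compute_aai_report(no_d7, "treated", aai_config()),
               class = "angioring_missing_days")
})

test_that("angiogenic profile orders parameters by category and serializes", {
  rep2 <- compute_aai_report(synthetic_table(2), "treated",
                             aai_config(aggregation = "pooled"))
  prof <- build_profile(rep2)
  expect_s3_class(prof, "angiogenic_profile")
  cats <- unique(prof$category)
  expect_equal(cats, c("explant", "pattern", "network_properties", "sprouting"))
  expect_equal(nrow(prof), 12)
  expect_true(all(diff(prof$angle_deg) > 0))
  # all-zero report -> flat profile
  prof0 <- build_profile(compute_aai_report(synthetic_table(1), "treated",
                                            aai_config(aggregation = "pooled")))
  expect_true(all(abs(prof0$aai) < 1e-12))
  p <- plot_profile(prof)
  expect_s3_class(p, "ggplot")
  tmp <- tempfile(fileext = ".json")
  write_profile_json(prof, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$final_aai, rep2$final_aai)
  expect_equal(nrow(back$spokes), 12)
})

test_that("with unit weights and one parameter per category, final equals that parameter", {
  params <- c("migration", "vessel_structure_pct", "max_radial_outgrowth",
              "vessel_density")
  tab <- synthetic_table(uplift = 1.75)
  cfg <- aai_config(parameters = params, aggregation = "pooled")
  rep1 <- compute_aai_report(tab, "treated", cfg)
  expect_equal(unname(rep1$subindex_values),
               unname(rep1$per_parameter_aai[params]))
  expect_equal(rep1$final_aai, 0.75, tolerance = 1e-12)
})
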