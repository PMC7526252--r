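test_that("a migrant-free world has every origin at its capture site", {
  cfg <- synth_config(seed = 5, migrant_fraction = 0, n_sites = 4,
                      bats_per_site = 5)
  w <- make_world(cfg)
  expect_false(any(w$truth$is_migrant))
  expect_equal(w$truth$origin_lon,
               w$sites$lon[match(w$truth$site_id, w$sites$site_id)])
  expect_equal(w$truth$displacement_km, rep(0, nrow(w$truth)))
})

test_that("worlds are reproducible from their seed", {
  cfg <- synth_config(seed = 123, n_sites = 3, bats_per_site = 4)
  w1 <- make_world(cfg)
  w2 <- make_world(cfg)
  expect_identical(w1$stations, w2$stations)
  expect_identical(w1$bats, w2$bats)
  expect_identical(w1$truth, w2$truth)
})

test_that("migrant counts fall in the binomial 99% band", {
  cfg <- synth_config(seed = 31, n_sites = 10, bats_per_site = 20,
                      migrant_fraction = 0.3)
  w <- make_world(cfg)
  n_mig <- sum(w$truth$is_migrant)
  expect_gte(n_mig, qbinom(0.005, 200, 0.3))
  expect_lte(n_mig, qbinom(0.995, 200, 0.3))
  # and displacements are in the configured band, measured on the sphere
  d <- w$truth$displacement_km[w$truth$is_migrant]
  expect_true(all(d >= 250 - 1 & d <= 1000 + 1))
})

test_that("infeasible displacements raise a config error", {
  cfg <- synth_config(seed = 7, bbox = c(0, 34, 4, 36),
                      migrant_fraction = 1, displacement_km = 1000,
                      n_sites = 2, bats_per_site = 2, n_stations = 12)
  expect_error(make_world(cfg), "config error")
})

test_that("recent arrivals carry wing values from the capture site", {
  cfg <- synth_config(seed = 11, bbox = c(-12, 28, 30, 62),
                      migrant_fraction = 1, displacement_km = 800,
                      displacement_bearing = c(0, 180),
                      recent_arrival_fraction = 1,
                      n_sites = 4, bats_per_site = 5)
  w <- make_world(cfg)
  expect_equal(w$truth$wing_origin_lat,
               w$sites$lat[match(w$truth$site_id, w$sites$site_id)])
  expect_false(any(w$truth$wing_origin_lat == w$truth$origin_lat))
})

test_that("the tissue generator follows the configured transfer truth", {
  # with zero field, zero nugget and zero noise, tissue values are an exact
  # linear map of the deterministic surface at the origin
  cfg <- synth_config(seed = 13, migrant_fraction = 0, n_sites = 5,
                      bats_per_site = 4,
                      field = list(partial_sill = 0, range_km = 300,
                                   nugget = 0),
                      transfer_truth = list(
                        fur = c(slope = 0.62, intercept = -14.66,
                                resid_sd = 0),
                        wing = c(slope = 0.64, intercept = -14.64,
                                 resid_sd = 0)),
                      analytical_sd = 0)
  w <- make_world(cfg)
  fur <- w$bats[w$bats$tissue == "fur", ]
  s <- 38 - 2 * fur$lat
  expect_equal(fur$d2h, 0.62 * s - 14.66, tolerance = 1e-9)
})

test_that("score_pipeline tallies the confusion matrix correctly", {
  truth <- data.frame(bat_id = sprintf("b%d", 1:6),
                      is_migrant = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  perfect <- data.frame(
    bat_id = truth$bat_id,
    combined = ifelse(truth$is_migrant, "non-local", "local"))
  sc <- score_pipeline(perfect, truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)

  all_local <- data.frame(bat_id = truth$bat_id, combined = "local")
  sc2 <- score_pipeline(all_local, truth)
  expect_equal(sc2$sensitivity, 0)
  expect_equal(sc2$specificity, 1)

  # hand-built mixed table: b1 caught, b2 missed, b6 caught; b3 false alarm
  calls <- data.frame(
    bat_id = truth$bat_id,
    combined = c("non-local", "local", "non-local", "local", "local",
                 "non-local"))
  sc3 <- score_pipeline(calls, truth)
  expect_equal(as.vector(sc3$confusion),
               c(2, 1, 1, 2))  # sedentary-local, migrant-local, sed-nl, mig-nl
  expect_equal(sc3$sensitivity, 2 / 3)
  expect_equal(sc3$specificity, 2 / 3)

  bad <- data.frame(bat_id = "zz", combined = "local")
  expect_error(score_pipeline(bad, truth), "join failure")
})

test_that("the end-to-end pipeline separates sedentary and migrant bats", {
  # sedentary-only worlds: almost everyone should be called local; the
  # bat-level rate pools three replicate worlds (600 bats) so the estimate
  # is not dominated by one draw
  specs <- vapply(c(411, 412, 413), function(s) {
    cfg0 <- synth_config(seed = s, n_sites = 25, bats_per_site = 24,
                         migrant_fraction = 0)
    res0 <- run_world(cfg0)
    score_pipeline(res0$classifications, res0$world$truth)$specificity
  }, numeric(1))
  expect_gte(mean(specs), 0.90)

  # 1000 km displacement along the latitudinal gradient: most migrants are
  # detected through their fur values
  cfg1 <- synth_config(seed = 1300, bbox = c(-12, 28, 30, 62),
                       n_sites = 10, bats_per_site = 40,
                       migrant_fraction = 0.25, displacement_km = 1000,
                       displacement_bearing = c(0, 180),
                       recent_arrival_fraction = 1)
  res1 <- run_world(cfg1)
  sc1 <- score_pipeline(res1$classifications, res1$world$truth)
  expect_gte(sc1$sensitivity, 0.5)
})

test_that("isoscape plus calibration recover the true transfer function", {
  # worlds of 600 sedentary bats; the fitted fur transfer should land near
  # the generating line (slope 0.62, intercept -14.66) across seeds
  slopes <- numeric(10); intercepts <- numeric(10)
  for (i in 1:10) {
    cfg <- synth_config(seed = 500 + i, n_sites = 25, bats_per_site = 24,
                        migrant_fraction = 0)
    res <- run_world(cfg)
    expect_gte(length(unique(res$calibrators$bat_id)), 80)
    slopes[i] <- res$tfs$fur$slope
    intercepts[i] <- res$tfs$fur$intercept
  }
  expect_true(all(abs(slopes - 0.62) <= 0.15))
  expect_true(all(abs(intercepts + 14.66) <= 8))
})
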