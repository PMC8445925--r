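test_that("identical config and seed give bit-identical output", {
  cfg <- herd_config(n_individuals = 60)
  a <- simulate_herd(cfg, seed = 123)
  b <- simulate_herd(cfg, seed = 123)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
  c <- simulate_herd(cfg, seed = 124)
  expect_false(identical(a$tracks$length_cm, c$tracks$length_cm))
})

test_that("an empty herd simulates to empty records and truth", {
  s <- simulate_herd(herd_config(n_individuals = 0), seed = 1)
  expect_equal(nrow(s$tracks), 0L)
  expect_equal(nrow(s$truth), 0L)
  r <- recovery_report(s)
  expect_equal(r$n, 0L)
})

test_that("invalid configurations fail before sampling", {
  expect_error(herd_config(mix = c(calf = 0.5, juvenile = 0.5,
                                   adolescent = 0.2, adult_female = 0,
                                   old_bull = 0)))
  expect_error(herd_config(noise_fl_sd = -0.1))
  # a male curve too small to ever produce old-bull-sized feet
  expect_error(herd_config(growth = growth_params(male_h_inf_cm = 200)),
               "old-bull threshold")
})

test_that("zero-noise simulation closes the loop to numerical precision", {
  cfg <- herd_config(n_individuals = 150, noise_height_sd = 0,
                     noise_fl_sd = 0)
  sim <- simulate_herd(cfg, seed = 11)
  r <- recovery_report(sim)
  expect_lt(r$height_rmse_rel, 1e-9)
  expect_lt(r$mass_rmse_rel, 1e-9)
  expect_true(all(abs(r$freq_error_pp) == 0))
})

test_that("an all-calf zero-noise herd re-estimates heights exactly", {
  cfg <- herd_config(n_individuals = 50,
                     mix = c(calf = 1, juvenile = 0, adolescent = 0,
                             adult_female = 0, old_bull = 0),
                     noise_height_sd = 0, noise_fl_sd = 0)
  sim <- simulate_herd(cfg, seed = 2)
  est <- estimate_tracks(sim$tracks, allometry_params(rounding = "none"),
                         cfg$growth)
  truth <- sim$truth[match(paste(sim$tracks$sector, sim$tracks$letter,
                                 sep = "."), sim$truth$individual), ]
  expect_lt(max(abs(est$esh_f_cm - truth$height_cm)), 1e-9)
  expect_true(all(sim$truth$age_years < 2))
})

test_that("simulated width/length ratios respect the limb bands", {
  sim <- simulate_herd(herd_config(n_individuals = 200), seed = 9)
  wl <- sim$tracks$width_cm / sim$tracks$length_cm
  expect_true(all(wl[sim$tracks$limb == "pes"] >= 0.70 - 1e-12))
  expect_true(all(wl[sim$tracks$limb == "pes"] <= 0.96 + 1e-12))
  expect_true(all(wl[sim$tracks$limb == "manus"] >= 1.00 - 1e-12))
  expect_true(all(wl[sim$tracks$limb == "manus"] <= 1.15 + 1e-12))
  # outside the circularity tolerance the classifier recovers the limb
  guess <- classify_limb(sim$tracks$length_cm, sim$tracks$width_cm)
  decided <- guess != "unknown"
  expect_true(all(guess[decided] == sim$tracks$limb[decided]))
  expect_gt(mean(decided), 0.7)
})

test_that("trackway geometry recovers pace, stride and bearing", {
  g <- trackway_geometry(0:3, rep(0, 4))
  expect_equal(g$pace_m, rep(1, 3))
  expect_equal(g$stride_m, rep(2, 2))
  expect_equal(g$bearing_deg, 0)

  g2 <- trackway_geometry(c(0, 1), c(0, 1))
  expect_equal(g2$pace_m, sqrt(2))
  expect_equal(length(g2$stride_m), 0L)
  expect_equal(g2$bearing_deg, 45)
  expect_error(trackway_geometry(1, 1), "at least 2")
})

test_that("simulated trackways carry the configured pace/height ratio", {
  cfg <- herd_config(n_individuals = 20, noise_height_sd = 0,
                     noise_fl_sd = 0, tracks_per_individual = 4,
                     pace_fraction = 0.6)
  sim <- simulate_herd(cfg, seed = 4)
  tw <- split(seq_len(nrow(sim$tracks)), sim$tracks$trackway_id)
  for (i in tw[1:5]) {
    geom <- trackway_geometry(sim$tracks$x_m[i], sim$tracks$y_m[i])
    key <- paste(sim$tracks$sector[i[1]], sim$tracks$letter[i[1]], sep = ".")
    h <- sim$truth$height_cm[sim$truth$individual == key]
    expect_lt(max(abs(geom$pace_m / (h / 100) - 0.6)), 1e-9)
    expect_lt(max(abs(geom$stride_m - 2 * geom$pace_m[1])), 1e-9)
  }
})

test_that("class frequencies are recovered across 20 seeded replicates", {
  errs <- vapply(1:20, function(s) {
    r <- recovery_report(simulate_herd(herd_config(n_individuals = 500),
                                       seed = s))
    mean(abs(r$freq_error_pp))
  }, numeric(1))
  # mean of the per-class absolute frequency errors, in percentage points
  expect_lt(mean(errs), 2)
})

test_that("recovery refuses estimates from a different run", {
  sim <- simulate_herd(herd_config(n_individuals = 20), seed = 1)
  other <- simulate_herd(herd_config(n_individuals = 20), seed = 2)
  est <- estimate_tracks(other$tracks, allometry_params(rounding = "none"),
                         growth_params())
  attr(est, "run_id") <- other$run_id
  expect_error(recovery_report(sim, est), "different run")
})

test_that("measurement-only noise shows the convex mass bias", {
  # one track per individual so no size selection enters; lognormal noise
  # e^eps on the foot length propagates as e^(c eps) through the power law,
  # so the analytic mass bias is exp((c sd)^2 / 2) - 1
  cfg <- herd_config(n_individuals = 4000, noise_height_sd = 0,
                     noise_fl_sd = 0.05, tracks_per_individual = 1)
  r <- recovery_report(simulate_herd(cfg, seed = 8))
  analytic <- exp((2.903 * 0.05)^2 / 2) - 1
  expect_gt(r$mass_bias, 0)
  expect_lt(abs(r$mass_bias - analytic), 0.007)
  expect_lt(abs(r$height_bias), 0.003)
})
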