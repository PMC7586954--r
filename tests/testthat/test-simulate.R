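test_that("LAI schedules are staged, bounded and nondecreasing", {
  sch <- lai_schedule(data.frame(doy = c(160, 175, 190), lai = c(1.5, 2.5, 3.5)))
  expect_equal(lai_at(sch, 159), 1.5)  # before first stage: first value
  expect_equal(lai_at(sch, 176), 2.5)
  expect_equal(lai_at(sch, 300), 3.5)
  expect_equal(lai_at(lai_schedule(3.5), 200), 3.5)
  expect_error(lai_schedule(data.frame(doy = 1:6, lai = 1:6)), "at most 5")
  expect_error(lai_schedule(data.frame(doy = c(1, 2), lai = c(3, 2))),
               "nondecreasing")
  expect_error(lai_schedule(9), "\\(0, 8\\]")
})

test_that("a quiescent step leaves the state unchanged", {
  cfg <- fixture_config()
  state <- init_sim_state(cfg)
  met <- data.frame(doy = 160, hour = 2, par = 0, t_air = 25, vpd = 0.5,
                    wind = 2, water_input = 0)
  st2 <- step_halfhour(state, met, cfg)
  expect_equal(st2$theta, state$theta)
  expect_equal(unname(st2$record["e_c"]), 0)
  expect_equal(unname(st2$record["transp_mm"]), 0)
})

test_that("infiltration is bucket-filling to field capacity, top down", {
  cfg <- fixture_config()
  state <- init_sim_state(cfg)
  # give layer 1 twelve mm of room below field capacity
  state$theta[1] <- state$theta_fc[1] - 12 / 300
  met <- data.frame(doy = 160, hour = 6, par = 0, t_air = 25, vpd = 0.5,
                    wind = 2, water_input = 10)
  st2 <- step_halfhour(state, met, cfg)
  # all 10 mm retained in layer 1; nothing reaches layer 2
  expect_equal((st2$theta[1] - state$theta[1]) * 300, 10, tolerance = 1e-9)
  expect_equal(st2$theta[-1], state$theta[-1])
  expect_equal(unname(st2$record["drain_mm"]), 0)
})

test_that("the season loop is deterministic, complete and conserves water", {
  f <- fixture_forcing_short(n_days = 10)
  cfg <- fixture_config()
  sim1 <- run_simulation(cfg, f)
  expect_equal(nrow(sim1$steps), 10 * 48)
  sim2 <- run_simulation(cfg, f)
  expect_identical(sim1$steps, sim2$steps)   # bitwise determinism
  expect_lt(abs(sim1$water_balance$residual), 1e-6)
  # per-layer theta within physical bounds everywhere
  for (l in 1:5) {
    th <- sim1$steps[[paste0("theta_", l)]]
    expect_true(all(th >= cfg$soil[[l]]$theta_r & th <= cfg$soil[[l]]$theta_s))
  }
  expect_true(all(sim1$steps$psi_leaf <= 0))
  expect_true(all(sim1$steps$e_c <= sim1$steps$e_crit + 1e-9))
})

test_that("forcing gaps and truncated windows are rejected", {
  f <- fixture_forcing_short(n_days = 3)
  expect_error(run_simulation(fixture_config(), f[-25, ]), "gaps")
  expect_error(run_simulation(fixture_config(), f[1:100, ]), "steps")
})

test_that("predawn leaf potential relaxes to the soil potential", {
  f <- fixture_forcing_short(n_days = 6)
  cfg <- fixture_config()
  sim <- run_simulation(cfg, f)
  s <- sim$steps[sim$steps$hour == 4, ]
  psis <- as.matrix(s[paste0("psi_soil_", 1:5)])
  # predawn psi_leaf within 0.05 MPa of the conductance-weighted soil psi
  # (uniform-profile check: within the min/max envelope plus margin)
  expect_true(all(s$psi_leaf <= apply(psis, 1, max) + 1e-6))
  expect_true(all(abs(s$psi_leaf - rowMeans(psis)) < 0.05))
})

test_that("well-watered forcing never hits the supply cap; deficit cuts transpiration", {
  ww <- gen_meteo(n_days = 8, seed = 7,
                  irrigation = list(interval_days = 1, depth_mm = 18,
                                    hour = 6))
  cfg <- fixture_config()
  sim_ww <- run_simulation(cfg, ww)
  expect_equal(sum(sim_ww$steps$capped), 0)
  wl <- ww
  wl$water_input <- wl$water_input * 0.2
  sim_wl <- run_simulation(cfg, wl)
  expect_lt(sim_wl$water_balance$transpiration,
            sim_ww$water_balance$transpiration)
})

test_that("rmse matches hand arithmetic", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(1, 4)), sqrt(2))
  expect_equal(rmse(3, 1), 2)
  expect_error(rmse(1:3, 1:2), "mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "at least one")
})

test_that("root-ratio calibration recovers the generating ratio", {
  f <- fixture_forcing_short(n_days = 12, depth_mm = 8, interval_days = 3)
  dp <- fixture_params()
  g_true <- dp$species
  g_true$root_to_leaf_area <- 2.5
  cfg <- sim_config(g_true, fixture_lc_hyd(), lai = 3.5,
                    root_profile = dp$root_profile)
  sim_true <- run_simulation(cfg, f)
  obs <- gen_observed_moisture(sim_true, sigma = 0, n_timepoints = 6,
                               seed = 2)
  cal <- calibrate_root_ratio(cfg, f, obs, ratios = c(1.5, 2.0, 2.5, 3.0))
  expect_equal(cal$best_ratio, 2.5)
  expect_equal(cal$profile$rmse[cal$profile$ratio == 2.5], 0,
               tolerance = 1e-12)
  # error grows monotonically away from the optimum
  expect_true(all(diff(cal$profile$rmse[cal$profile$ratio <= 2.5]) <= 0))
  expect_true(all(diff(cal$profile$rmse[cal$profile$ratio >= 2.5]) >= 0))
  expect_error(calibrate_root_ratio(cfg, f, obs, ratios = 2.5), "2 candidate")
  expect_error(calibrate_root_ratio(cfg, f, obs[0, ], c(1, 2)), "empty")
})

test_that("forcing IO round-trips including ISO timestamps", {
  f <- fixture_forcing_short(n_days = 2)
  path <- tempfile(fileext = ".csv")
  write_forcing(f, path)
  f2 <- read_forcing(path)
  expect_equal(f2$par, f$par, tolerance = 1e-9)
  # timestamp variant
  f3 <- f
  ts <- as.POSIXct("2012-06-08 00:00", tz = "UTC") +
    (seq_len(nrow(f)) - 1) * 1800
  f3 <- cbind(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
              f[, -(1:2)])
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(f3, path3, row.names = FALSE)
  f4 <- read_forcing(path3)
  expect_equal(f4$doy[1], 160)
  expect_equal(f4$hour[1:3], c(0, 0.5, 1))
})
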