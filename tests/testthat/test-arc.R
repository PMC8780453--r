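test_that("intermediate setpoint interpolates between measured and target", {
  expect_equal(intermediate_setpoint(95, 95, 0.5), 95)
  expect_equal(intermediate_setpoint(75, 95, 0.5), 85)
  expect_equal(intermediate_setpoint(75, 95, 1), 95)
  expect_equal(intermediate_setpoint(80, 95, 0.25), 83.75)
  expect_error(intermediate_setpoint(96, 95), "target")
})

test_that("volume percent error spans [0, 1] and decreases in measured MAP", {
  expect_equal(volume_percent_error(85, 85, wb_curve), 0)
  expect_equal(volume_percent_error(90, 85, wb_curve), 0)
  floor_p <- pv_pressure(wb_curve$v_min, wb_curve)
  expect_equal(volume_percent_error(floor_p, 95, wb_curve), 1)
  maps <- seq(40, 94, length.out = 30)
  errs <- vapply(maps, volume_percent_error, numeric(1),
                 map_set = 95, curve = wb_curve)
  expect_true(all(diff(errs) < 0))
  expect_true(all(errs >= 0 & errs <= 1))
})

test_that("the flow-rate law interpolates between the rate bounds", {
  cfg <- arc_config()
  expect_equal(arc_flow_rate(1, cfg, 1), 1200)
  expect_equal(arc_flow_rate(0, cfg, 1), cfg$q_min)
  cfg2 <- arc_config(q_min = 100, q_max = 1200)
  expect_equal(arc_flow_rate(0.5, cfg2, 1), 650)
  # correction factor scales multiplicatively, then clamps to the bounds
  expect_equal(arc_flow_rate(0.5, cfg2, 2), 1200)
  expect_equal(arc_flow_rate(0.5, cfg2, 0.1), 100)
  expect_equal(arc_flow_rate(0.2, cfg2, 1.5), 1.5 * (1100 * 0.2 + 100))
})

test_that("correction factor follows the multiplicative recursion", {
  expect_equal(update_correction_factor(1, 10, 10, 1), 1)
  expect_equal(update_correction_factor(1, 20, 10, 1), 2)
  expect_equal(update_correction_factor(1, 20, 10, 2), 4)
  expect_equal(update_correction_factor(2, 5, 10, 1), 1)
  # clamped at both ends
  expect_equal(update_correction_factor(8, 30, 10, 1), 10)
  expect_equal(update_correction_factor(0.2, 1, 10, 1), 0.1)
  expect_warning(out <- update_correction_factor(1.5, 10, 0, 1), "skip")
  expect_equal(out, 1.5)
  # deviation-scaled variant halves the departure from unity
  expect_equal(update_correction_factor(1, 20, 10, 0.5, mode = "deviation"),
               1.5)
})

test_that("predicted time follows the curve volume and inverse rate", {
  expect_equal(predicted_time(80, 80, 300, wb_curve), 0)
  t1 <- predicted_time(75, 85, 300, wb_curve)
  expect_equal(predicted_time(75, 85, 600, wb_curve), t1 / 2)
  expect_equal(t1, 60 * (pv_volume(85, wb_curve) - pv_volume(75, wb_curve)) / 300)
  expect_error(predicted_time(75, 85, 0, wb_curve), "rate")
})

test_that("predicted time matches the plant transit time at a fixed rate", {
  cfg <- plant_config(pulse_pressure = 0)
  s <- new_plant(cfg, map_init = 75)$state
  cmd <- actuator_commands(infusion_rate = 400)
  n <- 0
  while (s$central_map < 85) {
    s <- plant_step(s, cmd, cfg)
    n <- n + 1
  }
  expect_equal(n * cfg$dt, predicted_time(75, 85, 400, wb_curve),
               tolerance = 2 * cfg$dt / predicted_time(75, 85, 400, wb_curve))
})

test_that("hemorrhage criterion fires exactly at the stated error boundary", {
  expect_true(check_suspected_hemorrhage(20, 10))
  expect_false(check_suspected_hemorrhage(19, 10))
  expect_true(check_suspected_hemorrhage(2, 1))
  expect_false(check_suspected_hemorrhage(1.999999, 1))
  expect_true(check_suspected_hemorrhage(15, 10, threshold = 0.5))
  expect_false(check_suspected_hemorrhage(14.9, 10, threshold = 0.5))
})

test_that("a no-hemorrhage resuscitation reaches the termination band", {
  res <- run_resuscitation(hypo_plant(75), arc_config())
  expect_true(res$reached_target)
  expect_gte(res$final_map, 0.995 * 95)
  # commanded rates never leave [q_min, q_max]
  active <- res$rate_trace$rate[-nrow(res$rate_trace)]
  expect_true(all(active >= 50 & active <= 1200))
  # infused volume accounts exactly for the pressure rise
  dv <- pv_volume(res$final_map, wb_curve) - pv_volume(75, wb_curve)
  expect_equal(res$total_infused, dv, tolerance = 0.01)
  expect_equal(nrow(res$flag_intervals), 0)
})

test_that("a start at or above the target returns immediately with no volume", {
  res <- run_resuscitation(hypo_plant(95), arc_config())
  expect_true(res$reached_target)
  expect_equal(res$total_infused, 0)
  expect_lte(res$duration, 2)
})

test_that("the suspected-hemorrhage flag forces the maximum rate", {
  res <- run_resuscitation(hypo_plant(75), arc_config(), hem_rate = 360)
  expect_true(res$reached_target)
  rt <- res$rate_trace
  expect_true(any(rt$flag))
  expect_true(all(rt$rate[rt$flag] == 1200))
  expect_gt(nrow(res$flag_intervals), 0)
})

test_that("closed loop matches an open-loop rate integration oracle", {
  # with the correction factor frozen at 1, no pulse, a one-sample MAP
  # window, and no hemorrhage, the closed-loop engine must reproduce the
  # rate sequence of a plain arithmetic integration of the rate law on the
  # 1 Hz grid
  cfgp <- plant_config(pulse_pressure = 0, map_window_s = 0.02)
  cfga <- arc_config(cf_min = 1, cf_max = 1)
  res <- run_resuscitation(new_plant(cfgp, map_init = 75), cfga)

  v <- pv_volume(75, wb_curve)
  rates <- numeric(0)
  mi <- NA_real_
  repeat {
    wm <- pv_pressure(v, wb_curve)
    if (wm >= 0.995 * 95) break
    if (is.na(mi) || wm >= mi) {
      mi <- wm + 0.5 * (95 - wm)
      v_set <- pv_volume(mi, wb_curve)
      verr <- (v_set - v) / v_set
      rate <- min(max((1200 - 50) * verr + 50, 50), 1200)
    }
    rates <- c(rates, rate)
    v <- v + rate / 60
  }
  got <- res$rate_trace$rate
  got <- got[got > 0]
  expect_equal(length(got), length(rates))
  expect_equal(got, rates, tolerance = 1e-9)
  expect_false(any(res$rate_trace$flag))
})

test_that("convergence holds across random monotone plants", {
  set.seed(23)
  for (k in 1:5) {
    curve <- random_pv_curve()
    plant <- new_plant(plant_config(curve = curve), map_init = 75)
    res <- run_resuscitation(plant, arc_config())
    expect_true(res$reached_target)
    expect_gte(res$final_map, 0.995 * 95)
    dv <- pv_volume(res$final_map, curve) - pv_volume(75, curve)
    expect_equal(res$total_infused, dv, tolerance = 0.05)
  }
})
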