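test_that("bundled scenario files parse into the expected structures", {
  s1 <- bundled_scenario(1)
  expect_s3_class(s1, "scenario_spec")
  expect_length(s1$phases, 3)
  expect_equal(s1$infusate, "whole_blood")

  s5 <- bundled_scenario(5)
  expect_length(s5$phases, 5)
  # simultaneous complications: the hemorrhage from interval 4 is still
  # running when interval 5 loosens the tourniquet
  expect_equal(s5$phases[[4]]$set_hem, 240)
  expect_false(s5$phases[[4]]$stop_hem_on_end)
  expect_equal(s5$phases[[5]]$loosen, 0.55)
  expect_true(s5$phases[[5]]$stop_hem_on_end)

  for (k in 2:4) expect_length(bundled_scenario(k)$phases, 5)
})

test_that("malformed scenario files fail with the offending key named", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: bad", "infusate: whole_blood", "phases:",
               "  - name: p1", "    internal_hemorhage: 100",
               "    until: {time: 10}"), path)
  expect_error(load_scenario(path), "internal_hemorhage")

  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: bad2", "infusate: whole_blood", "typo_key: 1",
               "phases: []"), path2)
  expect_error(load_scenario(path2), "typo_key")

  path3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: bad3", "infusate: whole_blood", "phases:",
               "  - name: p1"), path3)
  expect_error(load_scenario(path3), "until")

  expect_error(load_scenario("no/such/file.yaml"), "no such file")
})

test_that("phase constructors validate triggers and rates", {
  expect_error(scenario_phase("p", until = list(bogus = 1)), "until")
  expect_error(scenario_phase("p", until = list(event = "not_a_kind")),
               "event kind")
  expect_error(scenario_phase("p", until = list(time = -5)), "numeric")
  expect_error(scenario_phase("p", until = list(time = 10),
                              loosen_tourniquet = 1.5), "loosen")
})

test_that("identical seeds reproduce a noisy scenario bit for bit", {
  cfgp <- plant_config(noise_sd = 0.5)
  s1 <- bundled_scenario(1)
  a <- run_scenario(s1, plant_cfg = cfgp, seed = 99)
  b <- run_scenario(s1, plant_cfg = cfgp, seed = 99)
  expect_identical(a$telemetry, b$telemetry)
  expect_identical(a$events, b$events)
  c_ <- run_scenario(s1, plant_cfg = cfgp, seed = 100)
  expect_false(identical(a$telemetry, c_$telemetry))
})

test_that("fluid balance equals the plant volume change at every tick", {
  log <- run_scenario(bundled_scenario(1))
  fb <- fluid_balance(log)
  dv <- log$telemetry$v_vessel - pv_volume(95, wb_curve)
  expect_lt(max(abs(fb$fluid_balance - dv)), 1e-6)
  # matches the telemetry column the engine logged
  expect_equal(fb$fluid_balance, log$telemetry$fluid_balance)
})

test_that("scenario 1 loses fluid early and recovers during resuscitation", {
  log <- run_scenario(bundled_scenario(1))
  fb <- fluid_balance(log)$fluid_balance
  b <- log$intervals
  t <- log$telemetry$t
  expect_lt(min(fb), -300)                       # deficit from the bleeds
  expect_lt(fb[max(which(t <= b[3]))], -300)     # still down entering ARC
  expect_gt(fb[length(fb)], -50)                 # mostly restored at the end
  # the windowed MAP settles near 75 at the first boundary
  expect_equal(log$telemetry$map_windowed[max(which(t <= b[2]))], 75,
               tolerance = 0.02)
})

test_that("interval binning aligns channels onto normalized coordinates", {
  log <- run_scenario(bundled_scenario(1))
  expect_error(bin_intervals(log, n_bins = 5), "3")
  bi <- bin_intervals(log, n_bins = 3)
  expect_equal(nrow(bi$summary), 3)
  expect_true(all(diff(bi$edges) > 0))
  expect_gte(min(bi$data$tau), 0)
  expect_lte(max(bi$data$tau), 3)
  # every telemetry row lands in a bin and bins partition the record
  expect_equal(sort(unique(bi$data$interval)), 1:3)
  # cuff is untouched during the initial hemorrhage interval
  expect_equal(bi$summary$cuff_pressure[1], 0)
  log5 <- run_scenario(bundled_scenario(5))
  expect_equal(nrow(bin_intervals(log5, n_bins = 5)$summary), 5)
})

test_that("heatmap export normalizes, pads, and round-trips", {
  out <- export_heatmap(list(rep(1200, 10)))
  expect_equal(unname(out$matrix[1, ]), rep(1, 10))
  traces <- list(a = rep(600, 5), b = rep(300, 8), c = rep(1200, 3))
  hm <- export_heatmap(traces)
  expect_equal(dim(hm$matrix), c(3, 8))
  expect_equal(sum(is.na(hm$matrix)), 3 + 0 + 5)
  expect_equal(unname(hm$matrix[2, 1]) * 1200, 300)
  expect_equal(hm$meta$durations_s, c(4, 7, 2))
  expect_error(export_heatmap(list()), "no traces")
  # files written alongside scaling metadata
  base <- file.path(withr::local_tempdir(), "hm")
  export_heatmap(traces, path = base)
  expect_true(file.exists(paste0(base, ".csv")))
  meta <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(meta$q_ref, 1200)
})

test_that("the benchmark matrix covers all eight conditions", {
  tab <- arc_test_matrix()
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$infusate == "whole_blood"), 6)
  expect_setequal(tab$scaling_factor[tab$infusate == "whole_blood" &
                                       tab$hem_rate == 0], c(0.5, 1, 2))
  expect_setequal(tab$hem_rate[tab$infusate == "whole_blood" &
                                 tab$scaling_factor == 1], c(0, 120, 240, 360))
  expect_setequal(tab$hem_rate[tab$infusate == "crystalloid"], c(0, 240))
  expect_error(run_arc_matrix("nope"), "unknown condition")
})

test_that("the matrix runner produces per-replicate traces and summaries", {
  out <- run_arc_matrix("wb_hem_240", replicates = 2, seed = 5)
  expect_equal(nrow(out$results), 2)
  expect_true(all(out$results$reached_target))
  expect_length(out$rate_traces, 2)
  expect_true(all(out$results$final_map >= 0.995 * 95))
})
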