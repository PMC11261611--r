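test_that("array layout is deterministic and honours the requested design", {
  lay <- c(TAS1R2_R3 = 11, TAS1R1_R3 = 6, MOCK = 6, YC_CONTROL = 3)
  a1 <- make_array(lay, seed = 7)
  a2 <- make_array(lay, seed = 7)
  expect_identical(a1, a2)
  expect_equal(sum(a1$receptor == "TAS1R2_R3"), 11)
  expect_equal(nrow(a1), sum(lay))
  expect_true(all(a1$position_delay >= 0 & a1$position_delay <= 4))
  # raising the pixel floor above the QC threshold leaves no failing spot
  a3 <- make_array(lay, seed = 7, pixel_range = c(20, 60))
  expect_equal(sum(a3$pixel_count < 15), 0)
  expect_error(make_array(c(TAS1R2_R3 = 0)), "zero replicates")
})

test_that("trace simulation is bit-identical under a fixed seed", {
  sc <- preset_scenario("fig2_sucrose_series", seed = 3)
  t1 <- simulate_traces(sc$spots, sc$models, sc$flow_config, sc$schedule,
                        sc$noise, seed = 3)
  t2 <- simulate_traces(sc$spots, sc$models, sc$flow_config, sc$schedule,
                        sc$noise, seed = 3)
  expect_identical(t1$traces, t2$traces)
})

test_that("controls behave: YC flat, mock dips, zero input gives baseline", {
  spots <- data.frame(spot_id = c("m1", "yc1", "sw1"),
                      receptor = c("MOCK", "YC_CONTROL", "TAS1R2_R3"),
                      pixel_count = 40, position_delay = 0,
                      stringsAsFactors = FALSE)
  models <- list(TAS1R2_R3 = receptor_model(
    amplitude = 1, ligands = list(sucrose = list(ec50 = 35, hill = 1))))
  fc <- flow_config(50, 300, 300)
  sched <- simple_schedule(60, "sucrose", 300) # high osmolarity
  nz <- noise_config(channel_cv = 0, amp_sdlog = 0, dip_gamma = 0.05)
  ts <- simulate_traces(spots, models, fc, sched, nz, seed = 1)
  ratios <- compute_ratio(ts)

  # sensor control: ratio exactly constant without noise
  expect_lt(diff(range(ratios$yc1$ratio)), 1e-12)
  # mock: ratio dips below its baseline during exposure
  expect_lt(min(ratios$m1$ratio), ratios$m1$ratio[1] - 1e-4)
  # sweet spot still peaks above baseline despite the dip
  expect_gt(max(ratios$sw1$ratio), ratios$sw1$ratio[1] + 0.05)

  # zero ligand, zero noise: channels sit exactly at their baselines
  sched0 <- injection_schedule(60, "blank", list(numeric(0)))
  ts0 <- simulate_traces(spots, models, fc, sched0, nz, seed = 1)
  expect_true(all(ts0$traces$intensity[ts0$traces$channel == "CFP"] == 1000))
  expect_true(all(ts0$traces$intensity[ts0$traces$channel == "YFP"] == 1000))
})

test_that("zero-noise responses grow monotonically with dose below saturation", {
  sc <- preset_scenario("fig2_sucrose_series", seed = 1)
  sc$noise <- noise_config(channel_cv = 0, amp_sdlog = 0)
  res <- suppressMessages(run_dose_response(sc, seed = 1))
  by_dose <- tapply(res$table$iratio, res$table$dose, mean)
  expect_true(all(diff(by_dose[order(as.numeric(names(by_dose)))]) > 0))
})

test_that("a repeated saturating dose desensitizes the receptor", {
  spots <- data.frame(spot_id = "b1", receptor = "TAS2R43", pixel_count = 40,
                      position_delay = 0, stringsAsFactors = FALSE)
  models <- list(TAS2R43 = receptor_model(
    amplitude = 0.5, desens_factor = 0.6,
    ligands = list(saccharine = list(ec50 = 0.3, hill = 1))))
  fc <- flow_config(50, 300, 300)
  sched <- simple_schedule(c(60, 360), "saccharine", c(10, 10))
  nz <- noise_config(channel_cv = 0, amp_sdlog = 0, dip_gamma = 0)
  ts <- simulate_traces(spots, models, fc, sched, nz, seed = 1)
  rt <- compute_ratio(ts)[[1]]
  ir <- iratio_response(rt, sched, window_length = 180)
  expect_lt(ir$iratio[2], ir$iratio[1])
  expect_equal(ir$iratio[2] / ir$iratio[1], 0.6, tolerance = 0.05)
})

test_that("an antagonist at [I] = Ki doubles the effective EC50 at hill 1", {
  fc <- flow_config(50, 300, 300)
  prof <- simulate_exposure(fc, 0, dt = 0.2, duration = 600)
  times <- prof$times
  m_ant <- receptor_model(ligands = list(saccharine = list(ec50 = 2, hill = 1)),
                          antagonists = list(cyclamate = list(ki = 5)))
  m_shift <- receptor_model(ligands = list(saccharine = list(ec50 = 4, hill = 1)))
  sched_mix <- injection_schedule(0, "mix", list(c(saccharine = 6, cyclamate = 5)))
  sched_pure <- injection_schedule(0, "pure", list(c(saccharine = 6)))
  c_mix <- receptomics:::receptor_response_curve(m_ant, sched_mix, prof$concentration,
                                                times, 0.2)
  c_dbl <- receptomics:::receptor_response_curve(m_shift, sched_pure, prof$concentration,
                                                 times, 0.2)
  # at the plateau the competitive shift equals a doubled EC50
  expect_equal(max(c_mix), max(c_dbl), tolerance = 5e-3)
})

test_that("schedules reject invalid inputs and presets encode the experiments", {
  expect_error(injection_schedule(c(300, 60), c("a", "b"),
                                  list(numeric(0), numeric(0))),
               "increasing")
  expect_error(injection_schedule(c(60, 120), c("a", "b"),
                                  list(numeric(0), numeric(0))),
               "spacing")
  expect_error(simulate_traces(make_array(c(MOCK = 5)), list(),
                               flow_config(),
                               injection_schedule(60, "x", list(c(sucrose = -1))),
                               seed = 1),
               "negative|non-negative")
  expect_error(preset_scenario("nope"), "unknown preset")

  # sucrose series: ascending doses ending at 100 mM
  sc <- preset_scenario("fig2_sucrose_series")
  expect_equal(sc$doses, c(1, 3, 10, 30, 100))
  # blocking preset: saccharine, mixture, saccharine, cyclamate in order
  fb <- preset_scenario("fig4_blocking")
  ids <- vapply(fb$schedule, `[[`, character(1), "sample_id")
  expect_equal(ids[4:7], c("saccharine_10mM", "saccharine_10mM_cyclamate_20mM",
                           "saccharine_10mM", "cyclamate_20mM"))
  # calibration preset carries no receptor spots
  cal <- preset_scenario("table1_calibration")
  expect_equal(nrow(cal$spots), 0)
})
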