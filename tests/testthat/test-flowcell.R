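test_that("theoretical exposure is loop volume over flow rate, in seconds", {
  expect_equal(theoretical_exposure(flow_config(50, 300, 300)), 60)
  expect_equal(theoretical_exposure(flow_config(50, 1000, 100)), 600)
  expect_error(flow_config(50, 0, 300), "injection_volume")
  expect_error(flow_config(50, 300, -1), "flow_rate")
  # optional effective loop volume override
  cfg <- flow_config(50, 1000, 100, effective_loop_volume = 940)
  expect_equal(theoretical_exposure(cfg), 564)
})

test_that("a long plug saturates the cell and repeated injections reproduce", {
  cfg <- flow_config(50, 300, 300)
  prof <- simulate_exposure(cfg, valve_times = 0, dt = 0.1)
  expect_gte(max(prof$concentration), 0.99)
  expect_true(all(prof$concentration >= 0 & prof$concentration <= 1))
  # washout: concentration returns to ~0 at the end of the window
  expect_lt(prof$concentration[length(prof$concentration)], 1e-3)

  # time invariance: two identical injections 600 s apart give identical
  # peaks after a time shift
  prof2 <- simulate_exposure(cfg, valve_times = c(60, 660), dt = 0.1,
                             duration = 960)
  i1 <- which.min(abs(prof2$times - 60)) + 0:2399   # 240 s around injection 1
  i2 <- which.min(abs(prof2$times - 660)) + 0:2399  # same window, injection 2
  expect_lt(max(abs(prof2$concentration[i1] - prof2$concentration[i2])), 1e-9)
})

test_that("simulated fwhm equals the plug duration once the plateau is reached", {
  # holds for any number of dispersion stages when tailing is off
  for (nt in 1:5) {
    cfg <- flow_config(50, 300, 300, n_tanks = nt)
    prof <- simulate_exposure(cfg, valve_times = 0, dt = 0.1)
    m <- exposure_metrics(prof, cfg)
    expect_equal(m$fwhm, 60, tolerance = 0.5)
  }
})

test_that("fwhm of the 50 uL / 300 uL / 600 uL/min condition is 30 s", {
  cfg <- flow_config(50, 300, 600)
  prof <- simulate_exposure(cfg, valve_times = 0, dt = 0.1)
  m <- exposure_metrics(prof, cfg)
  expect_equal(m$theoretical_exposure, 30)
  expect_equal(m$fwhm, 30, tolerance = 0.5)
  expect_gt(m$max_rise, 0)
  expect_lt(m$max_fall, 0)
})

test_that("a single-injection profile conserves the injected mass", {
  cfg <- flow_config(50, 300, 600)
  prof <- simulate_exposure(cfg, valve_times = 0, dt = 0.1)
  area <- sum(prof$concentration) * 0.1
  expect_equal(area, theoretical_exposure(cfg), tolerance = 0.01 * 30)
})

test_that("peak metrics match analytic shapes", {
  tt <- seq(0, 200, by = 0.1)
  # ideal boxcar of width 40
  box <- list(times = tt, concentration = as.numeric(tt >= 50 & tt < 90))
  expect_equal(exposure_metrics(box)$fwhm, 40, tolerance = 0.2)
  # symmetric triangle with half-base 30: fwhm = 30
  tri <- list(times = tt, concentration = pmax(0, 1 - abs(tt - 100) / 30))
  expect_equal(exposure_metrics(tri)$fwhm, 30, tolerance = 0.2)
  # flat profile has no peak
  expect_error(exposure_metrics(list(times = tt, concentration = rep(0, length(tt)))),
               "flat")
})

test_that("rise steepens with flow and tailing slows the fall", {
  rises <- vapply(c(100, 300, 600, 900), function(fl) {
    cfg <- flow_config(50, 300, fl)
    exposure_metrics(simulate_exposure(cfg, 0, dt = 0.1), cfg)$max_rise
  }, numeric(1))
  expect_true(all(diff(rises) >= 0))

  cfg_t <- flow_config(50, 300, 300, tailing_fraction = 0.2, tailing_tau = 40)
  m <- exposure_metrics(simulate_exposure(cfg_t, 0, dt = 0.1), cfg_t)
  expect_lt(abs(m$max_fall), m$max_rise)
})

test_that("the calibration table covers the full condition grid", {
  tab <- calibration_table(cell_volumes = 50, injection_volumes = c(300, 1000),
                           flow_rates = c(300, 600), dt = 0.5)
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("cell_volume", "injection_volume", "flow_rate",
                      "theoretical_exposure_s", "fwhm_s", "max_rise_pct_s",
                      "max_fall_pct_s"))
  r <- tab[tab$injection_volume == 300 & tab$flow_rate == 300, ]
  expect_equal(r$theoretical_exposure_s, 60)
  expect_equal(r$fwhm_s, 60, tolerance = 1)
})
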