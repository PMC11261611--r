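test_that("QC removes dim spots and thin receptor groups, strictly", {
  spots <- data.frame(
    spot_id = sprintf("s%02d", 1:12),
    receptor = c(rep("TAS1R2_R3", 6), rep("TAS2R43", 5), "MOCK"),
    pixel_count = c(14, 15, 30, 30, 30, 30, rep(30, 5), 30),
    position_delay = 0, stringsAsFactors = FALSE)
  kept <- suppressMessages(qc_filter(spots))
  # 14 pixels removed, 15 retained (threshold is strict "less than")
  expect_false("s01" %in% kept$spot_id)
  expect_true("s02" %in% kept$spot_id)
  # sweet group survives with exactly 5 replicates; MOCK group of 1 dropped
  expect_equal(sum(kept$receptor == "TAS1R2_R3"), 5)
  expect_equal(sum(kept$receptor == "TAS2R43"), 5)
  expect_false("MOCK" %in% kept$receptor)
  # a group falling to 4 survivors is removed entirely
  spots2 <- spots[spots$receptor == "TAS2R43", ]
  spots2$pixel_count[1] <- 10
  expect_error(suppressMessages(qc_filter(spots2)), "every spot")
  # idempotence
  expect_identical(suppressMessages(qc_filter(kept)), kept)
})

test_that("constant channels give a constant ratio and scaling cancels", {
  tt_c <- seq(0, 600, by = 2)
  tt_y <- tt_c + 1
  mk_ts <- function(scale = 1) {
    structure(list(
      traces = data.frame(
        time_s = c(tt_c, tt_y),
        spot_id = "s1",
        channel = rep(c("CFP", "YFP"), c(length(tt_c), length(tt_y))),
        intensity = c(rep(1000, length(tt_c)), rep(2000, length(tt_y))) * scale,
        stringsAsFactors = FALSE),
      spots = data.frame(spot_id = "s1", receptor = "MOCK", pixel_count = 30,
                         position_delay = 0, stringsAsFactors = FALSE),
      schedule = injection_schedule(60, "x", list(numeric(0))),
      flow_config = flow_config()), class = "trace_set")
  }
  r1 <- compute_ratio(mk_ts())[[1]]
  expect_true(all(abs(r1$ratio - 2) < 1e-12))
  # common-factor invariance of the whole pipeline statistic
  r2 <- compute_ratio(mk_ts(scale = 3.7))[[1]]
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  ir1 <- iratio_response(r1, mk_ts()$schedule, window_length = 180)
  ir2 <- iratio_response(r2, mk_ts()$schedule, window_length = 180)
  expect_equal(ir1$iratio, ir2$iratio, tolerance = 1e-12)
  # non-positive intensities are a data error naming the spot
  bad <- mk_ts()
  bad$traces$intensity[5] <- 0
  expect_error(compute_ratio(bad), "s1")
})

test_that("interleaved sampling is removed by interpolation", {
  # slowly varying calcium signal rendered on interleaved channel grids
  tt_c <- seq(0, 600, by = 2)
  tt_y <- tt_c + 1
  s_fun <- function(t) 0.3 * exp(-(t - 300)^2 / (2 * 60^2))
  ts <- structure(list(
    traces = data.frame(
      time_s = c(tt_c, tt_y),
      spot_id = "s1",
      channel = rep(c("CFP", "YFP"), c(length(tt_c), length(tt_y))),
      intensity = c(1000 * (1 - 0.15 * s_fun(tt_c)),
                    1000 * (1 + 0.15 * s_fun(tt_y))),
      stringsAsFactors = FALSE),
    spots = data.frame(spot_id = "s1", receptor = "TAS1R2_R3",
                       pixel_count = 30, position_delay = 0,
                       stringsAsFactors = FALSE),
    schedule = injection_schedule(60, "x", list(numeric(0))),
    flow_config = flow_config()), class = "trace_set")
  rt <- compute_ratio(ts)[[1]]
  analytic <- (1 + 0.15 * s_fun(rt$times)) / (1 - 0.15 * s_fun(rt$times))
  expect_equal(rt$ratio, analytic, tolerance = 1e-3)
  # the ratio peak sits at the injected signal maximum within one grid step
  expect_lt(abs(rt$times[which.max(rt$ratio)] - 300), 1.5)
})

test_that("iratio is the window peak over baseline, floored at zero", {
  tt <- seq(0, 400, by = 1)
  sched <- injection_schedule(100, "x", list(numeric(0)))
  # flat trace
  flat <- make_ratio_trace(tt, rep(2, length(tt)))
  expect_equal(iratio_response(flat, sched, 180)$iratio, 0)
  # pure dip stays at zero, not negative
  dip <- make_ratio_trace(tt, 2 - 0.2 * exp(-(tt - 150)^2 / 200))
  expect_lt(iratio_response(dip, sched, 180)$iratio, 1e-4)
  expect_gte(iratio_response(dip, sched, 180)$iratio, 0)
  # triangular peak of known height over baseline
  h <- 0.25
  peak <- make_ratio_trace(tt, 2 + h * pmax(0, 1 - abs(tt - 160) / 30))
  expect_equal(iratio_response(peak, sched, 180)$iratio, h, tolerance = 1e-6)
  # window extending past the trace end warns
  expect_warning(iratio_response(peak, injection_schedule(350, "y",
                                                          list(numeric(0))), 180),
                 "truncated")
})

test_that("reference correction removes the shared dip exactly", {
  tt <- seq(0, 400, by = 1)
  dip <- -0.1 * exp(-(tt - 150)^2 / 500)
  peak <- 0.3 * pmax(0, 1 - abs(tt - 170) / 40)
  target <- make_ratio_trace(tt, 2 + peak + dip)
  reference <- make_ratio_trace(tt, 2 + dip, receptor = "TAS1R1_R3")
  corrected <- reference_correct(target, reference)
  expect_equal(corrected$ratio, 2 + peak, tolerance = 1e-9)
  # reference at its own baseline: identity
  flat_ref <- make_ratio_trace(tt, rep(2, length(tt)), receptor = "TAS1R1_R3")
  expect_equal(reference_correct(target, flat_ref)$ratio, target$ratio)
  # target identical to reference: flat at baseline
  self <- reference_correct(reference, reference)
  expect_lt(diff(range(self$ratio)), 1e-12)
  # grid mismatch is an error
  short <- make_ratio_trace(tt[-1], (2 + dip)[-1], receptor = "TAS1R1_R3")
  expect_error(reference_correct(target, short), "grid")
})

test_that("reference correction makes iratio insensitive to the dip amplitude", {
  base <- preset_scenario("fig2_sucrose_series", seed = 2)
  run_gamma <- function(g) {
    sc <- base
    sc$noise <- noise_config(channel_cv = 0, amp_sdlog = 0, dip_gamma = g)
    suppressMessages(run_dose_response(sc, seed = 2))$table$iratio
  }
  ir0 <- run_gamma(0)
  ir1 <- run_gamma(0.1)
  # the ratio readout is mildly nonlinear in the calcium signal, so the
  # subtractive correction cancels the dip to first order only
  expect_equal(ir1, ir0, tolerance = 0.03)
})
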