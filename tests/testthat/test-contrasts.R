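# Simulated iRatio tables with a known multiplicative structure.
sim_iratio_tbl <- function(n_spots = 8, effects = c(inj01 = 1, inj02 = 1),
                           spot_sd = 0.3, resid_sd = 0.2, seed = 1,
                           receptor = "TAS2R43") {
  set.seed(seed)
  spot_eff <- rnorm(n_spots, 0, spot_sd)
  rows <- expand.grid(spot = seq_len(n_spots), inj = names(effects))
  data.frame(
    spot_id = sprintf("s%02d", rows$spot),
    receptor = receptor,
    injection_id = as.character(rows$inj),
    sample_id = as.character(rows$inj),
    iratio = exp(log(effects[rows$inj]) + spot_eff[rows$spot] +
                   rnorm(nrow(rows), 0, resid_sd)) * 0.05,
    stringsAsFactors = FALSE)
}

test_that("null data give estimates of 1 and no significance", {
  tbl <- sim_iratio_tbl(effects = c(inj01 = 1, inj02 = 1), resid_sd = 0,
                        spot_sd = 0)
  # constant data: lm warns about an essentially perfect fit, which is the
  # expected degenerate case here
  cs <- suppressWarnings(suppressMessages(
    fit_contrasts(tbl, data.frame(treatment = "inj02", control = "inj01"))))
  expect_equal(cs$estimate, 1, tolerance = 1e-9)
  expect_false(cs$significant)
})

test_that("with zero residual variance the contrast is the geometric-mean ratio", {
  # treatment = 2x control for every spot, spot effects present
  tbl <- sim_iratio_tbl(effects = c(inj01 = 1, inj02 = 2), resid_sd = 0,
                        spot_sd = 0.4)
  cs <- suppressMessages(fit_contrasts(tbl, data.frame(treatment = "inj02",
                                                       control = "inj01")))
  expect_equal(cs$estimate, 2, tolerance = 1e-8)
  expect_true(cs$significant)

  # brute-force oracle on noisy balanced data: ratio of geometric means
  tbl2 <- sim_iratio_tbl(effects = c(inj01 = 1, inj02 = 1.6), resid_sd = 0.25,
                         spot_sd = 0, seed = 4)
  gm <- function(x) exp(mean(log(x)))
  oracle <- gm(tbl2$iratio[tbl2$injection_id == "inj02"]) /
    gm(tbl2$iratio[tbl2$injection_id == "inj01"])
  cs2 <- suppressMessages(fit_contrasts(tbl2, data.frame(treatment = "inj02",
                                                         control = "inj01")))
  expect_equal(cs2$estimate, oracle, tolerance = 1e-8)
  expect_equal(cs2$model, "fixed") # zero spot variance falls back
})

test_that("nonpositive iratio values are floored before the log", {
  tbl <- sim_iratio_tbl(effects = c(inj01 = 1, inj02 = 2), resid_sd = 0.1)
  tbl$iratio[1] <- 0
  expect_message(
    fit_contrasts(tbl, data.frame(treatment = "inj02", control = "inj01")),
    "flooring 1")
})

test_that("thin receptor groups are skipped", {
  tbl <- sim_iratio_tbl(n_spots = 4)
  expect_error(suppressMessages(
    fit_contrasts(tbl, data.frame(treatment = "inj02", control = "inj01"))),
    "no contrasts")
})

test_that("blocking percentage follows the excess-over-1 reduction formula", {
  expect_equal(blocking_percent(3.6, 1.0), 100)
  expect_equal(blocking_percent(3.6, 3.6), 0)
  expect_equal(blocking_percent(3.6, 1 + 0.08 * 2.6), 92)
  # clipping: mixture larger than pure, or below 1
  expect_equal(blocking_percent(2, 2.5), 0)
  expect_equal(blocking_percent(2, 0.9), 100)
  expect_error(blocking_percent(0.9, 1.2), "not above 1")
  # data.frame rows work too
  df <- data.frame(estimate = c(3.6, 1.52))
  expect_equal(blocking_percent(df[1, , drop = FALSE], df[2, , drop = FALSE]),
               80, tolerance = 1e-9)
})

test_that("mixed-model CIs achieve near-nominal coverage under the null", {
  n_sim <- 150
  cover <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    tbl <- sim_iratio_tbl(effects = c(inj01 = 1, inj02 = 1), spot_sd = 0.3,
                          resid_sd = 0.2, seed = s)
    cs <- suppressMessages(fit_contrasts(tbl, data.frame(treatment = "inj02",
                                                         control = "inj01")))
    cover[s] <- !cs$significant
  }
  # binomial slack at n = 150 on a 95% nominal interval
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
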