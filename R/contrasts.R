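#' Mixed-model multiplicative contrasts of injection effects
#'
#' Per receptor group, fits a linear mixed model on log iRatio with the
#' injection as a fixed effect and the spot as a random intercept
#' (REML; \pkg{lmerTest}), then derives treatment-versus-control contrasts
#' on the multiplicative scale with Wald 95% confidence intervals
#' (Satterthwaite degrees of freedom via \pkg{emmeans}). An estimate of 1.1
#' reads as a 10% larger response than the control injection; a contrast is
#' significant when its CI excludes 1. When the spot variance is estimated
#' as zero (singular fit) the model falls back to fixed effects only, with
#' a message.
#'
#' @param iratio_tbl iRatio table ([iratio_table()] format): columns
#'   `spot_id`, `receptor`, `injection_id`, `iratio`.
#' @param pairs Data.frame of contrast pairs with columns `treatment` and
#'   `control` (injection ids).
#' @param receptors Receptors to analyze; default all in the table.
#' @param min_replicates Minimum spots per receptor group; groups below it
#'   are skipped with a message.
#' @param floor Nonpositive iRatio values are floored here before taking
#'   logs (count reported via `message()`).
#' @return Data.frame with one row per receptor x pair: `receptor`,
#'   `treatment`, `control`, `estimate`, `ci_low`, `ci_high`, `significant`,
#'   `model` (`"mixed"` or `"fixed"`).
#' @export
fit_contrasts <- function(iratio_tbl, pairs, receptors = NULL,
                          min_replicates = 5, floor = 1e-4) {
  stopifnot(all(c("spot_id", "receptor", "injection_id", "iratio") %in%
                names(iratio_tbl)),
            all(c("treatment", "control") %in% names(pairs)))
  if (is.null(receptors)) receptors <- unique(iratio_tbl$receptor)
  n_floored <- sum(iratio_tbl$iratio < floor)
  if (n_floored > 0)
    message(sprintf("fit_contrasts: flooring %d iratio value(s) at %g before log",
                    n_floored, floor))
  iratio_tbl$log_iratio <- log(pmax(iratio_tbl$iratio, floor))
  out <- list()
  for (r in receptors) {
    d <- iratio_tbl[iratio_tbl$receptor == r, , drop = FALSE]
    n_spots <- length(unique(d$spot_id))
    if (n_spots < min_replicates) {
      message(sprintf("fit_contrasts: skipping %s (%d < %d spots)",
                      r, n_spots, min_replicates))
      next
    }
    d$injection_id <- factor(d$injection_id)
    d$spot_id <- factor(d$spot_id)
    mixed <- TRUE
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(log_iratio ~ injection_id + (1 | spot_id), data = d))),
      error = function(e) NULL)
    if (is.null(fit)) {
      message(sprintf("fit_contrasts: mixed model failed for %s; using fixed-effects model",
                      r))
      fit <- stats::lm(log_iratio ~ injection_id, data = d)
      mixed <- FALSE
    } else if (stats::sigma(fit) < 1e-6) {
      # zero residual variance: Satterthwaite df degenerate
      message(sprintf("fit_contrasts: zero residual variance for %s; using fixed-effects model",
                      r))
      fit <- stats::lm(log_iratio ~ injection_id, data = d)
      mixed <- FALSE
    } else if (lme4::isSingular(fit, tol = 1e-5)) {
      message(sprintf("fit_contrasts: singular mixed fit for %s (zero spot variance); using fixed-effects model",
                      r))
      fit <- stats::lm(log_iratio ~ injection_id, data = d)
      mixed <- FALSE
    }
    emm <- tryCatch(
      suppressMessages(emmeans::emmeans(fit, "injection_id",
                                        lmer.df = "satterthwaite")),
      error = function(e) NULL)
    if (is.null(emm)) {
      # degenerate variance structure (e.g. an essentially perfect fit)
      message(sprintf("fit_contrasts: degenerate mixed fit for %s; using fixed-effects model",
                      r))
      fit <- stats::lm(log_iratio ~ injection_id, data = d)
      mixed <- FALSE
      emm <- suppressMessages(emmeans::emmeans(fit, "injection_id"))
    }
    for (k in seq_len(nrow(pairs))) {
      trt <- pairs$treatment[k]
      ctl <- pairs$control[k]
      lv <- levels(d$injection_id)
      if (!trt %in% lv || !ctl %in% lv) next
      w <- as.numeric(lv == trt) - as.numeric(lv == ctl)
      ct <- emmeans::contrast(emm, method = list(contrast = w))
      ci <- stats::confint(ct, level = 0.95)
      est <- exp(ci$estimate)
      lo <- exp(ci$lower.CL)
      hi <- exp(ci$upper.CL)
      out[[length(out) + 1]] <- data.frame(
        receptor = r, treatment = trt, control = ctl,
        estimate = est, ci_low = lo, ci_high = hi,
        significant = (lo > 1 || hi < 1),
        model = if (mixed) "mixed" else "fixed",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no contrasts could be estimated", call. = FALSE)
  do.call(rbind, out)
}

#' Blocking percentage of an antagonist from two contrasts
#'
#' Given the multiplicative agonist effect alone (`effect_pure`) and with
#' the antagonist co-injected (`effect_mix`), both against the same blank,
#' the blocking percentage is the reduction of the excess effect over 1:
#' `100 * (E_pure - E_mix) / (E_pure - 1)`, clipped to `[0, 100]`. A mixture
#' effect back at 1 (no response left) is a 100% block.
#'
#' @param effect_pure,effect_mix Multiplicative estimates (single rows of
#'   [fit_contrasts()] output, or bare numbers).
#' @return Blocking percentage in `[0, 100]`.
#' @export
blocking_percent <- function(effect_pure, effect_mix) {
  ep <- if (is.data.frame(effect_pure)) effect_pure$estimate else effect_pure
  em <- if (is.data.frame(effect_mix)) effect_mix$estimate else effect_mix
  stopifnot(length(ep) == 1, length(em) == 1)
  if (ep <= 1)
    stop("blocking undefined: pure-agonist effect is not above 1", call. = FALSE)
  min(100, max(0, 100 * (ep - em) / (ep - 1)))
}
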