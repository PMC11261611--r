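#' Fit a Hill (four-parameter logistic) dose-response curve
#'
#' Least-squares fit of
#' `r(C) = bottom + (top - bottom) * C^h / (C^h + ec50^h)`,
#' parameterized in log-dose space for numerical conditioning
#' (`Levenberg-Marquardt` via \pkg{minpack.lm}). Accepts replicate-level
#' responses (several responses per dose) or per-dose means.
#'
#' @param doses Positive ligand doses (same unit as the reported EC50).
#' @param responses Responses (e.g. iRatio) matching `doses`.
#' @param bounds_ec50 EC50 search bounds; default
#'   `[min(dose)/10, max(dose)*10]`.
#' @param bounds_hill Hill-slope bounds; default `(0, 10]`.
#' @return A `hill_fit`: list with `ec50`, `hill`, `top`, `bottom`,
#'   per-parameter `se`, `converged`, `n_points` (distinct doses), and the
#'   underlying `fit` object (`NULL` when rejected).
#' @examples
#' d <- rep(c(1, 3, 10, 30, 100), each = 3)
#' r <- 0.02 + 0.3 * d / (d + 35)
#' fit_hill(d, r)$ec50
#' @export
fit_hill <- function(doses, responses, bounds_ec50 = NULL,
                     bounds_hill = c(1e-6, 10)) {
  stopifnot(length(doses) == length(responses))
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  n_points <- length(unique(doses))
  if (n_points < 4)
    stop("need >= 4 distinct doses, got ", n_points, call. = FALSE)
  if (diff(range(responses)) <= 0 ||
      stats::sd(responses) < 1e-12 * max(abs(responses)))
    stop("zero dynamic range: responses carry no dose information", call. = FALSE)
  if (is.null(bounds_ec50)) bounds_ec50 <- c(min(doses) / 10, max(doses) * 10)
  df <- data.frame(ld = log(doses), r = responses)
  start <- list(bottom = min(responses), top = max(responses),
                lec50 = mean(log(range(doses))), h = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ bottom + (top - bottom) / (1 + exp(h * (lec50 - ld))),
      data = df, start = start,
      lower = c(bottom = -Inf, top = -Inf, lec50 = log(bounds_ec50[1]),
                h = bounds_hill[1]),
      upper = c(bottom = Inf, top = Inf, lec50 = log(bounds_ec50[2]),
                h = bounds_hill[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, se = NULL, converged = FALSE,
                          n_points = n_points,
                          diagnostics = conditionMessage(fit), fit = NULL),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  ec50 <- exp(cf[["lec50"]])
  ec50_se <- if (!is.na(se[["lec50"]])) ec50 * se[["lec50"]] else NA_real_
  structure(list(ec50 = ec50, hill = cf[["h"]], top = cf[["top"]],
                 bottom = cf[["bottom"]],
                 se = c(ec50 = ec50_se, hill = unname(se[["h"]]),
                        top = unname(se[["top"]]), bottom = unname(se[["bottom"]])),
                 converged = fit$convInfo$isConv, n_points = n_points,
                 diagnostics = NULL, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> NOT converged:", x$diagnostics %||% "see fit", "\n")
    return(invisible(x))
  }
  cat(sprintf("<hill_fit> EC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g (%d doses)\n",
              x$ec50, x$hill, x$top, x$bottom, x$n_points))
  invisible(x)
}

#' Effective concentration at a response fraction (EC10, EC50, ...)
#'
#' Closed-form inverse of the fitted Hill curve:
#' `ECf = ec50 * (f / (1 - f))^(1 / h)`. `ec_fraction(fit, 0.1)` is the EC10
#' proposed as an in vitro taste-threshold analog.
#'
#' @param fit A converged `hill_fit`.
#' @param f Response fraction in (0, 1).
#' @return Concentration in the dose unit of the fit.
#' @export
ec_fraction <- function(fit, f) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (any(f <= 0 | f >= 1)) stop("f must be in (0, 1)", call. = FALSE)
  fit$ec50 * (f / (1 - f))^(1 / fit$hill)
}
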