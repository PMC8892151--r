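#' Kinetic parameters of the gas-production curve
#'
#' @param B Asymptotic gas production (mL per g incubated DM), `>= 0`.
#' @param c Fractional rate constant (per hour), `>= 0`.
#' @param L Lag time (hours), `>= 0`.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(B, c, L = 0) {
  if (B < 0 || c < 0 || L < 0)
    stop("kinetic parameters must be non-negative")
  structure(list(B = B, c = c, L = L), class = "kinetic_params")
}

#' Exponential-with-lag gas-production model
#'
#' `G(t) = B (1 - exp(-c (t - L)))` for `t >= L`, clamped to 0 before the
#' lag (the raw expression is negative there, which has no biological
#' meaning).
#'
#' @param params A [kinetic_params()] (a [fermentation_params()] is also
#'   accepted, using its true values).
#' @param t Time(s) in hours, `>= 0`; vectorized.
#' @return Gas production in mL per g incubated DM.
#' @examples
#' predict_gp(kinetic_params(200, 0.08, 2), 26)  # 170.68
#' @export
predict_gp <- function(params, t) {
  if (inherits(params, "fermentation_params"))
    params <- kinetic_params(params$B_true, params$c_true, params$L_true)
  stopifnot(inherits(params, "kinetic_params"))
  ifelse(t <= params$L, 0,
         params$B * (1 - exp(-params$c * (t - params$L))))
}

# model function over a fixed time vector, used by the nls formula
gp_curve <- function(t, B, c, L) {
  ifelse(t <= L, 0, B * (1 - exp(-c * (t - L))))
}

#' Starting values for the kinetic fit
#'
#' Heuristic: `B0` is 1.05 times the curve maximum; `L0` is the last time at
#' which GP is still below 5 percent of the maximum (0 if none); `c0` comes
#' from the log-linearization `log(1 - G/B0) = -c (t - L0)` fitted over the
#' points below 95 percent of `B0`. All values are clamped non-negative.
#'
#' @param times Hours, increasing.
#' @param gp_values Cumulative GP (mL/g DM), non-negative.
#' @return A [kinetic_params()].
#' @export
initial_guess <- function(times, gp_values) {
  stopifnot(length(times) == length(gp_values))
  gmax <- max(gp_values)
  if (gmax <= 0) stop("all-zero gas production curve: nothing to fit")
  B0 <- 1.05 * gmax
  below <- which(gp_values < 0.05 * gmax)
  L0 <- if (length(below)) max(0, times[max(below)]) else 0
  keep <- gp_values < 0.95 * B0 & gp_values >= 0 & times > L0
  c0 <- NA_real_
  if (sum(keep) >= 2) {
    y <- log(pmax(1e-12, 1 - gp_values[keep] / B0))
    x <- times[keep] - L0
    c0 <- -sum(x * y) / sum(x * x)       # no-intercept LS slope
  }
  if (!is.finite(c0) || c0 <= 0) c0 <- 0.05
  kinetic_params(B0, c0, max(0, L0))
}

#' Fit the exponential-with-lag model by bounded least squares
#'
#' Levenberg-Marquardt least squares (via [minpack.lm::nlsLM()]) with
#' non-negativity bounds on all three parameters and the lag bounded by the
#' last observation time. Exponential fits are initialization-sensitive, so
#' the fit is restarted from three perturbed guesses (0.5x, 1x, 2x on the
#' initial rate) and the lowest-RSS converged result is kept. The returned
#' RSS never exceeds the RSS of the initial guess; if the optimizer fails
#' to improve on it the guess itself is returned with `converged = FALSE`.
#'
#' @param times Hours, strictly increasing, at least 4 points.
#' @param gp_values Cumulative blank-corrected GP (mL per g DM).
#' @param max_iter Iteration cap per start (default 500).
#' @param tol Convergence tolerance on the relative reduction and parameter
#'   step (default 1e-8).
#' @param start Optional [kinetic_params()] overriding [initial_guess()].
#' @return Object of class `kinetic_fit`: `params`, `rss`, `n_obs`,
#'   `converged`, `iterations`, `standard_errors` (from the curvature at
#'   the solution; `NA` when the Jacobian is singular).
#' @examples
#' t <- seq(0.25, 48, by = 0.25)
#' fit <- fit_kinetics(t, predict_gp(kinetic_params(200, 0.08, 2), t))
#' unlist(fit$params)
#' @export
fit_kinetics <- function(times, gp_values, max_iter = 500, tol = 1e-8,
                         start = NULL) {
  stopifnot(length(times) == length(gp_values))
  if (length(times) < 4)
    stop("at least 4 observations are required to fit 3 parameters")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")

  guess <- if (is.null(start)) initial_guess(times, gp_values) else start
  rss_of <- function(p) sum((gp_values - gp_curve(times, p$B, p$c, p$L))^2)
  guess_rss <- rss_of(guess)

  dat <- data.frame(t = times, y = gp_values)
  best <- NULL
  total_iter <- 0L
  for (mult in c(0.5, 1, 2)) {
    st <- list(B = guess$B, c = max(1e-6, guess$c * mult), L = guess$L)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ gp_curve(t, B, c, L), data = dat, start = st,
        lower = c(0, 0, 0), upper = c(Inf, Inf, max(times)),
        control = minpack.lm::nls.lm.control(
          maxiter = max_iter, ftol = tol, ptol = tol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    conv <- isTRUE(fit$convInfo$isConv)
    total_iter <- total_iter + fit$convInfo$finIter
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && rss < best$rss))
      best <- list(fit = fit, rss = rss, conv = conv)
  }

  if (is.null(best) || best$rss > guess_rss + 1e-12) {
    return(structure(list(params = guess, rss = guess_rss,
                          n_obs = length(times), converged = FALSE,
                          iterations = total_iter,
                          standard_errors = c(B = NA_real_, c = NA_real_,
                                              L = NA_real_)),
                     class = "kinetic_fit"))
  }

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(B = NA_real_, c = NA_real_,
                                       L = NA_real_))
  structure(list(params = kinetic_params(max(0, cf[["B"]]), max(0, cf[["c"]]),
                                         max(0, cf[["L"]])),
                 rss = best$rss, n_obs = length(times),
                 converged = best$conv,
                 iterations = total_iter,
                 standard_errors = se),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> B = %.3f mL/g, c = %.4f /h, L = %.3f h (rss %.4g, %s)\n",
    x$params$B, x$params$c, x$params$L, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit kinetics for every bottle of a gas-production table
#'
#' @param gp_table Long table with columns `bottle_id`, `time_h`,
#'   `gp_mL_per_g` (as produced by [build_gp_table()] after blank
#'   correction).
#' @param ... Passed to [fit_kinetics()].
#' @return data.frame `bottle_id`, `B`, `c`, `L`, `rss`, `converged`,
#'   `se_B`, `se_c`, `se_L`.
#' @export
fit_kinetics_table <- function(gp_table, ...) {
  ids <- unique(gp_table$bottle_id)
  out <- lapply(ids, function(id) {
    d <- gp_table[gp_table$bottle_id == id, ]
    d <- d[order(d$time_h), ]
    fit <- tryCatch(fit_kinetics(d$time_h, d$gp_mL_per_g, ...),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(bottle_id = id, B = NA_real_, c = NA_real_,
                        L = NA_real_, rss = NA_real_, converged = FALSE,
                        se_B = NA_real_, se_c = NA_real_, se_L = NA_real_))
    data.frame(bottle_id = id, B = fit$params$B, c = fit$params$c,
               L = fit$params$L, rss = fit$rss, converged = fit$converged,
               se_B = unname(fit$standard_errors[1]),
               se_c = unname(fit$standard_errors[2]),
               se_L = unname(fit$standard_errors[3]))
  })
  do.call(rbind, out)
}
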