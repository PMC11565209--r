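#' Sigmoidal induction model
#'
#' Time course of a gas-exchange variable after a step increase in
#' irradiance, in the Gompertz-type sigmoidal form
#' \deqn{y(t) = y_0 + (y_f - y_0)\,\exp(-\exp((\lambda - t)/k))}
#' where `t` is time since the step, `y0`/`yf` the pre-/post-step steady
#' values, `lam` the initial lag (s) and `k` the time constant (s). The
#' reported time constant tau equals `k`; a small `lam/k` reduces the curve
#' to a simple exponential rise.
#'
#' @param t Time since the step, s.
#' @param y0,yf Initial and final steady values.
#' @param lam Lag, s.
#' @param k Time constant, s.
#' @return Model value at `t`.
#' @export
induction_curve <- function(t, y0, yf, lam, k) {
  y0 + (yf - y0) * exp(-exp((lam - t) / k))
}

# sigmoid after the step, pre-step steady state before it
.induction_piecewise <- function(t, y0, yf, lam, k) {
  ifelse(t < 0, y0, induction_curve(t, y0, yf, lam, k))
}

#' Split a step-change series into baseline and response phases
#'
#' Locates the single upward light step (>= 5-fold increase) in a
#' step-change series and partitions it into the low-light baseline and the
#' post-step response. Samples are classified against the midpoint of the
#' observed Q range, so plateau jitter (e.g. 98-103 then 995-1005) does not
#' defeat detection.
#'
#' @param series A [gasx_series()] with protocol `"step_change"`.
#' @return A list of class `"step_phases"` with `baseline` and `response`
#'   (both `gasx_series`) and `t_step`, the time of the first high-light
#'   sample.
#' @export
split_step <- function(series) {
  stopifnot(inherits(series, "gasx_series"))
  if (attr(series, "protocol") != "step_change")
    stop("split_step expects a step_change series", call. = FALSE)
  mid <- (min(series$Q) + max(series$Q)) / 2
  high <- series$Q > mid
  trans <- diff(high)
  ups <- which(trans == 1L)
  downs <- which(trans == -1L)
  if (length(ups) != 1L || length(downs) != 0L)
    stop(sprintf("expected exactly one upward light step, found %d up / %d down transitions",
                 length(ups), length(downs)), call. = FALSE)
  lo_med <- stats::median(series$Q[!high])
  hi_med <- stats::median(series$Q[high])
  if (hi_med < 5 * max(lo_med, 1e-9))
    stop(sprintf("light step is only %.1f-fold; need >= 5-fold", hi_med / lo_med),
         call. = FALSE)
  i_step <- ups + 1L
  slice <- function(idx) {
    s <- series[idx, , drop = FALSE]
    attributes(s)[c("plant_id", "accession", "protocol")] <-
      attributes(series)[c("plant_id", "accession", "protocol")]
    class(s) <- class(series)
    s
  }
  structure(list(baseline = slice(seq_len(i_step - 1L)),
                 response = slice(i_step:nrow(series)),
                 t_step = series$t[i_step]),
            class = "step_phases")
}

#' @export
print.step_phases <- function(x, ...) {
  cat(sprintf("<step_phases> step at t = %g s; baseline n = %d, response n = %d\n",
              x$t_step, nrow(x$baseline), nrow(x$response)))
  invisible(x)
}

#' Fit induction kinetics after a light step
#'
#' Fits the sigmoidal induction model to A or gs, with time measured from
#' the step. By default the baseline samples participate in the fit as the
#' pre-step steady state (model value `y0` for t < 0): this anchors `y0`
#' and removes the lag/time-constant/`y0` ridge that makes response-only
#' fits wander under noise. The fit is seeded deterministically (`y0` from
#' the baseline mean, `yf` from the mean of the last 120 s) and started
#' from a grid of lag/time-constant combinations spanning the two orders
#' of magnitude that stomatal responses cover; the best starts are refined
#' by Levenberg-Marquardt least squares.
#'
#' If the apparent response amplitude `|yf - y0|` is below
#' `noise_mult` baseline standard deviations the trace is flagged as
#' "no response" and no parameters are estimated.
#'
#' @param phases A [split_step()] result.
#' @param variable `"A"` or `"gs"`.
#' @param lam_grid,k_grid Multi-start grid over lag and time constant, s.
#' @param noise_mult Response floor in baseline standard deviations
#'   (default 3).
#' @param include_baseline Use the baseline samples (at negative step time)
#'   to anchor `y0` (default `TRUE`).
#' @return An object of class `"induction_fit"`: coefficients `y0`, `yf`,
#'   `lam`, `k`, plus `tau` (= `k`), `sse`, `n`, `no_response`, `variable`,
#'   and the response data (`t` relative to the step). Supports `print`,
#'   `coef`, `summary`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' tr <- accession_truth()
#' s <- simulate_step_response(tr, seed = 1, noise = FALSE)
#' fit <- fit_induction(split_step(s), "gs")
#' coef(fit)[["k"]]  # recovers tr$k_gs
#' @export
fit_induction <- function(phases, variable = c("A", "gs"),
                          lam_grid = c(0, 30, 60, 120, 300),
                          k_grid = c(30, 100, 300, 1000),
                          noise_mult = 3, include_baseline = TRUE) {
  variable <- match.arg(variable)
  stopifnot(inherits(phases, "step_phases"))
  resp <- phases$response
  if (nrow(resp) < 60L)
    stop(sprintf("response phase has %d samples; need >= 60", nrow(resp)),
         call. = FALSE)
  t <- resp$t - phases$t_step
  y <- resp[[variable]]
  if (include_baseline) {
    t <- c(phases$baseline$t - phases$t_step, t)
    y <- c(phases$baseline[[variable]], y)
  }
  y0_init <- mean(phases$baseline[[variable]])
  tail120 <- t >= max(t) - 120
  yf_init <- mean(y[tail120])
  base_sd <- stats::sd(phases$baseline[[variable]])
  if (is.finite(base_sd) && base_sd > 0 &&
      abs(yf_init - y0_init) < noise_mult * base_sd) {
    return(structure(list(coefficients = c(y0 = y0_init, yf = yf_init,
                                           lam = NA_real_, k = NA_real_),
                          tau = NA_real_, sse = NA_real_, n = length(t),
                          no_response = TRUE, variable = variable,
                          data = data.frame(t = t, y = y)),
                     class = "induction_fit"))
  }

  # cheap SSE screen over the start grid, then LM refinement of the best starts
  grid <- expand.grid(lam = lam_grid, k = k_grid)
  grid_sse <- apply(grid, 1L, function(g)
    sum((y - .induction_piecewise(t, y0_init, yf_init, g[["lam"]], g[["k"]]))^2))
  ord <- order(grid_sse)
  dat <- data.frame(t = t, y = y)
  best <- NULL
  diagnostics <- character()
  for (i in utils::head(ord, 4L)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .induction_piecewise(t, y0, yf, lam, k),
        data = dat,
        start = list(y0 = y0_init, yf = yf_init,
                     lam = grid$lam[i], k = grid$k[i]),
        lower = c(y0 = -Inf, yf = -Inf, lam = 0, k = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) { diagnostics <<- c(diagnostics, conditionMessage(e)); NULL })
    if (!is.null(fit)) {
      sse <- sum(stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse - 1e-12) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best))
    stop("induction fit failed to converge from all grid starts: ",
         paste(unique(diagnostics), collapse = "; "), call. = FALSE)
  cf <- stats::coef(best$fit)
  structure(list(coefficients = cf, tau = unname(cf[["k"]]), sse = best$sse,
                 n = length(t), no_response = FALSE, variable = variable,
                 data = dat, nls = best$fit),
            class = "induction_fit")
}

#' @export
coef.induction_fit <- function(object, ...) object$coefficients

#' @export
predict.induction_fit <- function(object, newdata = NULL, ...) {
  if (object$no_response) stop("no-response fit has no model curve", call. = FALSE)
  t <- if (is.null(newdata)) object$data$t else newdata$t
  cf <- object$coefficients
  .induction_piecewise(t, cf[["y0"]], cf[["yf"]], cf[["lam"]], cf[["k"]])
}

#' @export
fitted.induction_fit <- function(object, ...) predict(object)

#' @export
residuals.induction_fit <- function(object, ...) object$data$y - fitted(object)

#' @export
print.induction_fit <- function(x, ...) {
  cat(sprintf("Induction-kinetics fit (%s)\n", x$variable))
  if (x$no_response) {
    cat(sprintf("  NO RESPONSE: |yf - y0| = %.4g below noise floor\n",
                abs(x$coefficients[["yf"]] - x$coefficients[["y0"]])))
  } else {
    cf <- x$coefficients
    cat(sprintf("  y0 = %.5g  yf = %.5g  lag = %.4g s  tau = %.4g s\n",
                cf[["y0"]], cf[["yf"]], cf[["lam"]], cf[["k"]]))
    cat(sprintf("  n = %d, SSE = %.5g\n", x$n, x$sse))
  }
  invisible(x)
}

#' @export
summary.induction_fit <- function(object, ...) {
  if (object$no_response) return(print(object))
  s <- summary(object$nls)
  structure(list(fit = object, nls_summary = s), class = "summary.induction_fit")
}

#' @export
print.summary.induction_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates (from nls):\n")
  stats::printCoefmat(x$nls_summary$coefficients)
  invisible(x)
}

#' @export
plot.induction_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, xlab = "t since step (s)",
                 ylab = x$variable, ...)
  if (!x$no_response) {
    tt <- seq(0, max(x$data$t), length.out = 300)
    graphics::lines(tt, predict(x, data.frame(t = tt)))
  }
  invisible(x)
}

#' Intrinsic water-use-efficiency time course
#'
#' Elementwise Wi = A / gs (umol CO2 mol^-1 H2O). Samples with
#' `gs < eps_gs` are masked to `NA` rather than producing exploding ratios;
#' masking is not an error.
#'
#' @param series A [gasx_series()].
#' @param eps_gs Conductance floor, mol m^-2 s^-1 (default 0.005, below
#'   typical instrument resolution).
#' @return Data frame with columns `t` and `Wi`.
#' @export
wi_timecourse <- function(series, eps_gs = 0.005) {
  Wi <- ifelse(series$gs >= eps_gs, series$A / series$gs, NA_real_)
  data.frame(t = series$t, Wi = Wi)
}

#' Steady-state intrinsic water use efficiency around a light step
#'
#' Mean Wi over the final `window` seconds (closed interval) of the
#' baseline and of the response phase of a step-change measurement.
#'
#' @param phases A [split_step()] result; baseline and response must each
#'   cover at least `window` seconds.
#' @param window Averaging window, s (default 300 = 5 min).
#' @param eps_gs Conductance floor passed to [wi_timecourse()].
#' @return A list with `Wi_low`, `Wi_high`, `n_low`, `n_high`.
#' @export
steady_state_wi <- function(phases, window = 300, eps_gs = 0.005) {
  stopifnot(inherits(phases, "step_phases"))
  span <- function(s) max(s$t) - min(s$t)
  # a phase sampled every dt seconds for `window` seconds spans window - dt
  slack <- function(s) stats::median(diff(s$t)) + 1e-9
  if (span(phases$baseline) < window - slack(phases$baseline))
    stop(sprintf("baseline spans %.0f s; need >= %g s", span(phases$baseline),
                 window), call. = FALSE)
  if (span(phases$response) < window - slack(phases$response))
    stop(sprintf("response spans %.0f s; need >= %g s", span(phases$response),
                 window), call. = FALSE)
  one <- function(s) {
    wi <- wi_timecourse(s, eps_gs)
    keep <- wi$t >= max(wi$t) - window & wi$t <= max(wi$t)
    v <- wi$Wi[keep]
    list(mean = mean(v, na.rm = TRUE), n = sum(keep & !is.na(wi$Wi)))
  }
  lo <- one(phases$baseline)
  hi <- one(phases$response)
  list(Wi_low = lo$mean, Wi_high = hi$mean, n_low = lo$n, n_high = hi$n)
}
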