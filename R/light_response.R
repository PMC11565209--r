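#' Rectangular-hyperbola light response
#'
#' Net assimilation as a function of PPFD under the rectangular hyperbola
#' (Michaelis-Menten form) parameterized so that the apparent quantum yield
#' is a direct parameter:
#' \deqn{A(Q) = \frac{\phi Q A_{max}}{\phi Q + A_{max}} - R_d}
#' `phi` is the initial slope dA/dQ at Q = 0, `Amax` the asymptotic gross
#' assimilation, `Rd` dark respiration (so A(0) = -Rd).
#'
#' @param Q PPFD, umol m^-2 s^-1.
#' @param phi Apparent quantum yield (mol CO2 mol^-1 photons).
#' @param Amax Asymptotic gross assimilation, umol m^-2 s^-1.
#' @param Rd Dark respiration, umol m^-2 s^-1.
#' @return Net assimilation, umol m^-2 s^-1.
#' @export
light_response_curve <- function(Q, phi, Amax, Rd) {
  phi * Q * Amax / (phi * Q + Amax) - Rd
}

#' Fit a steady-state light-response (A/Q) curve
#'
#' Least-squares fit of the rectangular hyperbola
#' `A(Q) = phi*Q*Amax/(phi*Q + Amax) - Rd` to the (Q, A) records of a
#' series. Initialization is deterministic: `Rd0` from the Q = 0 records
#' (or 0.5 if absent), `phi0` from the OLS slope through the three lowest
#' nonzero-Q levels, `Amax0 = max(A) + Rd0`; a small multiplicative
#' multi-start grid around those values guards against local minima.
#'
#' @param series A [gasx_series()], or any data frame with columns `Q`
#'   and `A`.
#' @return An object of class `"light_fit"` with components `coefficients`
#'   (`phi`, `Amax`, `Rd`), `sse`, `n`, `data`, and the underlying
#'   `nls` fit. Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals` and `plot`.
#' @examples
#' Q <- c(2000, 1500, 1250, 1000, 750, 500, 300, 200, 100, 50, 20, 0)
#' A <- light_response_curve(Q, phi = 0.05, Amax = 40, Rd = 2)
#' fit <- fit_light_response(data.frame(Q = Q, A = A))
#' coef(fit)
#' @export
fit_light_response <- function(series) {
  Q <- series$Q
  A <- series$A
  ok <- is.finite(Q) & is.finite(A)
  Q <- Q[ok]; A <- A[ok]
  lev <- sort(unique(round(Q, 6)))
  if (length(lev) < 4L)
    stop(sprintf("need >= 4 distinct Q levels to fit, got %d", length(lev)),
         call. = FALSE)
  dark <- Q <= 10
  Rd0 <- if (any(dark)) max(-mean(A[dark]), 0) else 0.5
  lo3 <- utils::head(setdiff(lev, lev[lev <= 10]), 3L)
  sel <- round(Q, 6) %in% lo3 | dark
  phi0 <- unname(stats::coef(stats::lm(A[sel] ~ Q[sel]))[2L])
  if (!is.finite(phi0) || phi0 <= 0) phi0 <- 0.05
  Amax0 <- max(A) + Rd0
  if (Amax0 <= 0) Amax0 <- 1

  dat <- data.frame(Q = Q, A = A)
  best <- NULL
  for (fp in c(1, 0.5, 2)) for (fa in c(1, 0.5, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        A ~ phi * Q * Amax / (phi * Q + Amax) - Rd,
        data = dat,
        start = list(phi = phi0 * fp, Amax = Amax0 * fa, Rd = Rd0),
        lower = c(phi = 1e-8, Amax = 1e-6, Rd = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse - 1e-12) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best))
    stop("light-response fit failed to converge from all starts", call. = FALSE)
  cf <- stats::coef(best$fit)
  structure(list(coefficients = cf, sse = best$sse, n = nrow(dat),
                 data = dat, nls = best$fit),
            class = "light_fit")
}

#' @export
coef.light_fit <- function(object, ...) object$coefficients

#' @export
fitted.light_fit <- function(object, ...) {
  unname(light_response_curve(object$data$Q, object$coefficients[["phi"]],
                              object$coefficients[["Amax"]],
                              object$coefficients[["Rd"]]))
}

#' @export
residuals.light_fit <- function(object, ...) object$data$A - fitted(object)

#' Predict from a fitted light-response curve
#'
#' @param object A `"light_fit"`.
#' @param newdata Data frame with a `Q` column, or omitted to predict at the
#'   fitted points.
#' @param ... Unused.
#' @return Predicted net assimilation at the requested PPFD values.
#' @export
predict.light_fit <- function(object, newdata = NULL, ...) {
  Q <- if (is.null(newdata)) object$data$Q else newdata$Q
  cf <- object$coefficients
  light_response_curve(Q, cf[["phi"]], cf[["Amax"]], cf[["Rd"]])
}

#' @export
print.light_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Rectangular-hyperbola light-response fit\n")
  cat(sprintf("  phi (QY) = %.5g   Amax = %.5g   Rd = %.5g\n",
              cf[["phi"]], cf[["Amax"]], cf[["Rd"]]))
  cat(sprintf("  n = %d, SSE = %.5g\n", x$n, x$sse))
  invisible(x)
}

#' @export
summary.light_fit <- function(object, ...) {
  s <- summary(object$nls)
  structure(list(fit = object, nls_summary = s), class = "summary.light_fit")
}

#' @export
print.summary.light_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates (from nls):\n")
  stats::printCoefmat(x$nls_summary$coefficients)
  invisible(x)
}

#' @export
plot.light_fit <- function(x, ...) {
  graphics::plot(x$data$Q, x$data$A, xlab = "PPFD (umol m-2 s-1)",
                 ylab = "A (umol m-2 s-1)", ...)
  qq <- seq(0, max(x$data$Q), length.out = 200)
  graphics::lines(qq, predict(x, data.frame(Q = qq)))
  invisible(x)
}

#' Apparent quantum yield from a linear low-light fit
#'
#' Alternative QY estimate: the OLS slope of A on Q over the dark record and
#' the three lowest nonzero PPFD levels, rather than the hyperbola's `phi`
#' parameter. Exposed for comparison; the parameter form is the default used
#' by the pipeline.
#'
#' @param series A [gasx_series()] or data frame with `Q` and `A`.
#' @return The slope (mol CO2 mol^-1 photons).
#' @export
qy_linear <- function(series) {
  lev <- sort(unique(round(series$Q, 6)))
  lo3 <- utils::head(setdiff(lev, lev[lev <= 10]), 3L)
  sel <- round(series$Q, 6) %in% lo3 | series$Q <= 10
  if (sum(sel) < 3L) stop("too few low-light points for a linear QY", call. = FALSE)
  unname(stats::coef(stats::lm(A ~ Q, data = series[sel, ]))[2L])
}

#' Summarize a light-response curve
#'
#' Derives the headline steady-state traits from a measured A/Q series and
#' its fit: QY (the fitted `phi`), `Asat` and `gssat` as the measured means
#' of A and gs at the nominal 2000 umol m^-2 s^-1 level (matched within
#' `level_tol`), and the per-level mean Ci/Ca ratio.
#'
#' @param series A [gasx_series()] with protocol `"light_curve"`.
#' @param fit The corresponding [fit_light_response()] result; fitted here
#'   if omitted.
#' @param nominal_levels Nominal PPFD levels of the protocol.
#' @param level_tol Relative tolerance for matching measured Q to a nominal
#'   level (default 5%; Q = 0 matched within 10 umol m^-2 s^-1 absolute).
#' @return A list of class `"light_curve_summary"` with `QY`, `Asat`,
#'   `gssat`, `Rd`, `sse`, and `ci_ca_by_level` (data frame of `Q`,
#'   `ci_ca`, `n`).
#' @export
summarize_light_curve <- function(series, fit = NULL,
                                  nominal_levels = c(2000, 1500, 1250, 1000,
                                                     750, 500, 300, 200, 100,
                                                     50, 20, 0),
                                  level_tol = 0.05) {
  if (is.null(fit)) fit <- fit_light_response(series)
  lev <- .nominal_level(series$Q, nominal_levels, level_tol)
  at2000 <- !is.na(lev) & lev == 2000
  if (!any(at2000))
    stop("series has no records at the nominal 2000 umol m^-2 s^-1 level",
         call. = FALSE)
  grp <- ifelse(is.na(lev), round(series$Q), lev)
  ratio <- series$Ci / series$Ca
  agg <- stats::aggregate(ratio, by = list(Q = grp), FUN = mean)
  cnt <- stats::aggregate(ratio, by = list(Q = grp), FUN = length)
  ci_ca <- data.frame(Q = agg$Q, ci_ca = agg$x, n = cnt$x)
  ci_ca <- ci_ca[order(-ci_ca$Q), ]
  rownames(ci_ca) <- NULL
  structure(list(QY = unname(fit$coefficients[["phi"]]),
                 Asat = mean(series$A[at2000]),
                 gssat = mean(series$gs[at2000]),
                 Rd = unname(fit$coefficients[["Rd"]]),
                 sse = fit$sse,
                 ci_ca_by_level = ci_ca),
            class = "light_curve_summary")
}

#' @export
print.light_curve_summary <- function(x, ...) {
  cat(sprintf("QY = %.4g  Asat = %.4g umol m-2 s-1  gssat = %.4g mol m-2 s-1  Rd = %.4g\n",
              x$QY, x$Asat, x$gssat, x$Rd))
  cat("Ci/Ca by level:\n")
  print(x$ci_ca_by_level, digits = 3)
  invisible(x)
}

#' Regression of assimilation on stomatal conductance
#'
#' Ordinary least squares of A on gs (slope in umol CO2 mol^-1 H2O), with
#' the Pearson correlation and its two-sided p-value. Used both within a
#' plant across light levels and across accession means at a fixed level.
#'
#' @param A,gs Paired vectors (at least 3 pairs), or a single
#'   [gasx_series()] in `A` with `gs` omitted.
#' @return A list with `slope`, `intercept`, `R`, `p`, `n`.
#' @export
a_gs_regression <- function(A, gs = NULL) {
  if (is.null(gs)) { gs <- A$gs; A <- A$A }
  ok <- is.finite(A) & is.finite(gs)
  A <- A[ok]; gs <- gs[ok]
  if (length(A) < 3L) stop("need at least 3 (A, gs) pairs", call. = FALSE)
  if (stats::var(gs) == 0)
    stop("gs has zero variance; regression undefined", call. = FALSE)
  fit <- stats::lm(A ~ gs)
  ct <- pearson(gs, A)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       R = ct$R, p = ct$p, n = length(A))
}
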