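paper_levels <- c(2000, 1500, 1250, 1000, 750, 500, 300, 200, 100, 50, 20, 0)

test_that("noiseless hyperbola data is recovered to 1e-6 relative", {
  truth <- c(phi = 0.05, Amax = 40, Rd = 2)
  A <- light_response_curve(paper_levels, truth[1], truth[2], truth[3])
  fit <- fit_light_response(data.frame(Q = paper_levels, A = A))
  for (p in names(truth))
    expect_rel_equal(coef(fit)[[p]], truth[[p]], 1e-6)
  # fitted value at Q = 0 equals -Rd
  expect_equal(predict(fit, data.frame(Q = 0)), -coef(fit)[["Rd"]])
})

test_that("noisy fit agrees with a twice-refined exhaustive grid search", {
  set.seed(7)
  A <- light_response_curve(paper_levels, 0.05, 40, 2) + rnorm(12, 0, 0.3)
  dat <- data.frame(Q = paper_levels, A = A)
  fit <- fit_light_response(dat)

  sse_of <- function(phi, Amax, Rd)
    sum((A - light_response_curve(paper_levels, phi, Amax, Rd))^2)
  grid_best <- c(phi = 0.05, Amax = 40, Rd = 2)
  widths <- c(phi = 0.04, Amax = 30, Rd = 2)
  for (pass in 1:3) {
    g <- expand.grid(
      phi = seq(grid_best[1] - widths[1], grid_best[1] + widths[1], length.out = 21),
      Amax = seq(grid_best[2] - widths[2], grid_best[2] + widths[2], length.out = 21),
      Rd = seq(max(grid_best[3] - widths[3], 0), grid_best[3] + widths[3], length.out = 21))
    g <- g[g$phi > 0 & g$Amax > 0, ]
    sse <- mapply(sse_of, g$phi, g$Amax, g$Rd)
    grid_best <- unlist(g[which.min(sse), ])
    widths <- widths / 8
  }
  # the continuous optimizer should do at least as well as the refined grid
  expect_lte(fit$sse, min(sse) + 1e-8)
  expect_rel_equal(coef(fit)[["phi"]], grid_best[["phi"]], 0.02)
  expect_rel_equal(coef(fit)[["Amax"]], grid_best[["Amax"]], 0.02)
})

test_that("in the linear limit phi equals the OLS slope", {
  Q <- paper_levels
  A <- 0.04 * Q - 1 + 0  # Amax -> infinity limit
  fit <- fit_light_response(data.frame(Q = Q, A = A))
  ols <- unname(coef(lm(A ~ Q))[2])
  expect_lt(abs(coef(fit)[["phi"]] - ols) / ols, 1e-3)
})

test_that("too few light levels is an error", {
  expect_error(fit_light_response(data.frame(Q = c(0, 100, 500),
                                             A = c(-1, 4, 15))),
               ">= 4 distinct Q levels")
})

test_that("fitted curve is monotone in Q and phi matches the numeric slope", {
  set.seed(3)
  for (i in 1:5) {
    truth <- c(runif(1, 0.03, 0.07), runif(1, 20, 45), runif(1, 0.5, 2.5))
    A <- light_response_curve(paper_levels, truth[1], truth[2], truth[3]) +
      rnorm(12, 0, 0.3)
    fit <- fit_light_response(data.frame(Q = paper_levels, A = A))
    qq <- seq(0, 2000, by = 5)
    expect_true(all(diff(predict(fit, data.frame(Q = qq))) >= 0))
    h <- 1e-3
    num_slope <- (predict(fit, data.frame(Q = h)) -
                  predict(fit, data.frame(Q = -h))) / (2 * h)
    expect_rel_equal(num_slope, coef(fit)[["phi"]], 1e-6)
  }
})

test_that("summary extracts measured Asat/gssat and per-level Ci:Ca", {
  n <- 12 * 3
  tr <- accession_truth()
  s <- simulate_light_curve(tr, seed = 5, noise = FALSE)
  s$A[s$Q == 2000] <- 35.0
  fit <- fit_light_response(s)
  sm <- summarize_light_curve(s, fit)
  expect_equal(sm$Asat, 35.0)
  expect_equal(sm$QY, unname(coef(fit)[["phi"]]))

  # constant Ci = 120 / Ca = 400 gives ratio 0.30 at every level
  s2 <- s
  s2$Ci <- rep(120, n); s2$Ca <- rep(400, n)
  sm2 <- summarize_light_curve(s2, fit)
  expect_true(all(abs(sm2$ci_ca_by_level$ci_ca - 0.30) < 1e-12))

  # missing 2000 level errors
  s3 <- simulate_light_curve(tr, seed = 5, noise = FALSE,
                             levels = c(1000, 500, 200, 100, 20, 0))
  expect_error(summarize_light_curve(s3, fit), "2000")
})

test_that("generated Ci:Ca ratios sit in the 0.25-0.35 band at Q >= 250", {
  tr <- accession_truth()
  for (seed in 1:5) {
    sm <- summarize_light_curve(simulate_light_curve(tr, seed = seed))
    hi <- sm$ci_ca_by_level[sm$ci_ca_by_level$Q >= 250, "ci_ca"]
    expect_true(all(hi >= 0.25 & hi <= 0.35))
  }
})

test_that("A-gs regression recovers an exact line and rejects degenerate input", {
  gs <- seq(0.05, 0.25, by = 0.05)
  A <- -1.7 + 200 * gs
  r <- a_gs_regression(A, gs)
  expect_equal(r$slope, 200, tolerance = 1e-10)
  expect_equal(r$intercept, -1.7, tolerance = 1e-10)
  expect_equal(r$R, 1, tolerance = 1e-10)
  expect_error(a_gs_regression(rep(5, 5), gs), "constant")
  expect_error(a_gs_regression(A, rep(0.1, 5)), "zero variance")
  expect_error(a_gs_regression(A[1:2], gs[1:2]), "at least 3")
})

test_that("regression slope is recovered across seeds at measurement noise", {
  tr <- accession_truth(coupling_slope = 150, coupling_intercept = -5)
  slopes <- sapply(1:20, function(i) {
    s <- simulate_light_curve(tr, seed = 100 + i)
    a_gs_regression(s)$slope
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 150), 2 * se + 5)
})

test_that("linear low-light QY estimate tracks the parameter form", {
  tr <- accession_truth()
  s <- simulate_light_curve(tr, seed = 2, noise = FALSE)
  # the secant slope over finite low-light levels underestimates the true
  # initial slope slightly; it must still be in its neighborhood
  expect_rel_equal(qy_linear(s), 0.05, 0.15)
})
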