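test_that("split_step finds the canonical step and rejects odd traces", {
  tr <- accession_truth()
  s <- simulate_step_response(tr, seed = 1)
  ph <- split_step(s)
  expect_equal(ph$t_step, 300)
  expect_equal(nrow(ph$baseline), 30L)
  expect_equal(nrow(ph$response), 181L)
  expect_equal(nrow(ph$baseline) + nrow(ph$response), nrow(s))

  # plateau jitter does not defeat detection
  s2 <- s
  set.seed(4)
  s2$Q <- ifelse(s$Q < 500, runif(nrow(s), 98, 103), runif(nrow(s), 995, 1005))
  ph2 <- split_step(s2)
  expect_equal(ph2$t_step, 300)

  # two steps is an error
  s3 <- s
  s3$Q[150:180] <- 100
  expect_error(split_step(s3), "one upward")
  # a light-curve series is refused
  lc <- simulate_light_curve(tr, seed = 1)
  expect_error(split_step(lc), "step_change")
})

test_that("noiseless induction fits recover truth to 1e-6 relative", {
  tr <- accession_truth(k_gs = 100, k_A = 100, lam = 60)
  ph <- split_step(simulate_step_response(tr, seed = 1, noise = FALSE))
  for (v in c("A", "gs")) {
    f <- fit_induction(ph, v)
    expect_false(f$no_response)
    expect_rel_equal(coef(f)[["k"]], 100, 1e-6)
    expect_rel_equal(coef(f)[["lam"]], 60, 1e-6)
    expect_equal(f$tau, unname(coef(f)[["k"]]))
  }
})

test_that("median relative error of k stays below 10% at stated noise", {
  errs <- sapply(1:20, function(i) {
    tr <- accession_truth(k_gs = 100, lam = 60)
    ph <- split_step(simulate_step_response(tr, seed = 2000 + i))
    f <- fit_induction(ph, "gs")
    abs(coef(f)[["k"]] - 100) / 100
  })
  expect_lte(median(errs), 0.10)
})

test_that("flat traces are flagged as no-response, not fitted", {
  tr <- accession_truth()
  s <- simulate_step_response(tr, seed = 3)
  s$gs <- rnorm(nrow(s), 0.08, 0.005)  # no step in gs
  s <- gasx_series("p", "a", "step_change", t = seq(0, 2100, 10), Q = s$Q,
                   A = s$A, gs = pmax(s$gs, 0), Ci = s$Ci, Ca = s$Ca)
  f <- fit_induction(split_step(s), "gs")
  expect_true(f$no_response)
  expect_true(is.na(f$tau))
  expect_error(predict(f), "no-response")
})

test_that("time-origin shift leaves k and the amplitude unchanged", {
  tr <- accession_truth(k_gs = 200, lam = 45)
  s <- simulate_step_response(tr, seed = 8)
  f0 <- fit_induction(split_step(s), "gs")
  s2 <- gasx_series(attr(s, "plant_id"), attr(s, "accession"), "step_change",
                    t = s$t + 1234, Q = s$Q, A = s$A, gs = s$gs,
                    Ci = s$Ci, Ca = s$Ca)
  f2 <- fit_induction(split_step(s2), "gs")
  expect_equal(coef(f2)[["k"]], coef(f0)[["k"]], tolerance = 1e-6)
  expect_equal(coef(f2)[["lam"]], coef(f0)[["lam"]], tolerance = 1e-5)
  expect_equal(coef(f2)[["yf"]] - coef(f2)[["y0"]],
               coef(f0)[["yf"]] - coef(f0)[["y0"]], tolerance = 1e-6)
})

test_that("fitted sigmoid is monotone and stays near the data range", {
  for (seed in 1:5) {
    tr <- accession_truth(k_gs = c(60, 150, 400, 700, 1000)[seed])
    ph <- split_step(simulate_step_response(tr, seed = 40 + seed))
    f <- fit_induction(ph, "gs")
    tt <- data.frame(t = seq(0, 1800, by = 5))
    pr <- predict(f, tt)
    expect_true(all(diff(pr) >= -1e-12))
    rng <- range(f$data$y)
    noise_scale <- 5 * tr$noise_gs
    expect_true(all(pr >= rng[1] - noise_scale & pr <= rng[2] + noise_scale))
  }
})

test_that("a closing (downward) response fits with the same machinery", {
  tr <- accession_truth()
  s <- simulate_step_response(tr, seed = 9, noise = FALSE)
  # mirror the trace: high-to-low step still has one upward Q transition
  s2 <- gasx_series("p", "a", "step_change", t = s$t, Q = s$Q,
                    A = s$A, gs = rev(s$gs), Ci = s$Ci, Ca = s$Ca)
  f <- fit_induction(split_step(s2), "gs")
  expect_false(f$no_response)
  expect_lt(coef(f)[["yf"]], coef(f)[["y0"]])
})

test_that("Wi timecourse masks tiny conductances and is scale invariant", {
  s <- make_flat_series(A = 20, gs = 0.1)
  wi <- wi_timecourse(s)
  expect_true(all(wi$Wi == 200))

  s$gs[3] <- 0
  s$gs[4] <- 0.004
  wi2 <- wi_timecourse(s)
  expect_true(is.na(wi2$Wi[3]))
  expect_true(is.na(wi2$Wi[4]))
  expect_equal(wi2$Wi[5], 200)

  s3 <- make_flat_series(A = 60, gs = 0.3)  # both channels scaled by 3
  expect_equal(wi_timecourse(s3)$Wi, wi_timecourse(make_flat_series(A = 20))$Wi)
  expect_true(all(wi_timecourse(s3)$Wi == 200))
})

test_that("steady-state Wi averages the last five minutes of each phase", {
  s <- make_step_series(A_low = 12, A_high = 18, gs_low = 0.1, gs_high = 0.1)
  wi <- steady_state_wi(split_step(s))
  expect_equal(wi$Wi_low, 120)
  expect_equal(wi$Wi_high, 180)

  # 10-sample brute-force oracle on the baseline window
  ph <- split_step(s)
  base <- ph$baseline
  oracle <- naive_window_mean(base$t, base$A / base$gs,
                              max(base$t) - 300, max(base$t))
  expect_equal(wi$Wi_low, oracle$mean)

  short <- make_step_series(t_step = 100, t_end = 500)
  expect_error(steady_state_wi(split_step(short)), "baseline")
})
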