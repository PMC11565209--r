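test_that("gasx_series enforces its invariants", {
  t <- c(0, 10, 20)
  ok <- gasx_series("p", "a", "light_curve", t, Q = c(0, 100, 200),
                    A = c(-1, 2, 5), gs = c(0.01, 0.02, 0.05),
                    Ci = c(400, 200, 150), Ca = c(400, 400, 400))
  expect_s3_class(ok, "gasx_series")
  expect_error(gasx_series("p", "a", "light_curve", c(0, 10, 10),
                           c(0, 1, 2), c(1, 2, 3), c(0.1, 0.1, 0.1),
                           c(1, 1, 1), c(400, 400, 400)),
               "row 3")
  expect_error(gasx_series("p", "a", "light_curve", t, c(0, -1, 2),
                           c(1, 2, 3), c(0.1, 0.1, 0.1), c(1, 1, 1),
                           c(400, 400, 400)), "Q")
  expect_error(gasx_series("p", "a", "light_curve", c(0, 10), c(0, 1),
                           c(1, 2, 3), c(0.1, 0.1), c(1, 1), c(400, 400)),
               "length")
  expect_warning(gasx_series("p", "a", "light_curve", t, c(0, 1, 2),
                             c(1, 2, 3), c(0.1, 0.1, 0.1), c(1, 1, 1),
                             c(400, 400, 350)), "set-point")
})

test_that("reading a written table is lossless and grouping works", {
  tr <- accession_truth()
  s <- simulate_step_response(tr, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gasx_table(s, path, sep = ",")
  back <- read_gasx_table(path)
  expect_length(back, 1L)
  b <- back[[1L]]
  expect_equal(attr(b, "protocol"), "step_change")
  expect_equal(attr(b, "plant_id"), attr(s, "plant_id"))
  expect_equal(nrow(b), 211L)
  for (col in c("t", "Q", "A", "gs", "Ci", "Ca"))
    expect_equal(b[[col]], s[[col]], tolerance = 0, ignore_attr = TRUE)
})

test_that("reader reports missing columns and bad cells precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,Q,A,gs,Ci", "0,1,2,0.1,100"), path)
  expect_error(read_gasx_table(path), "Ca")
  writeLines(c("t,Q,A,gs,Ci,Ca", "0,1,2,0.1,100,400",
               "10,1,oops,0.1,100,400"), path)
  expect_error(read_gasx_table(path), "row 2")
})

test_that("column-name synonyms of different instrument dialects map", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Elapsed,PARi,Photo,Cond,Ci,CO2S",
               "0,100,3,0.06,250,400", "10,100,3.1,0.06,251,400",
               "20,100,3,0.061,250,400"), path)
  s <- read_gasx_table(path)[[1L]]
  expect_equal(s$A, c(3, 3.1, 3))
  expect_equal(s$gs, c(0.06, 0.06, 0.061))
})

test_that("window_mean matches a brute-force loop and honors closed bounds", {
  # A = t on t = 0..100 at 10 s spacing: mean over [0,100] is 50 with n = 11
  t <- seq(0, 100, 10)
  s <- gasx_series("p", "a", "light_curve", t, Q = rep(1, 11), A = t,
                   gs = rep(0.1, 11), Ci = rep(120, 11), Ca = rep(400, 11))
  wm <- window_mean(s, "A", 0, 100)
  expect_equal(wm$mean, 50)
  expect_equal(wm$n, 11L)

  flat <- make_flat_series(A = 10)
  expect_equal(window_mean(flat, "A", 37, 203)$mean, 10)

  set.seed(99)
  t2 <- seq(1400, 1900, by = 10)
  v <- rnorm(length(t2), 5, 2)
  s2 <- gasx_series("p", "a", "step_change", t2, Q = rep(1000, length(t2)),
                    A = v, gs = rep(0.1, length(t2)), Ci = rep(120, length(t2)),
                    Ca = rep(400, length(t2)))
  oracle <- naive_window_mean(t2, v, 1500, 1800)
  got <- window_mean(s2, "A", 1500, 1800)
  expect_equal(got$mean, oracle$mean)
  expect_equal(got$n, oracle$n)
  expect_error(window_mean(s2, "A", 100, 200), "empty window")
  expect_error(window_mean(s2, "A", 300, 200), "t_start")
})

test_that("validate_protocol passes canonical series and warns on gaps", {
  tr <- accession_truth()
  lc <- simulate_light_curve(tr, seed = 1)
  expect_true(all(validate_protocol(lc)$status == "pass"))
  st <- simulate_step_response(tr, seed = 1)
  expect_true(all(validate_protocol(st)$status == "pass"))

  few <- simulate_light_curve(tr, seed = 1,
                              levels = c(2000, 1000, 500, 100, 0))
  rep5 <- validate_protocol(few)
  expect_true(any(grepl("incomplete protocol", rep5$note)))
})

test_that("anatomy records validate geometry and surfaces", {
  df <- data.frame(plant_id = "p1", accession = "a", surface = "abaxial",
                   field_count = 10, field_area_mm2 = 0.29,
                   gcl_um = 40, pore_um = 20)
  expect_s3_class(anatomy_records(df), "anatomy_records")
  bad <- df; bad$pore_um <- 45
  expect_error(anatomy_records(bad), "pore_um must be <")
  bad2 <- df; bad2$surface <- "top"
  expect_error(anatomy_records(bad2), "surface")
  bad3 <- df; bad3$field_count <- -1
  expect_error(anatomy_records(bad3), "field_count")
})

test_that("constants validate and carry sane defaults", {
  k <- gasx_constants()
  expect_equal(k$d, 2.46e-5)
  expect_equal(k$v, 2.44e-2)
  expect_error(gasx_constants(d = -1), "d")
  expect_error(gasx_constants(v = 0), "v")
})
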