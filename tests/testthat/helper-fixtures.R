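# shared fixture builders; everything is generated in code at test time

make_flat_series <- function(A = 10, n = 31, dt = 10, gs = 0.1,
                             protocol = "light_curve") {
  t <- dt * (seq_len(n) - 1L)
  gasx_series(plant_id = "p1", accession = "acc1", protocol = protocol,
              t = t, Q = rep(500, n), A = rep(A, n), gs = rep(gs, n),
              Ci = rep(120, n), Ca = rep(400, n))
}

make_step_series <- function(t_step = 300, dt = 10, t_end = 2100,
                             Q_low = 100, Q_high = 1000,
                             A_low = 3, A_high = 18,
                             gs_low = 0.06, gs_high = 0.15) {
  t <- seq(0, t_end, by = dt)
  high <- t >= t_step
  gasx_series(plant_id = "p1", accession = "acc1", protocol = "step_change",
              t = t, Q = ifelse(high, Q_high, Q_low),
              A = ifelse(high, A_high, A_low),
              gs = ifelse(high, gs_high, gs_low),
              Ci = rep(120, length(t)), Ca = rep(400, length(t)))
}

# brute-force mean by an explicit loop (independent of window_mean internals)
naive_window_mean <- function(t, v, lo, hi) {
  s <- 0; n <- 0L
  for (i in seq_along(t)) if (t[i] >= lo && t[i] <= hi) { s <- s + v[i]; n <- n + 1L }
  list(mean = s / n, n = n)
}

# one-way sums of squares from first principles
naive_oneway_F <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  lev <- unique(groups)
  ss_b <- 0; ss_w <- 0
  for (g in lev) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - gm)^2
    ss_w <- ss_w + sum((v - mean(v))^2)
  }
  df_b <- length(lev) - 1L
  df_w <- length(values) - length(lev)
  list(F = (ss_b / df_b) / (ss_w / df_w), df_b = df_b, df_w = df_w,
       ss_b = ss_b, ss_w = ss_w)
}

# exhaustive check of the letter-display contract against the pairwise calls
cld_contract_holds <- function(letters, nonsig) {
  k <- nrow(nonsig)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    share <- length(intersect(strsplit(letters[i], "")[[1L]],
                              strsplit(letters[j], "")[[1L]])) > 0L
    if (share != nonsig[i, j]) return(FALSE)
  }
  TRUE
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
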