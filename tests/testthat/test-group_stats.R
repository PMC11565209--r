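test_that("identical groups give F ~ 0 and separated groups give tiny p", {
  v <- rep(c(1, 2, 3), 3)
  g <- rep(letters[1:3], each = 3)
  at <- anova_table(v, g)
  expect_equal(at$statistic[at$term == "f1"], 0, tolerance = 1e-12)
  expect_equal(at$p[at$term == "f1"], 1, tolerance = 1e-12)

  set.seed(1)
  v2 <- c(rnorm(3, 0, 1e-4), rnorm(3, 10, 1e-4))
  at2 <- anova_table(v2, rep(c("a", "b"), each = 3))
  expect_lt(at2$p[at2$term == "f1"], 1e-6)
})

test_that("one-way F matches a from-scratch sum-of-squares computation", {
  set.seed(21)
  v <- c(rnorm(3, 5), rnorm(5, 6), rnorm(4, 5.5))  # unbalanced on purpose
  g <- rep(c("a", "b", "c"), times = c(3, 5, 4))
  at <- anova_table(v, g)
  oracle <- naive_oneway_F(v, g)
  expect_equal(at$statistic[at$term == "f1"], oracle$F, tolerance = 1e-10)
  expect_equal(at$df[at$term == "f1"], oracle$df_b)
  expect_equal(at$sumsq[at$term == "f1"], oracle$ss_b, tolerance = 1e-10)
  expect_equal(at$sumsq[at$term == "Residuals"], oracle$ss_w, tolerance = 1e-10)
})

test_that("two-way ANOVA includes requested interaction and validates input", {
  set.seed(2)
  d <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y", "z"), rep = 1:3)
  v <- rnorm(nrow(d)) + as.numeric(d$f1 == "b")
  at <- anova_table(v, d$f1, d$f2, interaction = TRUE)
  expect_setequal(at$term, c("f1", "f2", "f1:f2", "Residuals"))
  at2 <- anova_table(v, d$f1, d$f2, interaction = FALSE)
  expect_false("f1:f2" %in% at2$term)
  expect_error(anova_table(v, rep("a", length(v))), ">= 2 levels")
})

test_that("zero residual variance is reported as degenerate with p = 0", {
  v <- rep(c(1, 5, 9), each = 3)
  at <- anova_table(v, rep(c("a", "b", "c"), each = 3))
  expect_true(isTRUE(attr(at, "degenerate")))
  expect_equal(at$p[at$term == "f1"], 0)
})

test_that("two-group Tukey reduces to the pooled t-test with q = t*sqrt(2)", {
  set.seed(31)
  v <- c(rnorm(6, 0), rnorm(9, 1))  # unequal n: Tukey-Kramer path
  g <- rep(c("a", "b"), times = c(6, 9))
  th <- tukey_hsd(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(th$pairs$q_stat, abs(tt$statistic[[1]]) * sqrt(2),
               tolerance = 1e-9)
  # with two means the studentized range p equals the t-test p
  expect_equal(th$pairs$p_adj, tt$p.value, tolerance = 1e-9)
})

test_that("Tukey agrees with stats::TukeyHSD on an unbalanced fixture", {
  set.seed(5)
  v <- c(rnorm(4, 0), rnorm(6, 1.2), rnorm(5, 0.3), rnorm(8, 2))
  g <- rep(c("g1", "g2", "g3", "g4"), times = c(4, 6, 5, 8))
  th <- tukey_hsd(v, g)
  ref <- TukeyHSD(aov(v ~ factor(g)))[[1]]
  key <- paste(th$pairs$group_j, th$pairs$group_i, sep = "-")
  expect_equal(th$pairs$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-8)
  expect_equal(th$pairs$mean_diff, unname(ref[key, "diff"]), tolerance = 1e-10)
})

test_that("well-separated groups get distinct letters, flat data one letter", {
  set.seed(6)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 5, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("a", "b", "c"), each = 5)
  th <- tukey_hsd(v, g)
  expect_equal(unname(th$letters[c("a", "b", "c")]), c("a", "b", "c"))

  nonsig <- matrix(TRUE, 3, 3, dimnames = list(1:3, 1:3))
  expect_true(all(compact_letter_display(nonsig) == "a"))
})

test_that("the chain case A!=B, B~C, A!=C yields a / b / b", {
  m <- matrix(c(TRUE, FALSE, FALSE,
                FALSE, TRUE, TRUE,
                FALSE, TRUE, TRUE), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- compact_letter_display(m)
  expect_equal(unname(cl), c("a", "b", "b"))
})

test_that("letter display rejects malformed matrices", {
  m <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  expect_error(compact_letter_display(m), "symmetric")
  d <- diag(c(TRUE, TRUE)); d[1, 1] <- FALSE
  expect_error(compact_letter_display(matrix(as.logical(d), 2, 2)), "diagonal")
})

test_that("letter display satisfies the share-letter biconditional on random data", {
  set.seed(8)
  for (i in 1:200) {
    mu <- sample(c(0, 0, 1, 2, 4, 8), 6, replace = TRUE)
    v <- rnorm(6 * 4, rep(mu, each = 4), 1)
    g <- rep(paste0("g", 1:6), each = 4)
    th <- tukey_hsd(v, g)
    k <- length(th$groups)
    nonsig <- diag(TRUE, k)
    for (m in seq_len(nrow(th$pairs))) {
      i1 <- match(th$pairs$group_i[m], th$groups)
      i2 <- match(th$pairs$group_j[m], th$groups)
      nonsig[i1, i2] <- nonsig[i2, i1] <- th$pairs$p_adj[m] > th$alpha
    }
    expect_true(cld_contract_holds(unname(th$letters[th$groups]), nonsig))
  }
})

test_that("letters are invariant to group relabeling up to permutation", {
  set.seed(9)
  v <- rnorm(24, rep(c(0, 1, 4, 4.2), each = 6))
  g1 <- rep(c("a", "b", "c", "d"), each = 6)
  g2 <- rep(c("w", "x", "y", "z"), each = 6)
  l1 <- tukey_hsd(v, g1)$letters
  l2 <- tukey_hsd(v, g2)$letters
  expect_equal(unname(l1), unname(l2))
})

test_that("Tukey adjusted p never undercuts the pairwise t-test p", {
  set.seed(10)
  v <- rnorm(20, rep(c(0, 0.5, 1, 3), each = 5))
  g <- rep(paste0("g", 1:4), each = 5)
  th <- tukey_hsd(v, g)
  for (m in seq_len(nrow(th$pairs))) {
    # unadjusted pairwise t on the same pooled error as the Tukey test
    tstat <- th$pairs$q_stat[m] / sqrt(2)
    p_t <- 2 * pt(-tstat, df = th$df_error)
    expect_gte(th$pairs$p_adj[m] + 1e-12, p_t)
  }
})

test_that("pearson matches the naive covariance formula and validates input", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$R, 1)
  expect_equal(pearson(1:10, -(1:10))$R, -1)
  set.seed(11)
  x <- rnorm(10); y <- x + rnorm(10)
  r <- pearson(x, y)
  naive <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$R, naive, tolerance = 1e-12)
  tstat <- naive * sqrt(8 / (1 - naive^2))
  expect_equal(r$p, 2 * pt(-abs(tstat), df = 8), tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})
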