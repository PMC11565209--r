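#' One- or two-way fixed-effects ANOVA table
#'
#' Thin wrapper around [stats::aov()] returning a tidy table with sequential
#' (Type I) sums of squares, matching how unbalanced designs are decomposed
#' by `aov`. For two factors the interaction term is included on request.
#'
#' @param values Numeric response vector.
#' @param f1 First factor (coerced with [factor()]).
#' @param f2 Optional second factor.
#' @param interaction Include the `f1:f2` interaction (two-way only).
#' @return Data frame with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic` (F), `p`. If the residual variance is exactly zero the
#'   p-values are reported as 0 and the attribute `degenerate` is set.
#' @export
anova_table <- function(values, f1, f2 = NULL, interaction = TRUE) {
  f1 <- factor(f1)
  if (nlevels(f1) < 2L) stop("factor 1 needs >= 2 levels", call. = FALSE)
  if (any(table(f1) < 1L)) stop("every factor level needs >= 1 observation",
                                call. = FALSE)
  dat <- data.frame(y = values, f1 = f1)
  if (is.null(f2)) {
    form <- y ~ f1
  } else {
    dat$f2 <- factor(f2)
    if (nlevels(dat$f2) < 2L) stop("factor 2 needs >= 2 levels", call. = FALSE)
    form <- if (interaction) y ~ f1 * f2 else y ~ f1 + f2
  }
  fit <- stats::aov(form, data = dat)
  tab <- summary(fit)[[1L]]
  resid_df <- tab[nrow(tab), "Df"]
  if (resid_df < 2L) stop("need >= 2 residual degrees of freedom", call. = FALSE)
  out <- data.frame(term = trimws(rownames(tab)),
                    df = tab[["Df"]],
                    sumsq = tab[["Sum Sq"]],
                    meansq = tab[["Mean Sq"]],
                    statistic = tab[["F value"]],
                    p = tab[["Pr(>F)"]])
  rownames(out) <- NULL
  ms_resid <- out$meansq[out$term == "Residuals"]
  if (ms_resid <= .Machine$double.eps * max(abs(values))^2) {
    sig <- out$term != "Residuals" & out$sumsq > 0
    out$p[sig] <- 0
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Tukey's honestly-significant-difference test with letter groupings
#'
#' All pairwise comparisons of group means after a one-way layout, using the
#' studentized-range distribution. Unequal replication is handled by the
#' Tukey-Kramer correction: the standard error of a pair (i, j) is
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))`. Adjusted p-values come from
#' [stats::ptukey()] with `k` means and `N - k` error degrees of freedom.
#' Groups are summarised by a compact letter display
#' ([compact_letter_display()]): two groups share a letter iff their
#' adjusted p exceeds `alpha`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups; letters are assigned in sorted
#'   label order for determinism).
#' @param alpha Family significance level in (0, 0.5].
#' @return Object of class `"tukey_hsd"`: `pairs` (data frame with
#'   `group_i`, `group_j`, `mean_diff`, `se`, `q_stat`, `p_adj`), `letters`
#'   (named character vector), `means`, `n`, `df_error`, `mse`, `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2L) stop("Tukey HSD needs at least 2 groups", call. = FALSE)
  stopifnot(alpha > 0, alpha <= 0.5)
  ns <- tapply(values, g, length)
  means <- tapply(values, g, mean)
  N <- length(values)
  df_err <- N - k
  if (df_err < 1L) stop("no residual degrees of freedom", call. = FALSE)
  sse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  mse <- sse / df_err
  lev <- levels(g)
  comb <- utils::combn(k, 2L)
  gi <- comb[1L, ]; gj <- comb[2L, ]
  diff <- means[gj] - means[gi]
  se <- sqrt(mse / 2 * (1 / ns[gi] + 1 / ns[gj]))
  q <- abs(diff) / se
  p_adj <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
  pairs <- data.frame(group_i = lev[gi], group_j = lev[gj],
                      mean_diff = as.numeric(diff), se = as.numeric(se),
                      q_stat = as.numeric(q), p_adj = as.numeric(p_adj))
  nonsig <- diag(TRUE, k)
  rownames(nonsig) <- colnames(nonsig) <- lev
  for (m in seq_len(ncol(comb))) {
    ns_m <- pairs$p_adj[m] > alpha
    nonsig[gi[m], gj[m]] <- ns_m
    nonsig[gj[m], gi[m]] <- ns_m
  }
  letters <- compact_letter_display(nonsig)
  structure(list(pairs = pairs, letters = letters,
                 means = as.numeric(means), n = as.integer(ns),
                 groups = lev, df_error = df_err, mse = mse, alpha = alpha),
            class = "tukey_hsd")
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat(sprintf("Tukey HSD (alpha = %g, %d groups, error df = %d)\n",
              x$alpha, length(x$groups), x$df_error))
  df <- data.frame(group = x$groups, n = x$n, mean = signif(x$means, 5),
                   letters = unname(x$letters[x$groups]))
  print(df, row.names = FALSE)
  cat("\nPairwise comparisons:\n")
  out <- x$pairs
  out$p_adj <- signif(out$p_adj, 4)
  out$q_stat <- signif(out$q_stat, 4)
  print(out, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compact letter display from a non-significance matrix
#'
#' Insert-and-absorb construction: start with a single letter covering all
#' groups; for each significant pair, every letter set containing both
#' members is split into two copies, one without each member; sets that are
#' subsets of another are absorbed, to a fixpoint. The result is
#' deterministic given the matrix row order and satisfies the display
#' contract: two groups share at least one letter iff their pair is
#' non-significant.
#'
#' @param nonsig Square logical matrix, `TRUE` where the pair is NOT
#'   significantly different. Must be symmetric with a `TRUE` diagonal; row
#'   names (if any) label the groups.
#' @return Named character vector: letter string per group (letters
#'   `a`, `b`, ... in first-member order).
#' @export
compact_letter_display <- function(nonsig) {
  stopifnot(is.matrix(nonsig), is.logical(nonsig))
  k <- nrow(nonsig)
  if (ncol(nonsig) != k) stop("matrix must be square", call. = FALSE)
  if (!all(diag(nonsig))) stop("diagonal must be TRUE", call. = FALSE)
  if (!isTRUE(all(nonsig == t(nonsig))))
    stop("non-significance matrix must be symmetric", call. = FALSE)
  labels <- rownames(nonsig)
  if (is.null(labels)) labels <- as.character(seq_len(k))

  sets <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (nonsig[i, j]) next
    hit <- vapply(sets, function(s) s[i] && s[j], logical(1))
    if (!any(hit)) next
    new_sets <- list()
    for (m in seq_along(sets)) {
      if (!hit[m]) { new_sets[[length(new_sets) + 1L]] <- sets[[m]]; next }
      a <- sets[[m]]; a[i] <- FALSE
      b <- sets[[m]]; b[j] <- FALSE
      new_sets[[length(new_sets) + 1L]] <- a
      new_sets[[length(new_sets) + 1L]] <- b
    }
    # absorb: drop any set contained in another (incl. duplicates)
    keep <- rep(TRUE, length(new_sets))
    for (a_i in seq_along(new_sets)) for (b_i in seq_along(new_sets)) {
      if (a_i == b_i || !keep[a_i] || !keep[b_i]) next
      sub <- all(!new_sets[[a_i]] | new_sets[[b_i]])
      eq <- identical(new_sets[[a_i]], new_sets[[b_i]])
      if (sub && (!eq || a_i > b_i)) keep[a_i] <- FALSE
    }
    sets <- new_sets[keep]
  }
  sets <- sets[vapply(sets, any, logical(1))]
  first <- vapply(sets, function(s) which(s)[1L], integer(1))
  sets <- sets[order(first, -vapply(sets, sum, integer(1)))]
  letts <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(k), function(g)
    paste(letts[which(vapply(sets, function(s) s[g], logical(1)))],
          collapse = ""), character(1))
  names(out) <- labels
  out
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation and its two-sided p-value from the
#' t-transform with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return List with `R`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}
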