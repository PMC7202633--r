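make_design <- function(n_cell, means = c(0, 0, 0, 0), sd = 1, seed = 1) {
  set.seed(seed)
  g <- rep(rep(c("Control", "DbDb"), each = n_cell), 2)
  d <- rep(c("CD", "WD"), each = 2 * n_cell)
  mu <- means[as.integer(interaction(g, d, lex.order = TRUE))]
  data.frame(y = rnorm(length(g), mu, sd), genotype = g, diet = d)
}

test_that("constant data yield zero F and p = 1 for every effect", {
  df <- make_design(3)
  df$y <- 5
  expect_warning(a <- two_way_anova(df$y, df$genotype, df$diet),
                 "zero residual")
  eff <- a[a$effect != "Residuals", ]
  expect_equal(eff$F, c(0, 0, 0))
  expect_equal(eff$p, c(1, 1, 1))
})

test_that("residual df is N - 4 and p values are probabilities", {
  df <- make_design(7, means = c(0, 1, 0.5, 2), seed = 3)
  a <- two_way_anova(df$y, df$genotype, df$diet)
  expect_equal(a$df[a$effect == "Residuals"], nrow(df) - 4)
  eff <- a[a$effect != "Residuals", ]
  expect_setequal(eff$effect, c("genotype", "diet", "interaction"))
  expect_true(all(eff$p >= 0 & eff$p <= 1))
})

test_that("Type II sums of squares match the sequential fit on balanced data", {
  df <- make_design(6, means = c(0, 1, 0.5, 1.8), seed = 11)
  a2 <- two_way_anova(df$y, df$genotype, df$diet)
  a1 <- anova(lm(y ~ genotype * diet, data = df))   # Type I reference
  for (eff in c("genotype", "diet")) {
    expect_equal(a2$sum_sq[a2$effect == eff], a1[eff, "Sum Sq"],
                 tolerance = 1e-10)
  }
})

test_that("one-way ANOVA p equals the pooled two-sample t-test (F = t^2)", {
  set.seed(21)
  for (i in 1:10) {
    y <- rnorm(24)
    g <- rep(c("a", "b"), each = 12)
    a <- two_way_anova(y, g)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(a$p[a$effect == "genotype"], tt$p.value, tolerance = 1e-9)
    expect_equal(a$F[a$effect == "genotype"], unname(tt$statistic)^2,
                 tolerance = 1e-9)
  }
})

test_that("degenerate designs are rejected", {
  df <- make_design(3)
  expect_error(two_way_anova(df$y[df$diet == "CD"],
                             df$genotype[df$diet == "CD"],
                             df$diet[df$diet == "CD"]), "two levels")
  # empty cell
  keep <- !(df$genotype == "DbDb" & df$diet == "WD")
  expect_error(two_way_anova(df$y[keep], df$genotype[keep], df$diet[keep]),
               "degenerate")
  # single observation in a cell
  drop1 <- which(df$genotype == "DbDb" & df$diet == "WD")[-1]
  expect_error(two_way_anova(df$y[-drop1], df$genotype[-drop1],
                             df$diet[-drop1]), "degenerate")
})

test_that("identical groups get Tukey p near 1; separation drives p down", {
  y <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  tk <- tukey_hsd(y, g)
  expect_equal(tk$p_adj, 1, tolerance = 1e-9)

  # monotonicity: growing one group's mean shrinks its p against a fixed one
  set.seed(5)
  base <- rnorm(10)
  p_prev <- 1
  for (shift in c(0.5, 1.5, 3)) {
    yy <- c(base, base + shift)
    p <- tukey_hsd(yy, rep(c("a", "b"), each = 10))$p_adj
    expect_lt(p, p_prev + 1e-12)
    p_prev <- p
  }
})

test_that("Tukey adjusted p dominates the unadjusted pairwise t-test p", {
  set.seed(9)
  df <- make_design(5, means = c(0, 0.8, 0.3, 1.4), seed = 9)
  grp <- paste(df$genotype, df$diet, sep = "/")
  tk <- tukey_hsd(df$y, grp)
  mse <- sum(resid(aov(df$y ~ grp))^2) / (nrow(df) - 4)
  for (i in seq_len(nrow(tk))) {
    gs <- strsplit(tk$pair[i], "-", fixed = TRUE)[[1]]
    y1 <- df$y[grp == gs[1]]; y2 <- df$y[grp == gs[2]]
    tstat <- abs(mean(y1) - mean(y2)) /
      sqrt(mse * (1 / length(y1) + 1 / length(y2)))
    p_unadj <- 2 * pt(tstat, df = nrow(df) - 4, lower.tail = FALSE)
    expect_gte(tk$p_adj[i] + 1e-12, p_unadj)
  }
})

test_that("group summaries report n, mean and sample sd", {
  s <- summarize_groups(c(1, 2, 3), rep("a", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  s2 <- summarize_groups(c(1, 2, 3, 9), c("a", "a", "a", "b"))
  expect_true(s2$degenerate[s2$group == "b"])
  expect_true(is.na(s2$sd[s2$group == "b"]))

  # sampling check against generating distributions
  set.seed(31)
  mu <- c(16.59, 14.32); sdv <- c(4.98, 3.65); n <- 200
  y <- c(rnorm(n, mu[1], sdv[1]), rnorm(n, mu[2], sdv[2]))
  lab <- rep(c("Control", "DbDb"), each = n)
  s3 <- summarize_groups(y, lab)
  for (i in 1:2)
    expect_lt(abs(s3$mean[i] - mu[i]), 2 * sdv[i] / sqrt(n))
})
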