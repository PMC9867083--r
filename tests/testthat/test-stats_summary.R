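test_that("Welch tests from summaries reproduce the published statistics", {
  cases <- list(
    list(a = c(224.1, 11.01, 24), b = c(288.4, 7.51, 36),
         t = 4.825, df = 43.23),
    list(a = c(69.57, 2.15, 24), b = c(73.20, 2.71, 28),
         t = 1.049, df = 48.93),
    list(a = c(238.3, 11.48, 16), b = c(284.8, 7.01, 36),
         t = 3.457, df = 26.68))
  for (cs in cases) {
    w <- welch_from_summary(group_summary("a", cs$a[1], cs$a[2], cs$a[3]),
                            group_summary("b", cs$b[1], cs$b[2], cs$b[3]))
    expect_equal(w$statistic, cs$t, tolerance = 5e-4)
    expect_equal(w$df1, cs$df, tolerance = 2e-4)
  }
})

test_that("Welch test is symmetric and null on identical groups", {
  a <- group_summary("a", 12.3, 1.1, 10)
  b <- group_summary("b", 15.1, 2.3, 14)
  w1 <- welch_from_summary(a, b); w2 <- welch_from_summary(b, a)
  expect_equal(w1$statistic, w2$statistic)
  expect_equal(w1$df1, w2$df1)
  expect_equal(w1$p, w2$p)
  same <- welch_from_summary(a, group_summary("c", 12.3, 1.1, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(welch_from_summary(group_summary("a", 1, 0, 8),
                                  group_summary("b", 2, 0, 8)),
               class = "mesiso_zero_variance")
})

test_that("summary ANOVA reproduces the published F statistics", {
  an <- anova_from_summary(potency_series$pb_scoparone)
  expect_equal(an$statistic, 6.534, tolerance = 1e-3)
  expect_identical(c(an$df1, an$df2), c(2L, 45L))
  expect_lt(abs(an$p - 0.003), 5e-4)
  an2 <- anova_from_summary(potency_series$vpa_borneol)
  expect_equal(an2$statistic, 15.80, tolerance = 3e-3)
  expect_identical(c(an2$df1, an2$df2), c(3L, 68L))
  an3 <- anova_from_summary(potency_series$cbz_scoparone)
  expect_equal(an3$statistic, 2.719, tolerance = 1e-3)
  eqm <- anova_from_summary(data.frame(label = c("a", "b", "c"), mean = 5,
                                       sem = 1, n = 8))
  expect_equal(eqm$statistic, 0)
  expect_error(anova_from_summary(data.frame(label = "a", mean = 1, sem = 1,
                                             n = 8)),
               class = "mesiso_single_group")
})

test_that("two balanced groups give F equal to the squared pooled t", {
  a <- group_summary("a", 10.4, 1.2, 12)
  b <- group_summary("b", 13.9, 1.5, 12)
  an <- anova_from_summary(list(a, b))
  # pooled-variance t on the same summaries
  sp2 <- (11 * (1.2^2 * 12) + 11 * (1.5^2 * 12)) / 22
  t <- (13.9 - 10.4) / sqrt(sp2 * (1 / 12 + 1 / 12))
  expect_equal(an$statistic, t^2, tolerance = 1e-10)
})

test_that("summaries of raw data give the classic one-way ANOVA", {
  set.seed(77)
  g <- rep(c("a", "b", "c"), times = c(8, 10, 9))
  y <- rnorm(length(g), mean = c(a = 10, b = 12, c = 9)[g])
  sums <- lapply(split(y, g), function(v)
    group_summary("x", mean(v), sd(v) / sqrt(length(v)), length(v)))
  an <- anova_from_summary(sums)
  ref <- anova(aov(y ~ g))
  expect_equal(an$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(an$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Tukey-Kramer marks the PB series baseline contrast below 0.01", {
  tk <- tukey_kramer_from_summary(potency_series$pb_scoparone)
  row <- tk$comparisons[tk$comparisons$group2 == "PB + scoparone (50)" &
                        tk$comparisons$group1 == "PB + vehicle", ]
  expect_lt(row$p_adj, 0.01)
  # equal means: all q zero, all adjusted p one
  eqm <- tukey_kramer_from_summary(data.frame(label = c("a", "b", "c"),
                                              mean = 5, sem = 1, n = 8))
  expect_true(all(eqm$comparisons$q == 0))
  expect_true(all(eqm$comparisons$p_adj == 1))
})

test_that("Tukey-Kramer adjusted p matches a Monte-Carlo range oracle", {
  groups <- data.frame(label = c("a", "b", "c"),
                       mean = c(10, 11.6, 12.4), sem = c(0.7, 0.8, 0.75),
                       n = 10)
  tk <- tukey_kramer_from_summary(groups)
  for (i in seq_len(nrow(tk$comparisons))) {
    mc <- mc_tukey_p(tk$comparisons$q[i], k = 3, nu = 27, seed = 100 + i)
    expect_equal(tk$comparisons$p_adj[i], mc, tolerance = 0.01)
  }
})

test_that("Dunnett with one treatment equals the unadjusted pooled t-test", {
  ctrl <- group_summary("ctrl", 10, 1.1, 8)
  trt <- group_summary("t", 12.5, 1.3, 8)
  du <- dunnett_from_summary(ctrl, list(trt))
  cp <- anova_from_summary(list(ctrl, trt))
  t <- du$comparisons$t[1]
  expect_equal(du$comparisons$p_adj[1], 2 * pt(-abs(t), 14),
               tolerance = 1e-4)
  # identical treatments get identical adjusted p
  du3 <- dunnett_from_summary(ctrl, list(trt, trt, trt))
  expect_equal(du3$comparisons$p_adj,
               rep(du3$comparisons$p_adj[1], 3), tolerance = 1e-4)
  expect_error(dunnett_from_summary(ctrl, list()),
               class = "mesiso_no_treatments")
})

test_that("Dunnett adjusted p matches a Monte-Carlo multivariate-t oracle", {
  ctrl <- group_summary("ctrl", 10, 1 / sqrt(8), 8)
  trts <- list(group_summary("t1", 11.1, 1 / sqrt(8), 8),
               group_summary("t2", 10.5, 1 / sqrt(8), 8),
               group_summary("t3", 9.2, 1 / sqrt(8), 8))
  du <- dunnett_from_summary(ctrl, trts)
  for (i in seq_along(trts)) {
    mc <- mc_dunnett_p(abs(du$comparisons$t[i]), k = 3, n_each = 8,
                       seed = 500 + i)
    expect_equal(du$comparisons$p_adj[i], mc, tolerance = 0.01)
  }
  # repeated calls are deterministic
  du2 <- dunnett_from_summary(ctrl, trts)
  expect_identical(du$comparisons$p_adj, du2$comparisons$p_adj)
})

test_that("post-hoc adjusted p-values are never below the unadjusted ones", {
  set.seed(11)
  for (r in 1:20) {
    k <- sample(3:5, 1)
    gs <- lapply(seq_len(k), function(i)
      group_summary(paste0("g", i), rnorm(1, 10, 2), runif(1, 0.5, 1.5),
                    sample(6:12, 1)))
    tk <- tukey_kramer_from_summary(gs)
    df2 <- sum(vapply(gs, `[[`, 0L, "n")) - k
    for (j in seq_len(nrow(tk$comparisons))) {
      q <- tk$comparisons$q[j]
      # unadjusted two-sided p of the same contrast (t = q / sqrt(2))
      p_un <- 2 * pt(-q / sqrt(2), df2)
      expect_gte(tk$comparisons$p_adj[j] + 1e-12, p_un)
    }
    du <- dunnett_from_summary(gs[[1]], gs[-1])
    p_un <- 2 * pt(-abs(du$comparisons$t), df2)
    expect_true(all(du$comparisons$p_adj + 1e-4 >= p_un))
  }
})

test_that("p-value formatting follows the reporting convention", {
  expect_identical(format_p(c(0.00005, 0.002, 0.0499, 0.891)),
                   c("<0.0001", "0.002", "0.050", "0.891"))
  expect_identical(sig_marker(c(0.2, 0.04, 0.009, 0.0005)),
                   c("", "*", "**", "***"))
})
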