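test_that("Welch statistic matches its definition and the reference implementation", {
  x <- c(1, 2, 3, 4)
  w <- welch_t(x, x)
  expect_equal(w$statistic, 0)
  expect_equal(w$p.value, 1)
  # internal identity S_d^2 = S_X^2/n + S_Y^2/m, exactly, on random calls
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1))
    w <- welch_t(a, b)
    expect_identical(w$s2_d, w$s2_x / length(a) + w$s2_y / length(b))
    ref <- t.test(a, b)   # independent reference implementation
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p.value, ref$p.value, tolerance = 1e-10)
  }
  # equal n and equal sample variances: identical to the pooled statistic
  a <- c(0, 1, 2, 3); b <- c(5, 6, 7, 8)   # same spread
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(welch_t(a, b)$statistic, unname(pooled$statistic))
  # degenerate zero-variance equal samples
  z <- rep(1, 5)
  expect_equal(welch_t(z, z)$p.value, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA agrees with pooled t and hand-computed sums of squares", {
  set.seed(11)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  an <- anova_oneway(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p, tt$p.value, tolerance = 1e-10)
  # 3 x 3 toy against manual sum-of-squares arithmetic
  g <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  gm <- mean(unlist(g))
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  Fman <- (ssb / 2) / (ssw / 6)
  an3 <- anova_oneway(g)
  expect_equal(an3$F, Fman, tolerance = 1e-12)
  expect_equal(an3$p, pf(Fman, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("ANOVA null rejection rate is calibrated near alpha", {
  set.seed(12)
  rej <- vapply(1:600, function(i) {
    g <- list(rnorm(10), rnorm(8), rnorm(12))
    anova_oneway(g)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("Tukey-Kramer matches TukeyHSD and the two-group identity", {
  set.seed(13)
  g <- list(HC = rnorm(27), LTLE = rnorm(19, 0.4), RTLE = rnorm(17, 0.1))
  tk <- tukey_kramer(g)
  df <- data.frame(y = unlist(g), grp = factor(rep(names(g), lengths(g))))
  hsd <- TukeyHSD(aov(y ~ grp, df))$grp
  for (i in seq_len(nrow(tk))) {
    key <- paste0(tk$group2[i], "-", tk$group1[i])
    key2 <- paste0(tk$group1[i], "-", tk$group2[i])
    row <- if (key %in% rownames(hsd)) hsd[key, ] else hsd[key2, ]
    expect_equal(tk$p[i], unname(row["p adj"]), tolerance = 1e-8)
  }
  # two groups: q = sqrt(2) |t_pooled|
  g2 <- list(a = rnorm(10), b = rnorm(14, 1))
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  tk2 <- tukey_kramer(g2)
  q <- sqrt(2) * abs(unname(tt$statistic))
  expect_equal(tk2$p, ptukey(q, 2, 22, lower.tail = FALSE),
               tolerance = 1e-10)
  # a far-shifted group is significant only in its own pairs
  g3 <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 50)
  tk3 <- tukey_kramer(g3)
  sig <- tk3$p < 0.05
  involves_c <- tk3$group1 == "c" | tk3$group2 == "c"
  expect_true(all(sig[involves_c]))
  expect_false(any(sig[!involves_c]))
})

test_that("age correction removes an injected trend and little else", {
  set.seed(14)
  n <- 300
  ages <- runif(n, 16, 67)
  base <- rnorm(n, 0.02, 0.01)
  vals <- base + 0.001 * (ages - mean(ages))
  corr <- age_correct(vals, ages)
  expect_equal(attr(corr, "slope"), 0.001, tolerance = 0.25)
  expect_lt(abs(cor(corr, ages)), 1e-10)        # residuals orthogonal to age
  expect_equal(mean(corr), mean(vals), tolerance = 1e-12)
  # zero injected slope: output ~ input
  v0 <- rnorm(n, 0, 0.01)
  c0 <- age_correct(v0, ages)
  expect_lt(abs(attr(c0, "slope")), 5e-4)
  expect_gt(cor(c0, v0), 0.99)
  expect_error(age_correct(v0, rep(30, n)), "constant")
  expect_error(age_correct(1:2, c(1, 2)), "3 subjects")
})

test_that("variance change percentages follow the covariance decomposition", {
  set.seed(15)
  x <- rnorm(50, 0, 0.01)
  expect_equal(variance_change(x, rep(0.003, 50)), 0)
  expect_equal(variance_change(x, x), -100)
  # independent reference of equal variance roughly doubles the variance
  n <- 20000
  a <- rnorm(n); r <- rnorm(n)
  expect_equal(variance_change(a, r), 100, tolerance = 0.05)
  expect_error(variance_change(rep(1, 10), rnorm(10)), "zero")
})

test_that("the variance decomposition identity holds to machine precision", {
  set.seed(16)
  for (i in 1:50) {
    x <- rnorm(sample(3:60, 1), sd = 10^runif(1, -3, 3))
    r <- rnorm(length(x), sd = 10^runif(1, -3, 3))
    bd <- bienayme_decomposition(x, r)
    lhs <- bd$var_diff
    rhs <- bd$var_x + bd$var_r - 2 * bd$cov
    expect_lt(abs(lhs - rhs), 1e-12 * max(abs(lhs), abs(rhs), 1e-300))
  }
  x <- rnorm(30)
  expect_equal(bienayme_decomposition(x, x)$var_diff, 0)
  expect_error(bienayme_decomposition(1:3, 1:4), "length")
})
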