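test_that("Welch ANOVA is zero for identical group distributions", {
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- welch_anova(v, g)
  expect_equal(res$F_welch, 0)
  expect_equal(res$p_omnibus, 1)
})

test_that("two-group Welch F equals the squared Welch t", {
  for (seed in 1:20) {
    set.seed(seed)
    a <- rnorm(7, sd = 1); b <- rnorm(9, mean = 0.5, sd = 2)
    f <- welch_anova(c(a, b), rep(c("a", "b"), c(7, 9)))
    t2 <- welch_t(a, b, "welch")$t^2
    expect_lt(abs(f$F_welch - t2), 1e-10)
    expect_lt(abs(f$df2 - welch_t(a, b, "welch")$df), 1e-10)
  }
})

test_that("Welch ANOVA matches stats::oneway.test on seeded data", {
  for (seed in 1:50) {
    set.seed(seed)
    v <- rnorm(21, sd = rep(c(1, 2, 0.5), each = 7))
    g <- rep(c("a", "b", "c"), each = 7)
    ours <- welch_anova(v, g)
    ref <- stats::oneway.test(v ~ factor(g), var.equal = FALSE)
    expect_lt(abs(ours$F_welch - unname(ref$statistic)), 1e-10)
    expect_lt(abs(ours$df2 - unname(ref$parameter[2])), 1e-8)
    expect_lt(abs(ours$p_omnibus - ref$p.value), 1e-10)
  }
})

test_that("Welch ANOVA is invariant to affine transforms", {
  set.seed(77)
  v <- rnorm(21); g <- rep(c("a", "b", "c"), each = 7)
  f0 <- welch_anova(v, g)$F_welch
  expect_equal(welch_anova(-2.5 * v + 7, g)$F_welch, f0,
               tolerance = 1e-10)
})

test_that("Welch ANOVA validates its preconditions", {
  expect_error(welch_anova(1:5, rep("a", 5)), "2 groups")
  expect_error(welch_anova(c(1, 2, 3, 4, 5), c("a", "a", "a", "a", "b")),
               "n < 2")
  expect_error(welch_anova(c(1, 1, 2, 3), c("a", "a", "b", "b")), "zero")
})

test_that("Dunnett T3 t statistics match a per-pair Welch oracle", {
  set.seed(31)
  v <- rnorm(21, mean = rep(c(0, 1, 3), each = 7),
             sd = rep(c(1, 2, 1), each = 7))
  g <- rep(c("a", "b", "c"), each = 7)
  tab <- dunnett_t3(v, g)
  expect_equal(nrow(tab), 3L)          # all unordered pairs
  for (j in 1:3) {
    x <- v[g == tab$group_i[j]]; y <- v[g == tab$group_j[j]]
    ref <- stats::t.test(x, y, var.equal = FALSE)
    expect_lt(abs(tab$t_statistic[j] - unname(ref$statistic)), 1e-10)
    expect_lt(abs(tab$df_welch[j] - unname(ref$parameter)), 1e-8)
    expect_lt(abs(tab$p_unadjusted[j] - ref$p.value), 1e-10)
  }
  expect_true(all(tab$p_adjusted >= tab$p_unadjusted))
})

test_that("Dunnett T3 on identical groups gives adjusted p of 1", {
  v <- rep(c(1.2, 3.4, 2.1, 0.7, 5, 2, 1), 3)
  g <- rep(c("a", "b", "c"), each = 7)
  tab <- dunnett_t3(v, g)
  expect_true(all(abs(tab$t_statistic) < 1e-12))
  expect_true(all(tab$p_adjusted == 1))
})

test_that("two-sample t variants agree with stats::t.test", {
  set.seed(32)
  a <- rnorm(8); b <- rnorm(10, 0.8, 1.7)
  s <- welch_t(a, b, "student")
  w <- welch_t(a, b, "welch")
  rs <- stats::t.test(a, b, var.equal = TRUE)
  rw <- stats::t.test(a, b, var.equal = FALSE)
  expect_lt(abs(s$t - unname(rs$statistic)), 1e-10)
  expect_lt(abs(s$p - rs$p.value), 1e-10)
  expect_lt(abs(w$t - unname(rw$statistic)), 1e-10)
  expect_lt(abs(w$df - unname(rw$parameter)), 1e-8)
  # identical samples: t = 0, p = 1
  z <- welch_t(c(1, 2, 3), c(1, 2, 3), "welch")
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  # equal n, equal variance: the variants coincide
  set.seed(33); x <- rnorm(6); y <- x[sample(6)] + 1
  expect_equal(welch_t(x, y, "student")$t, welch_t(x, y, "welch")$t,
               tolerance = 1e-12)
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero combined variance")
})

test_that("pearson_cor matches cor.test and handles exact cases", {
  set.seed(34)
  x <- rnorm(15); y <- 0.6 * x + rnorm(15)
  ours <- pearson_cor(x, y)
  ref <- stats::cor.test(x, y)
  expect_lt(abs(ours$r - unname(ref$estimate)), 1e-12)
  expect_lt(abs(ours$p - ref$p.value), 1e-12)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_equal(pearson_cor(x, -x)$p, 0)
  expect_error(pearson_cor(x, rep(1, 15)), "constant")
  expect_error(pearson_cor(x[1:2], x[1:2]), "n >= 3")
})

test_that("ROUT flags gross outliers and spares tight clusters", {
  clean <- c(9.8, 10.1, 10.0, 9.9, 10.2)
  expect_false(any(rout_outliers(clean, Q = 0.01)))
  withcont <- c(clean, 100)
  mask <- rout_outliers(withcont, Q = 0.01)
  expect_true(mask[6])
  expect_false(any(mask[1:5]))
  expect_error(rout_outliers(c(1, 2, 3), 0.01), "n >= 4")
  expect_error(rout_outliers(clean, 0.5), "Q")
})

test_that("null p values are uniform (KS sanity check)", {
  set.seed(35)
  nrep <- 2000
  p_w <- numeric(nrep)
  g <- rep(c("a", "b", "c"), each = 7)
  for (i in seq_len(nrep)) {
    p_w[i] <- welch_anova(rnorm(21), g)$p_omnibus
  }
  expect_gt(stats::ks.test(p_w, "punif")$p.value, 0.001)
})

test_that("significance stars follow the figure-legend thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.004, 0.0004)),
               c("ns", "*", "**", "***"))
})
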