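test_that("encode_groups builds centered indicator columns", {
  y <- encode_groups(c("A", "A", "A", "B", "B"))
  expect_equal(unname(y[, "A"]), c(1, 1, 1, 0, 0) - 3 / 5)
  expect_equal(unname(y[, "B"]), c(0, 0, 0, 1, 1) - 2 / 5)
  expect_equal(attr(y, "levels"), c("A", "B"))
  # balanced 3-level case: every column sums to zero
  y3 <- encode_groups(rep(c("x", "y", "z"), each = 3))
  expect_lt(max(abs(colSums(y3))), 1e-14)
})

test_that("encode_groups rejects degenerate designs", {
  expect_error(encode_groups(rep("A", 5)), "2 group levels")
  expect_error(encode_groups(c("A", "A", "B", "B", "C")), "C")
})

test_that("NIPALS puts the dominant weight on the informative column", {
  set.seed(31)
  n <- 50
  y <- rnorm(n)
  noise <- matrix(rnorm(n * 4), n, 4)
  noise <- noise - outer(y, colSums(noise * y) / sum(y^2))  # orthogonal to y
  X <- scale(cbind(signal = y, noise))
  Y <- matrix(y - mean(y), ncol = 1)
  fit <- fit_pls(X, Y, n_components = 2)
  expect_gt(abs(fit$W["signal", 1]), 0.95)
})

test_that("1-component weights match the SVD of X'Y", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- scale(matrix(rnorm(40), 8, 5))
    Y <- encode_groups(rep(c("a", "b"), each = 4))
    fit <- fit_pls(X, Y, n_components = 1)
    expect_gt(cosine(fit$W[, 1], oracle_svd_w1(X, Y)), 1 - 1e-8)
  }
})

test_that("a constant response is rejected", {
  X <- scale(matrix(rnorm(30), 10, 3))
  Y <- matrix(0, 10, 1)
  expect_error(fit_pls(X, Y), "constant")
})

test_that("weight columns are unit norm and scores are orthogonal", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    X <- scale(matrix(rnorm(21 * 8), 21, 8))
    Y <- encode_groups(rep(c("a", "b", "c"), each = 7))
    fit <- fit_pls(X, Y, n_components = 3)
    expect_lt(max(abs(sqrt(colSums(fit$W^2)) - 1)), 1e-10)
    tt <- crossprod(fit$T)
    expect_lt(max(abs(tt[upper.tri(tt)])), 1e-8)
  }
})

test_that("projection reproduces training scores and is linear", {
  set.seed(12)
  X <- scale(matrix(rnorm(60), 12, 5))
  colnames(X) <- paste0("c", 1:5)
  Y <- encode_groups(rep(c("a", "b", "c"), each = 4))
  fit <- fit_pls(X, Y, n_components = 2)
  expect_lt(max(abs(project(fit, X) - fit$T)), 1e-10)
  # all-zero row maps to all-zero scores; doubling a row doubles scores
  z <- matrix(0, 1, 5, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(project(fit, z)), matrix(0, 1, 2))
  r <- X[3, , drop = FALSE]
  expect_equal(project(fit, 2 * r), 2 * project(fit, r), tolerance = 1e-12)
})

test_that("projection validates the analyte set", {
  set.seed(13)
  X <- scale(matrix(rnorm(40), 8, 5))
  colnames(X) <- paste0("c", 1:5)
  fit <- fit_pls(X, encode_groups(rep(c("a", "b"), 4)), n_components = 2)
  bad <- X[, 1:4]
  expect_error(project(fit, bad), "c5")
})

test_that("variance_explained matches a brute-force residual oracle", {
  set.seed(14)
  X <- scale(matrix(rnorm(72), 12, 6))
  Y <- encode_groups(rep(c("a", "b", "c"), 4))
  fit <- fit_pls(X, Y, n_components = 3)
  ve <- variance_explained(fit, X, Y)
  expect_true(all(ve$x_fraction >= 0 & ve$x_fraction <= 1))
  expect_true(all(diff(ve$x_cumulative) >= -1e-12))
  expect_true(all(diff(ve$y_cumulative) >= -1e-12))
  # oracle: explained fraction = 1 - ||X - T_a P_a'||^2 / ||X||^2
  for (a in 1:3) {
    Xhat <- fit$T[, 1:a, drop = FALSE] %*% t(fit$P[, 1:a, drop = FALSE])
    expect_equal(ve$x_cumulative[a], 1 - sum((X - Xhat)^2) / sum(X^2),
                 tolerance = 1e-10)
    Yhat <- fit$T[, 1:a, drop = FALSE] %*% t(fit$Q[, 1:a, drop = FALSE])
    expect_equal(ve$y_cumulative[a], 1 - sum((Y - Yhat)^2) / sum(Y^2),
                 tolerance = 1e-10)
  }
})

test_that("rank-2 X is fully explained by 2 components", {
  set.seed(15)
  A <- matrix(rnorm(20), 10, 2)
  B <- matrix(rnorm(8), 2, 4)
  X <- A %*% B
  X <- sweep(X, 2, colMeans(X))      # centered, rank 2
  Y <- encode_groups(rep(c("a", "b"), 5))
  fit <- suppressWarnings(fit_pls(X, Y, n_components = 2))
  ve <- variance_explained(fit, X, Y)
  expect_equal(ve$x_cumulative[2], 1, tolerance = 1e-8)
})

test_that("sign indeterminacy: flipping a weight/score pair is harmless", {
  set.seed(16)
  X <- scale(matrix(rnorm(60), 12, 5))
  Y <- encode_groups(rep(c("a", "b", "c"), 4))
  fit <- fit_pls(X, Y, n_components = 2)
  recon <- fit$T %*% t(fit$P)
  fit2 <- fit
  fit2$W[, 1] <- -fit2$W[, 1]; fit2$T[, 1] <- -fit2$T[, 1]
  fit2$P[, 1] <- -fit2$P[, 1]; fit2$Q[, 1] <- -fit2$Q[, 1]
  expect_equal(fit2$T %*% t(fit2$P), recon, tolerance = 1e-12)
})

test_that("permuting sample order permutes scores identically", {
  set.seed(17)
  X <- scale(matrix(rnorm(60), 12, 5))
  gr <- rep(c("a", "b", "c"), 4)
  fit <- fit_pls(X, encode_groups(gr), n_components = 2)
  perm <- sample(12)
  Xp <- scale(X[perm, ])
  fitp <- fit_pls(Xp, encode_groups(gr[perm]), n_components = 2)
  # align signs before comparing (indeterminacy)
  for (a in 1:2) {
    s <- sign(sum(fitp$T[, a] * fit$T[perm, a]))
    expect_equal(s * fitp$T[, a], fit$T[perm, a], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("a model bundle round-trips through write_pls_model", {
  set.seed(18)
  X <- scale(matrix(rnorm(60), 12, 5))
  colnames(X) <- paste0("c", 1:5)
  fit <- fit_pls(X, encode_groups(rep(c("a", "b", "c"), 4)),
                 n_components = 2,
                 x_center = attr(X, "scaled:center"),
                 x_scale = attr(X, "scaled:scale"))
  dir <- file.path(tempfile("plsbundle"))
  write_pls_model(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("model.json", "W.csv",
                                               "P.csv", "Q.csv", "T.csv")))))
  back <- read_pls_model(dir)
  expect_equal(back$W, fit$W, tolerance = 1e-12)
  expect_equal(back$n_components, fit$n_components)
  expect_equal(back$x_columns, fit$x_columns)
  # projection still works from the deserialized bundle
  expect_equal(project(back, X), fit$T, tolerance = 1e-10)
})
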