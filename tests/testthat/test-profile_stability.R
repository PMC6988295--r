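# Builds a minimal pls_model-shaped object with an orthonormal weight pair
# and prescribed scores, for rotation tests that need controlled geometry.
fake_model <- function(t1, t2, p = 6) {
  W <- diag(p)[, 1:2]
  structure(list(W = W, P = W, Q = matrix(1, 1, 2),
                 T = cbind(LV1 = t1, LV2 = t2), n_components = 2L,
                 x_columns = paste0("a", 1:p),
                 y_encoding = list(type = "group_indicator"),
                 x_center = NULL, x_scale = NULL),
            class = "pls_model")
}

test_that("theta = 0 is selected when LV1 already maximizes the contrast", {
  gr <- rep(c("A", "B", "AB"), each = 4)
  t1 <- c(rep(-1, 8), rep(3, 4)) + 0.01 * (1:12)
  t2 <- rep(c(1, -1), 6)           # contrast of t2 across AB vs rest is 0
  rot <- rotate_lv_plane(fake_model(t1, t2), "contrast_separation",
                         groups = gr, positive_group = "AB",
                         grid_points = 360)
  expect_equal(rot$theta, 0)
  expect_equal(rot$flip[1], 1)
  expect_equal(rot$T_rot[, 1], t1, ignore_attr = TRUE)
})

test_that("grid optimizer matches a 10x finer brute-force scan", {
  # brute force coded as a plain loop over angles using the scalar
  # textbook Welch F oracle
  set.seed(21)
  gr <- rep(c("A", "B", "AB"), each = 7)
  for (seed in 1:5) {
    set.seed(seed)
    t1 <- rnorm(21) + (gr == "AB") * 2
    t2 <- rnorm(21) + (gr == "B")
    m <- fake_model(t1, t2)
    coarse <- 181L
    rot <- rotate_lv_plane(m, "group_F", groups = gr, grid_points = coarse)
    fine_theta <- (seq_len(coarse * 10L) - 1L) * pi / (coarse * 10L)
    fine_best <- -Inf
    for (th in fine_theta) {
      s <- cos(th) * t1 + sin(th) * t2
      f <- oracle_welch_f(s, gr)$F
      if (f > fine_best) fine_best <- f
    }
    step <- max(abs(diff(rot$grid$objective)))
    expect_lte(fine_best - rot$objective_value, step)
  }
})

test_that("rotated pairs stay orthogonal at every grid angle", {
  set.seed(22)
  Z <- zscore(toy_panel(seed = 22, n_per = 7, p = 8, effect = 1)$values)
  Y <- encode_groups(rep(c("A", "B", "AB"), each = 7))
  fit <- fit_pls(Z, Y, 2)
  rot <- rotate_lv_plane(fit, "contrast_separation",
                         groups = rep(c("A", "B", "AB"), each = 7),
                         positive_group = "AB", grid_points = 721)
  w1 <- rot$W_rot[, 1]; w2 <- rot$W_rot[, 2]
  th <- rot$grid$theta
  # rotate the (orthonormal) selected pair through the whole grid
  dots <- vapply(th, function(a) {
    v1 <- cos(a) * w1 + sin(a) * w2
    v2 <- -sin(a) * w1 + cos(a) * w2
    abs(sum(v1 * v2))
  }, numeric(1))
  expect_lt(max(dots), 1e-15)
  expect_lt(check_orthogonality(rot), 1e-15)
})

test_that("check_orthogonality hard-errors on a skewed pair", {
  skewed <- structure(list(W_rot = cbind(c(1, 0, 0), c(0.1, 1, 0))),
                      class = "rotation_result")
  expect_error(check_orthogonality(skewed), "not orthogonal")
})

test_that("rotate_lv_plane rejects non-orthogonal input weights", {
  m <- fake_model(rnorm(12), rnorm(12))
  m$W[, 2] <- m$W[, 1] * 0.5 + m$W[, 2]
  expect_error(rotate_lv_plane(m, "group_F",
                               groups = rep(c("a", "b"), 6)),
               "not orthogonal")
})

test_that("rotation preserves the model subspace reconstruction", {
  set.seed(23)
  Z <- zscore(toy_panel(seed = 23, n_per = 7, p = 8, effect = 1)$values)
  gr <- rep(c("A", "B", "AB"), each = 7)
  fit <- fit_pls(Z, encode_groups(gr), 2)
  rot <- rotate_lv_plane(fit, "contrast_separation", groups = gr,
                         positive_group = "AB")
  expect_lt(norm(rot$T_rot %*% t(rot$W_rot) -
                   fit$T[, 1:2] %*% t(fit$W[, 1:2]), "F"), 1e-10)
})

test_that("sign_correct aligns vectors with the reference", {
  ref <- c(0.5, -0.5, 0.7)
  expect_equal(sign_correct(-ref, ref), ref)
  expect_equal(sign_correct(ref, ref), ref)
  set.seed(24)
  for (i in 1:20) {
    v <- rnorm(3)
    out <- sign_correct(v, ref)
    expect_gte(sum(out * ref), 0)
    # antisymmetry in the reference
    if (sum(v * ref) != 0) {
      expect_equal(sign_correct(v, -ref), -sign_correct(v, ref))
    }
  }
  expect_warning(out <- sign_correct(c(1, 0, 0), c(0, 1, 0)), "zero")
  expect_equal(out, c(1, 0, 0))
})

test_that("fraction = 1 degenerates to zero SD and the full-model profile", {
  panel <- toy_panel(seed = 25, effect = 1.5)
  spec <- lv_analysis("plsda", positive_group = "AB")
  prof <- subsample_profiles(panel, spec, fraction = 1, iterations = 5,
                             seed = 1)
  expect_true(all(prof$lv1$sd_signal == 0))
  expect_true(all(prof$lv2$sd_signal == 0))
  expect_equal(prof$lv1$mean_signal, unname(prof$rotation$W_rot[, 1]))
})

test_that("subsampling is reproducible by seed and varies across seeds", {
  panel <- toy_panel(seed = 26, effect = 1.5)
  spec <- lv_analysis("plsda", positive_group = "AB")
  a <- subsample_profiles(panel, spec, iterations = 20, seed = 7)
  b <- subsample_profiles(panel, spec, iterations = 20, seed = 7)
  c <- subsample_profiles(panel, spec, iterations = 20, seed = 8)
  expect_identical(a$lv1$mean_signal, b$lv1$mean_signal)
  expect_false(identical(a$lv1$mean_signal, c$lv1$mean_signal))
})

test_that("subsampling SDs shrink as the fraction grows", {
  panel <- toy_panel(seed = 27, n_per = 10, effect = 1.5)
  spec <- lv_analysis("plsda", positive_group = "AB")
  tot <- c(lo = 0, hi = 0)
  for (seed in 1:3) {
    lo <- subsample_profiles(panel, spec, fraction = 0.6, iterations = 60,
                             seed = seed)
    hi <- subsample_profiles(panel, spec, fraction = 0.9, iterations = 60,
                             seed = seed)
    tot["lo"] <- tot["lo"] + mean(lo$lv1$sd_signal)
    tot["hi"] <- tot["hi"] + mean(hi$lv1$sd_signal)
  }
  expect_lt(tot[["hi"]], tot[["lo"]])
})

test_that("strong effects recover the injected direction", {
  # scaled-down form of the recovery experiment (full scale in acceptance)
  hits <- 0
  for (seed in 1:5) {
    truth <- synthetic_truth(
      interaction_effects = c(rep(1.5, 5), rep(0, 17)), seed = seed)
    gen <- generate_panel(truth)
    spec <- lv_analysis("plsda", positive_group = "APP_PS1-DIAB")
    prof <- subsample_profiles(gen$panel, spec, iterations = 100,
                               seed = seed)
    if (all(prof$lv1$mean_signal[1:5] > 0)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("subsample_profiles validates its inputs", {
  panel <- toy_panel(seed = 28)
  spec <- lv_analysis("plsda", positive_group = "AB")
  expect_error(subsample_profiles(panel, spec, fraction = 0), "fraction")
  expect_error(subsample_profiles(panel, spec, fraction = 1.2), "fraction")
  expect_error(subsample_profiles(panel, spec, iterations = 0),
               "iterations")
})
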