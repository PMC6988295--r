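# Independent oracles and fixture builders. These deliberately use
# different code paths (scalar loops, stats:: reference tests, SVD) than
# the package implementation they check.

# Scalar textbook Welch F (Welch 1951), coded as a plain loop.
oracle_welch_f <- function(values, groups) {
  gr <- factor(groups)
  k <- nlevels(gr)
  w <- m <- n <- numeric(k)
  for (g in seq_len(k)) {
    x <- values[gr == levels(gr)[g]]
    n[g] <- length(x)
    m[g] <- sum(x) / n[g]
    w[g] <- n[g] / (sum((x - m[g])^2) / (n[g] - 1))
  }
  mt <- sum(w * m) / sum(w)
  num <- sum(w * (m - mt)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  list(F = num / den, df1 = k - 1, df2 = (k^2 - 1) / (3 * lam))
}

# Dominant left singular vector of X'Y: the 1-component PLS weight.
oracle_svd_w1 <- function(X, Y) {
  svd(crossprod(as.matrix(X), as.matrix(Y)))$u[, 1L]
}

cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# A small complete panel with known structure for generic pipeline tests.
toy_panel <- function(seed = 1, n_per = 7, p = 6,
                      groups = c("A", "B", "AB"), effect = 0) {
  set.seed(seed)
  n <- n_per * length(groups)
  vals <- matrix(exp(rnorm(n * p, mean = 2, sd = 0.5)), n, p,
                 dimnames = list(sprintf("s%02d", 1:n),
                                 paste0("cyt", 1:p)))
  gr <- rep(groups, each = n_per)
  if (effect != 0) {
    vals[gr == groups[length(groups)], 1:2] <-
      vals[gr == groups[length(groups)], 1:2] * exp(effect)
  }
  cytokine_panel(vals, group = gr, units = "pg_per_mg")
}

# Write a tiny panel + metadata CSV pair; returns the two paths.
write_toy_csvs <- function(dir = NULL,
                           ids = c("m1", "m2", "m3"),
                           meta_ids = ids) {
  if (is.null(dir)) {
    dir <- tempfile("toycsv")
    dir.create(dir)
  }
  panel_path <- file.path(dir, "panel.csv")
  meta_path <- file.path(dir, "meta.csv")
  writeLines(c("sample_id,IL-6,TNF-a",
               paste0(ids[1], ",1.5,2.0"),
               paste0(ids[2], ",2.5,n.d."),
               paste0(ids[3], ",3.5,4.0")), panel_path)
  writeLines(c("sample_id,group,sex,glucose",
               paste0(meta_ids[1], ",WT,M,110"),
               paste0(meta_ids[2], ",WT,F,132"),
               paste0(meta_ids[3], ",APP,M,168")), meta_path)
  c(panel = panel_path, meta = meta_path)
}
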