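#' Welch's heteroscedastic one-way ANOVA
#'
#' Variance-weighted one-way ANOVA that does not assume equal group
#' variances: weights `w_g = n_g / s_g^2`, the Welch F* statistic, and a
#' Satterthwaite-type fractional denominator df.
#'
#' @param values numeric vector of per-sample scalars (e.g. composite LV
#'   scores).
#' @param groups per-sample group labels (>= 2 levels, each n >= 2, each
#'   with positive variance).
#' @return list of class `welch_anova`: `groups`, `n`, `means`,
#'   `variances`, `F_welch`, `df1`, `df2`, `p_omnibus`.
#' @export
welch_anova <- function(values, groups) {
  gr <- factor(groups)
  if (length(values) != length(gr)) stop("length mismatch", call. = FALSE)
  k <- nlevels(gr)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  ng <- tabulate(gr)
  if (any(ng < 2L)) {
    stop("group(s) with n < 2: ",
         paste(levels(gr)[ng < 2L], collapse = ", "), call. = FALSE)
  }
  m <- tapply(values, gr, mean)
  v <- tapply(values, gr, stats::var)
  if (any(v == 0)) {
    stop("zero within-group variance in group(s): ",
         paste(levels(gr)[v == 0], collapse = ", "), call. = FALSE)
  }
  w <- ng / v
  W <- sum(w)
  mtilde <- sum(w * m) / W
  A <- sum(w * (m - mtilde)^2) / (k - 1)
  lam <- sum((1 - w / W)^2 / (ng - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  Fw <- A / B
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lam)
  structure(list(groups = levels(gr), n = as.integer(ng),
                 means = as.numeric(m), variances = as.numeric(v),
                 F_welch = Fw, df1 = df1, df2 = df2,
                 p_omnibus = stats::pf(Fw, df1, df2, lower.tail = FALSE)),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch ANOVA: F(%d, %.2f) = %.4f, p = %.4g %s\n",
              x$df1, x$df2, x$F_welch, x$p_omnibus, p_stars(x$p_omnibus)))
  invisible(x)
}

#' Dunnett T3 pairwise comparisons for unequal variances
#'
#' All-pairs post hoc comparisons with per-pair Welch t statistics and
#' Welch-Satterthwaite df. The exact reference distribution of Dunnett's T3
#' is the studentized maximum modulus; here the family-wise adjustment uses
#' the Sidak bound `1 - (1 - p)^m` over the `m = k(k-1)/2` comparisons,
#' which equals the maximum-modulus probability under independence and is
#' conservative under the positive dependence induced by shared group
#' means.
#'
#' @param values,groups as in [welch_anova()].
#' @param alpha significance level recorded in the table.
#' @return data.frame with one row per unordered pair: `group_i`,
#'   `group_j`, `mean_diff`, `t_statistic`, `df_welch`, `p_unadjusted`,
#'   `p_adjusted`, `significant`, `stars`.
#' @export
dunnett_t3 <- function(values, groups, alpha = 0.05) {
  gr <- factor(groups)
  om <- welch_anova(values, gr)   # validates inputs
  k <- length(om$groups)
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    se2a <- om$variances[i1] / om$n[i1]
    se2b <- om$variances[i2] / om$n[i2]
    tstat <- (om$means[i1] - om$means[i2]) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (om$n[i1] - 1) + se2b^2 / (om$n[i2] - 1))
    p_un <- 2 * stats::pt(-abs(tstat), df)
    out[[j]] <- data.frame(group_i = om$groups[i1], group_j = om$groups[i2],
                           mean_diff = om$means[i1] - om$means[i2],
                           t_statistic = tstat, df_welch = df,
                           p_unadjusted = p_un,
                           p_adjusted = 1 - (1 - p_un)^m)
  }
  tab <- do.call(rbind, out)
  tab$significant <- tab$p_adjusted < alpha
  tab$stars <- p_stars(tab$p_adjusted)
  tab
}

#' Welch ANOVA plus Dunnett T3 on one set of scores
#'
#' Convenience wrapper bundling the omnibus test and the pairwise table.
#'
#' @inheritParams dunnett_t3
#' @return list of class `group_comparison`: `omnibus` ([welch_anova()]
#'   result) and `pairwise` ([dunnett_t3()] table).
#' @export
group_comparison <- function(values, groups, alpha = 0.05) {
  structure(list(omnibus = welch_anova(values, groups),
                 pairwise = dunnett_t3(values, groups, alpha = alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$omnibus)
  df <- x$pairwise
  for (j in seq_len(nrow(df))) {
    cat(sprintf("  %s vs %s: t = %.3f, df = %.2f, p_adj = %.4g %s\n",
                df$group_i[j], df$group_j[j], df$t_statistic[j],
                df$df_welch[j], df$p_adjusted[j], df$stars[j]))
  }
  invisible(x)
}

#' Two-sample t test (Student or Welch)
#'
#' @param values_a,values_b the two samples (each n >= 2).
#' @param variant `"student"` pools variances; `"welch"` does not.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(values_a, values_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each sample needs n >= 2", call. = FALSE)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va + vb == 0) stop("zero combined variance", call. = FALSE)
  d <- mean(values_a) - mean(values_b)
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- d / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Pearson correlation with two-sided p value
#'
#' The p value comes from the t transform `r * sqrt((n-2)/(1-r^2))` on
#' n - 2 df. Used for composite-score vs. phenotype association.
#'
#' @param scores,phenotype numeric vectors (n >= 3, both nonconstant).
#' @return list of class `correlation_result`: `r`, `n`, `p`.
#' @export
pearson_cor <- function(scores, phenotype) {
  if (length(scores) != length(phenotype)) stop("length mismatch",
                                                call. = FALSE)
  n <- length(scores)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(phenotype) == 0) {
    stop("constant input", call. = FALSE)
  }
  r <- stats::cor(scores, phenotype)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(r = r, n = n, p = p), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), p = %.4g %s\n",
              x$r, x$n, x$p, p_stars(x$p)))
  invisible(x)
}

#' Significance stars at the conventional thresholds
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, else `ns`.
#'
#' @param p vector of p values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
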