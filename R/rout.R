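#' ROUT-style robust outlier detection for a univariate sample
#'
#' One-group location version of the "robust regression and outlier
#' removal" procedure popularized by GraphPad Prism: fit a robust location
#' (the median), form a robust scale estimate (RSDR: the 68.27th percentile
#' of absolute residuals, inflated by n/(n-1)), convert residuals to
#' t-like statistics, and sweep from the most extreme point inward with a
#' Benjamini-Hochberg step-down criterion at level Q. The i-th most
#' extreme point is flagged when its two-sided t probability (df = n - 1)
#' falls below `Q * i / n`; the sweep stops at the first non-significant
#' point.
#'
#' @param values numeric sample, n >= 4.
#' @param Q desired false discovery rate, in (0, 0.1].
#' @return logical mask, TRUE for detected outliers, with attributes
#'   `rsdr` and `t` (the per-point statistics).
#' @export
rout_outliers <- function(values, Q = 0.01) {
  n <- length(values)
  if (n < 4L) stop("ROUT needs n >= 4", call. = FALSE)
  if (!(Q > 0 && Q <= 0.1)) stop("Q must be in (0, 0.1]", call. = FALSE)
  resid <- values - stats::median(values)
  rsdr <- stats::quantile(abs(resid), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr == 0) {
    # degenerate: majority of points identical; any nonzero residual is
    # infinitely many robust SDs out
    mask <- resid != 0
    attr(mask, "rsdr") <- 0
    attr(mask, "t") <- ifelse(resid == 0, 0, Inf)
    return(mask)
  }
  tstat <- abs(resid) / rsdr
  ord <- order(-tstat)
  pvals <- 2 * stats::pt(-tstat, df = n - 1)
  mask <- logical(n)
  for (i in seq_len(n)) {
    thr <- Q * i / n
    if (pvals[ord[i]] < thr) {
      mask[ord[i]] <- TRUE
    } else {
      break
    }
  }
  attr(mask, "rsdr") <- rsdr
  attr(mask, "t") <- tstat
  mask
}
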