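#' Encode group labels as a centered indicator response
#'
#' Builds the PLSDA response: one column per group level, 1 for membership
#' and 0 otherwise, then column-centered so the response has mean zero.
#' The level order is recorded for downstream interpretation.
#'
#' @param labels per-sample categorical labels (factor or character).
#' @return centered indicator matrix with attribute `levels`.
#' @export
encode_groups <- function(labels) {
  g <- factor(labels)
  counts <- tabulate(g, nbins = nlevels(g))
  if (nlevels(g) < 2L) stop("need at least 2 group levels", call. = FALSE)
  if (any(counts < 2L)) {
    stop("group level(s) with fewer than 2 samples: ",
         paste(levels(g)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  y <- matrix(0, length(g), nlevels(g),
              dimnames = list(names(labels), levels(g)))
  y[cbind(seq_along(g), as.integer(g))] <- 1
  y <- sweep(y, 2L, colMeans(y), "-")
  attr(y, "levels") <- levels(g)
  y
}

#' Fit a partial least squares model by NIPALS
#'
#' Classical NIPALS PLS2 with X-deflation only (Y is not deflated). Each
#' component's weight vector is iterated to a fixed point; the inner loop is
#' initialized deterministically from the response column of largest
#' variance, so the fit has no random element. Weight columns have unit
#' norm; score columns are mutually orthogonal.
#'
#' @param X column-standardized predictor matrix (samples x analytes).
#' @param Y centered response matrix (continuous, or the output of
#'   [encode_groups()]).
#' @param n_components number of latent variables to extract.
#' @param tol convergence tolerance on the weight-vector change.
#' @param max_iter maximum NIPALS iterations per component. The inner loop
#'   is a power iteration whose rate is the squared singular-value ratio of
#'   `t(X) %*% Y`; near-degenerate instances legitimately need thousands of
#'   (cheap) iterations at `tol = 1e-12`, so the cap is generous.
#' @param x_center,x_scale standardization constants used to produce `X`
#'   (stored for later projection of new data); taken from `attributes(X)`
#'   when present.
#' @return object of class `pls_model` with elements `W` (weights), `P`
#'   (X-loadings), `Q` (Y-loadings), `T` (scores), `n_components`,
#'   `x_columns`, `y_encoding`, `x_center`, `x_scale`.
#' @export
fit_pls <- function(X, Y, n_components = 2L, tol = 1e-12, max_iter = 20000L,
                    x_center = attr(X, "center"), x_scale = attr(X, "scale")) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) stop("fit_pls requires complete data", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("X and Y row counts differ", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components > min(n - 1L, p)) {
    stop("n_components exceeds min(n_samples - 1, n_analytes)", call. = FALSE)
  }
  if (all(abs(Y) < .Machine$double.eps * 100)) {
    stop("response is constant (all zero after centering)", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  TT <- matrix(0, n, n_components)
  Xd <- X
  ncomp_used <- n_components

  for (a in seq_len(n_components)) {
    if (sqrt(sum(Xd^2)) < 1e-12) {
      warning("X residual exhausted; stopping at ", a - 1L, " components",
              call. = FALSE)
      ncomp_used <- a - 1L
      break
    }
    yvar <- apply(Y, 2L, stats::var)
    u <- Y[, which.max(yvar)]
    w_old <- rep(0, p)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Y, tt) / sum(tt^2)
      if (ncol(Y) == 1L) {              # PLS1: weight is a fixed point at once
        converged <- TRUE
        break
      }
      u <- Y %*% q / sum(q^2)
      if (sqrt(sum((w - w_old)^2)) < tol) {
        converged <- TRUE
        break
      }
      w_old <- w
    }
    if (!converged) {
      stop("NIPALS failed to converge for component ", a, call. = FALSE)
    }
    tt <- drop(Xd %*% w)
    pp <- drop(crossprod(Xd, tt)) / sum(tt^2)
    qq <- drop(crossprod(Y, tt)) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pp)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq; TT[, a] <- tt
  }
  if (ncomp_used < 1L) stop("no components could be extracted", call. = FALSE)
  keep <- seq_len(ncomp_used)
  dimnames(W) <- list(colnames(X), paste0("LV", keep))
  dimnames(P) <- dimnames(W)
  dimnames(Q) <- list(colnames(Y), paste0("LV", keep))
  dimnames(TT) <- list(rownames(X), paste0("LV", keep))

  structure(
    list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
         Q = Q[, keep, drop = FALSE], T = TT[, keep, drop = FALSE],
         n_components = ncomp_used,
         x_columns = colnames(X),
         y_encoding = if (!is.null(attr(Y, "levels")))
           list(type = "group_indicator", levels = attr(Y, "levels"))
         else list(type = "continuous", names = colnames(Y)),
         x_center = x_center, x_scale = x_scale,
         ssx_total = sum(X^2), ssy_total = sum(Y^2)),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d analytes, %d samples (%s)\n",
              x$n_components, length(x$x_columns), nrow(x$T),
              x$y_encoding$type))
  invisible(x)
}

#' Project new samples onto a fitted PLS model
#'
#' Reproduces the NIPALS deflation structure: scores are computed
#' sequentially, deflating the new data by the stored X-loadings after each
#' component. Projecting the training matrix returns the stored scores.
#'
#' @param model a `pls_model`.
#' @param X_new matrix with columns matching `model$x_columns`, standardized
#'   with the model's `x_center`/`x_scale` (or already standardized).
#' @param standardize if TRUE, apply the model's stored center/scale first.
#' @return score matrix (rows = new samples, columns = components).
#' @export
project <- function(model, X_new, standardize = FALSE) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    missing <- setdiff(model$x_columns, colnames(X_new))
    extra <- setdiff(colnames(X_new), model$x_columns)
    if (length(missing) || length(extra)) {
      stop("analyte mismatch; missing: [",
           paste(missing, collapse = ", "), "] extra: [",
           paste(extra, collapse = ", "), "]", call. = FALSE)
    }
    X_new <- X_new[, model$x_columns, drop = FALSE]
  } else if (ncol(X_new) != length(model$x_columns)) {
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         length(model$x_columns), call. = FALSE)
  }
  if (standardize) {
    if (is.null(model$x_center)) stop("model carries no standardization",
                                      call. = FALSE)
    X_new <- sweep(sweep(X_new, 2L, model$x_center, "-"),
                   2L, model$x_scale, "/")
  }
  Td <- matrix(0, nrow(X_new), model$n_components,
               dimnames = list(rownames(X_new), colnames(model$T)))
  Xd <- X_new
  for (a in seq_len(model$n_components)) {
    tt <- Xd %*% model$W[, a, drop = FALSE]
    Xd <- Xd - tt %*% t(model$P[, a, drop = FALSE])
    Td[, a] <- tt
  }
  Td
}

#' Fraction of X and Y variance captured per component
#'
#' @param model a `pls_model`.
#' @param X,Y the matrices used at fit time (standardized/centered).
#' @return data.frame with per-component and cumulative fractions for X
#'   and Y.
#' @export
variance_explained <- function(model, X, Y) {
  stopifnot(inherits(model, "pls_model"))
  ssx <- sum(as.matrix(X)^2)
  ssy <- sum(as.matrix(Y)^2)
  t2 <- colSums(model$T^2)
  x_frac <- t2 * colSums(model$P^2) / ssx
  y_frac <- t2 * colSums(model$Q^2) / ssy
  data.frame(component = colnames(model$T),
             x_fraction = unname(x_frac),
             x_cumulative = cumsum(unname(x_frac)),
             y_fraction = unname(y_frac),
             y_cumulative = cumsum(unname(y_frac)),
             row.names = NULL)
}

#' Serialize a fitted PLS model to a JSON + CSV bundle
#'
#' Writes `model.json` (dimensions, response encoding, standardization
#' constants) plus `W.csv`, `P.csv`, `Q.csv`, `T.csv` into a directory, a
#' plain-text format downstream tools can consume without R.
#'
#' @param model a `pls_model`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pls_model <- function(model, dir) {
  stopifnot(inherits(model, "pls_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("W", "P", "Q", "T")) {
    utils::write.csv(as.data.frame(model[[nm]]),
                     file.path(dir, paste0(nm, ".csv")))
  }
  meta <- list(n_components = model$n_components,
               x_columns = model$x_columns,
               y_encoding = model$y_encoding,
               x_center = model$x_center, x_scale = model$x_scale,
               ssx_total = model$ssx_total, ssy_total = model$ssy_total)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a PLS model bundle written by [write_pls_model()]
#'
#' @param dir the bundle directory.
#' @return a `pls_model`.
#' @export
read_pls_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  mats <- lapply(c(W = "W", P = "P", Q = "Q", T = "T"), function(nm) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                          row.names = 1, check.names = FALSE)
    as.matrix(df)
  })
  structure(c(mats,
              list(n_components = meta$n_components,
                   x_columns = meta$x_columns,
                   y_encoding = meta$y_encoding,
                   x_center = meta$x_center, x_scale = meta$x_scale,
                   ssx_total = meta$ssx_total, ssy_total = meta$ssy_total)),
            class = "pls_model")
}
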