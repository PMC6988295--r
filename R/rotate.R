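#' Orthogonal rotation of the LV1-LV2 plane toward a separation objective
#'
#' PLS components are ordered by covariance with the response, not by how
#' cleanly their scores separate the contrast of scientific interest. This
#' step searches rotation angles theta over a uniform grid on [0, pi)
#' (rotation by theta + pi is a sign flip, which is handled separately as
#' orientation) and applies the 2x2 rotation maximizing the chosen
#' objective to both the weight pair and the score pair. Orientation is
#' fixed so that the designated group (or the positive phenotype
#' association) scores positive on the rotated LV1.
#'
#' Objectives:
#' \describe{
#'   \item{`contrast_separation`}{difference between the designated group's
#'     mean score and the pooled mean of the remaining samples (default for
#'     "combined pathology vs. each alone" designs).}
#'   \item{`group_F`}{omnibus Welch F of the rotated LV1 scores across all
#'     groups.}
#'   \item{`phenotype_correlation`}{absolute Pearson correlation of rotated
#'     LV1 scores with a continuous variable (PLSR mode).}
#' }
#'
#' The input weight pair must span an (almost) orthonormal plane, as NIPALS
#' weights do; a single Gram-Schmidt pass removes the residual floating
#' point drift so the rotated pair satisfies the strict orthogonality bound
#' checked by [check_orthogonality()].
#'
#' @param model a `pls_model` with at least 2 components.
#' @param objective one of `"contrast_separation"`, `"group_F"`,
#'   `"phenotype_correlation"`.
#' @param groups per-sample group labels (required for the two group
#'   objectives).
#' @param positive_group the group level oriented positive on rotated LV1
#'   (required for `contrast_separation`; used for orientation under
#'   `group_F`, defaulting to the group with the largest mean score).
#' @param phenotype per-sample continuous variable
#'   (`phenotype_correlation` only).
#' @param grid_points number of angles in the search grid (default 3601,
#'   i.e. 0.05-degree resolution).
#' @param components which two components span the rotated plane.
#' @return object of class `rotation_result`: `theta` (selected angle,
#'   radians in [0, pi)), `flip` (length-2 sign vector applied after
#'   rotation for orientation), `W_rot` (analyte x 2), `T_rot`
#'   (sample x 2), `objective_name`, `objective_value`, `grid` (angles and
#'   objective values, for diagnostics).
#' @export
rotate_lv_plane <- function(model,
                            objective = c("contrast_separation", "group_F",
                                          "phenotype_correlation"),
                            groups = NULL, positive_group = NULL,
                            phenotype = NULL, grid_points = 3601L,
                            components = c(1L, 2L)) {
  stopifnot(inherits(model, "pls_model"))
  objective <- match.arg(objective)
  if (model$n_components < max(components)) {
    stop("model has fewer than ", max(components), " components",
         call. = FALSE)
  }
  w1 <- model$W[, components[1L]]
  w2 <- model$W[, components[2L]]
  if (abs(sum(w1 * w2)) > 1e-8) {
    stop("input weight pair is not orthogonal (|w1.w2| > 1e-8); ",
         "rotation requires an orthonormal NIPALS weight pair", call. = FALSE)
  }
  # re-orthonormalize to remove floating-point drift (span is preserved)
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- w2 - sum(w1 * w2) * w1
  w2 <- w2 / sqrt(sum(w2^2))
  t1 <- model$T[, components[1L]]
  t2 <- model$T[, components[2L]]

  theta <- (seq_len(grid_points) - 1L) * (pi / grid_points)
  ct <- cos(theta); st <- sin(theta)

  obj <- switch(objective,
    contrast_separation = {
      gr <- .check_groups(groups, length(t1), positive_group, need_pos = TRUE)
      pos <- gr == positive_group
      a <- mean(t1[pos]) - mean(t1[!pos])
      b <- mean(t2[pos]) - mean(t2[!pos])
      abs(a * ct + b * st)
    },
    group_F = {
      gr <- .check_groups(groups, length(t1), positive_group,
                          need_pos = FALSE)
      .welch_f_grid(t1, t2, gr, ct, st)
    },
    phenotype_correlation = {
      if (is.null(phenotype) || length(phenotype) != length(t1)) {
        stop("phenotype of length n is required", call. = FALSE)
      }
      if (stats::sd(phenotype) == 0) stop("phenotype is constant",
                                          call. = FALSE)
      y <- phenotype - mean(phenotype)
      c1 <- sum(t1 * y); c2 <- sum(t2 * y)
      v1 <- sum(t1^2); v2 <- sum(t2^2); c12 <- sum(t1 * t2)
      num <- c1 * ct + c2 * st
      den <- sqrt((ct^2 * v1 + st^2 * v2 + 2 * ct * st * c12) * sum(y^2))
      abs(num / den)
    })

  best <- which.max(obj)
  th <- theta[best]
  cb <- ct[best]; sb <- st[best]
  # rotation matrix applied on the right of [w1 w2] / [t1 t2]
  R <- matrix(c(cb, sb, -sb, cb), 2L, 2L)
  W_rot <- cbind(w1, w2) %*% R
  T_rot <- cbind(t1, t2) %*% R

  # orientation of rotated LV1
  flip <- c(1, 1)
  s1 <- T_rot[, 1L]
  orient <- switch(objective,
    contrast_separation = ,
    group_F = {
      gr <- .check_groups(groups, length(t1), positive_group,
                          need_pos = FALSE)
      pg <- positive_group
      if (is.null(pg)) {
        means <- tapply(s1, gr, mean)
        pg <- names(means)[which.max(abs(means))]
      }
      mean(s1[gr == pg]) - mean(s1[gr != pg])
    },
    phenotype_correlation = stats::cov(s1, phenotype))
  if (orient < 0) flip[1L] <- -1
  W_rot <- sweep(W_rot, 2L, flip, "*")
  T_rot <- sweep(T_rot, 2L, flip, "*")
  colnames(W_rot) <- colnames(T_rot) <- c("LV1", "LV2")
  rownames(W_rot) <- model$x_columns
  rownames(T_rot) <- rownames(model$T)

  structure(
    list(theta = th, flip = flip, W_rot = W_rot, T_rot = T_rot,
         objective_name = objective, objective_value = obj[best],
         positive_group = if (objective != "phenotype_correlation")
           positive_group else NULL,
         grid = list(theta = theta, objective = obj)),
    class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("<rotation_result> theta = %.4f rad, objective %s = %.4g\n",
              x$theta, x$objective_name, x$objective_value))
  invisible(x)
}

.check_groups <- function(groups, n, positive_group, need_pos) {
  if (is.null(groups) || length(groups) != n) {
    stop("groups of length n are required for this objective", call. = FALSE)
  }
  gr <- factor(groups)
  if (nlevels(gr) < 2L) stop("objective undefined with a single group",
                             call. = FALSE)
  if (need_pos) {
    if (is.null(positive_group) || !(positive_group %in% levels(gr))) {
      stop("positive_group must name one of the group levels", call. = FALSE)
    }
  }
  gr
}

# Welch F of the rotated score cos(theta) t1 + sin(theta) t2, vectorized
# over the angle grid via per-group first and second moments.
.welch_f_grid <- function(t1, t2, gr, ct, st) {
  k <- nlevels(gr)
  ng <- tabulate(gr)
  m1 <- tapply(t1, gr, mean); m2 <- tapply(t2, gr, mean)
  v1 <- tapply(t1, gr, stats::var); v2 <- tapply(t2, gr, stats::var)
  c12 <- vapply(levels(gr),
                function(l) stats::cov(t1[gr == l], t2[gr == l]),
                numeric(1))
  G <- length(ct)
  Wsum <- num <- numeric(G)
  mg <- matrix(0, k, G)   # group means per angle
  vg <- matrix(0, k, G)   # group variances per angle
  for (g in seq_len(k)) {
    mg[g, ] <- m1[g] * ct + m2[g] * st
    vg[g, ] <- ct^2 * v1[g] + st^2 * v2[g] + 2 * ct * st * c12[g]
  }
  vg[vg < .Machine$double.eps] <- .Machine$double.eps
  wg <- sweep(1 / vg, 1L, ng, "*")               # n_g / s_g^2
  Wsum <- colSums(wg)
  mtilde <- colSums(wg * mg) / Wsum
  A <- colSums(wg * (mg - rep(mtilde, each = k))^2) / (k - 1)
  lam <- colSums(sweep((1 - sweep(wg, 2L, Wsum, "/"))^2, 1L, ng - 1, "/"))
  B <- 1 + (2 * (k - 2) / (k^2 - 1)) * lam
  A / B
}

#' Sign-correct a subsampled latent variable against a reference
#'
#' Removes the sign indeterminacy of PLS by multiplying the subsampled
#' weight vector by the sign of its scalar product with the corresponding
#' full-model vector, so that the aligned vector satisfies
#' `sum(out * reference) >= 0`. A scalar product of exactly zero keeps the
#' original sign with a warning.
#'
#' @param subsample_lv weight vector from a subsample refit.
#' @param reference_lv corresponding vector from the full model.
#' @return the aligned weight vector.
#' @export
sign_correct <- function(subsample_lv, reference_lv) {
  if (length(subsample_lv) != length(reference_lv)) {
    stop("vectors differ in length", call. = FALSE)
  }
  if (all(reference_lv == 0)) stop("reference vector is zero", call. = FALSE)
  s <- sum(subsample_lv * reference_lv)
  if (s == 0) {
    warning("scalar product with reference is exactly zero; keeping sign",
            call. = FALSE)
    return(subsample_lv)
  }
  subsample_lv * sign(s)
}

#' Check orthogonality of a rotated component pair
#'
#' Returns the magnitude of the scalar product between the two rotated
#' weight vectors and errors if it exceeds the configured bound (default
#' 1e-15, the strictest bound double precision supports for a rotated
#' orthonormal pair). The pipeline runs this check before any composite
#' scores are used for ANOVA.
#'
#' @param result a `rotation_result`.
#' @param bound maximum tolerated `|w1 . w2|`.
#' @return the scalar product magnitude, invisibly on success.
#' @export
check_orthogonality <- function(result, bound = 1e-15) {
  stopifnot(inherits(result, "rotation_result"))
  dp <- abs(sum(result$W_rot[, 1L] * result$W_rot[, 2L]))
  if (dp > bound) {
    stop(sprintf(
      "rotated components are not orthogonal: |w1.w2| = %.3e > %.0e ",
      dp, bound), "(non-orthonormal input weights?)", call. = FALSE)
  }
  invisible(dp)
}
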