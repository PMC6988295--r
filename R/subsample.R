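#' Specify a latent-variable analysis
#'
#' Collects everything needed to (re)fit the model on a sample subset:
#' discriminant vs. regression mode, the rotation objective and its
#' designated group or phenotype, and the component count. Used by
#' [subsample_profiles()] and the pipeline drivers.
#'
#' @param mode `"plsda"` (group-indicator response) or `"plsr"` (continuous
#'   response).
#' @param objective rotation objective (see [rotate_lv_plane()]); defaults
#'   to `"contrast_separation"` for PLSDA and `"phenotype_correlation"` for
#'   PLSR.
#' @param positive_group designated group for contrast/orientation.
#' @param phenotype name of the phenotype column (PLSR).
#' @param n_components latent variables to extract (>= 2).
#' @param grid_points rotation search grid size.
#' @param reoptimize_rotation if TRUE (default) the rotation angle is
#'   re-optimized in every subsample refit, treating rotation as part of
#'   model regeneration; if FALSE the full-model angle and orientation are
#'   reused.
#' @return an `lv_analysis` specification object.
#' @export
lv_analysis <- function(mode = c("plsda", "plsr"),
                        objective = NULL,
                        positive_group = NULL, phenotype = NULL,
                        n_components = 2L, grid_points = 3601L,
                        reoptimize_rotation = TRUE) {
  mode <- match.arg(mode)
  if (is.null(objective)) {
    objective <- if (mode == "plsda") "contrast_separation"
                 else "phenotype_correlation"
  }
  objective <- match.arg(objective, c("contrast_separation", "group_F",
                                      "phenotype_correlation"))
  if (mode == "plsr" && is.null(phenotype)) {
    stop("plsr mode requires a phenotype name", call. = FALSE)
  }
  if (objective == "contrast_separation" && is.null(positive_group)) {
    stop("contrast_separation requires positive_group", call. = FALSE)
  }
  structure(list(mode = mode, objective = objective,
                 positive_group = positive_group, phenotype = phenotype,
                 n_components = as.integer(n_components),
                 grid_points = as.integer(grid_points),
                 reoptimize_rotation = reoptimize_rotation),
            class = "lv_analysis")
}

# Fit + rotate on one sample subset. Returns the rotation_result and model.
.fit_rotated <- function(panel, spec, idx = NULL,
                         fixed = NULL) {
  vals <- panel$values
  gr <- panel$group
  if (!is.null(idx)) {
    vals <- vals[idx, , drop = FALSE]
    gr <- droplevels(gr[idx])
  }
  Z <- zscore(vals)
  if (spec$mode == "plsda") {
    Y <- encode_groups(gr)
    y_for_phen <- NULL
  } else {
    ph <- panel$phenotypes[[spec$phenotype]]
    if (is.null(ph)) stop("phenotype '", spec$phenotype,
                          "' not found in panel", call. = FALSE)
    if (!is.null(idx)) ph <- ph[idx]
    if (anyNA(ph)) stop("phenotype '", spec$phenotype, "' has missing values",
                        call. = FALSE)
    Y <- matrix(ph - mean(ph), ncol = 1L,
                dimnames = list(NULL, spec$phenotype))
    y_for_phen <- ph
  }
  model <- fit_pls(Z, Y, n_components = spec$n_components)
  if (!is.null(fixed)) {
    # reuse the full-model angle/orientation instead of re-optimizing
    R <- matrix(c(cos(fixed$theta), sin(fixed$theta),
                  -sin(fixed$theta), cos(fixed$theta)), 2L, 2L)
    W_rot <- model$W[, 1:2] %*% R
    T_rot <- model$T[, 1:2] %*% R
    W_rot <- sweep(W_rot, 2L, fixed$flip, "*")
    T_rot <- sweep(T_rot, 2L, fixed$flip, "*")
    rot <- structure(list(theta = fixed$theta, flip = fixed$flip,
                          W_rot = W_rot, T_rot = T_rot,
                          objective_name = spec$objective,
                          objective_value = NA_real_, grid = NULL),
                     class = "rotation_result")
  } else {
    rot <- rotate_lv_plane(model, objective = spec$objective,
                           groups = gr,
                           positive_group = spec$positive_group,
                           phenotype = y_for_phen,
                           grid_points = spec$grid_points)
  }
  list(model = model, rotation = rot, groups = gr, phenotype = y_for_phen)
}

#' Monte-Carlo subsampling stability of latent-variable profiles
#'
#' Estimates the variability of the per-analyte LV1/LV2 weights by
#' repeatedly refitting the whole pipeline on random subsamples: draw a
#' stratified subsample without replacement (default 80% of each group,
#' minimum 2 per group), re-z-score within the subsample, refit the PLS
#' model, re-rotate with the same objective, sign-correct each rotated LV
#' against the full-model rotated LV, and accumulate the weights. The mean
#' and standard deviation over iterations form the error bars of the
#' familiar LV bar-plot profile.
#'
#' Reproducibility: a master seed deterministically derives one substream
#' seed per iteration, so iteration i is reproducible in isolation.
#'
#' @param panel a [cytokine_panel] (complete values; filter/impute first).
#' @param spec an [lv_analysis] specification.
#' @param fraction subsample fraction per group (default 0.8).
#' @param iterations number of Monte-Carlo iterations (default 1000).
#' @param seed master integer seed.
#' @return list with `lv1` and `lv2` (each of class `lv_profile`: analytes,
#'   `mean_signal`, `sd_signal`, `n_iterations`, `subsample_fraction`,
#'   `seed`), the full-model `rotation`, `model`, and `n_retries`.
#' @export
subsample_profiles <- function(panel, spec, fraction = 0.8,
                               iterations = 1000L, seed = 1L) {
  stopifnot(inherits(panel, "cytokine_panel"), inherits(spec, "lv_analysis"))
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)

  full <- .fit_rotated(panel, spec)
  ref1 <- full$rotation$W_rot[, 1L]
  ref2 <- full$rotation$W_rot[, 2L]
  fixed <- if (spec$reoptimize_rotation) NULL else
    list(theta = full$rotation$theta, flip = full$rotation$flip)

  gr <- panel$group
  idx_by_group <- split(seq_along(gr), gr)
  take <- vapply(idx_by_group, function(ix) {
    m <- max(2L, as.integer(round(fraction * length(ix))))
    if (m > length(ix)) m <- length(ix)
    m
  }, integer(1))
  if (any(lengths(idx_by_group) < 2L)) {
    stop("every group needs at least 2 samples to subsample", call. = FALSE)
  }

  p <- ncol(panel$values)
  acc1 <- matrix(NA_real_, iterations, p)
  acc2 <- matrix(NA_real_, iterations, p)
  n_retries <- 0L

  for (i in seq_len(iterations)) {
    fails <- 0L
    repeat {
      # substream: deterministic per-iteration seed below 2^31
      sub_seed <- (as.double(seed) * 48271 + i * 1000003 + fails) %%
        2147483647
      set.seed(as.integer(sub_seed))
      idx <- unlist(lapply(seq_along(idx_by_group), function(g) {
        ix <- idx_by_group[[g]]
        if (take[g] == length(ix)) ix else sample(ix, take[g])
      }), use.names = FALSE)
      res <- tryCatch(.fit_rotated(panel, spec, idx = idx, fixed = fixed),
                      error = function(e) e)
      if (!inherits(res, "error")) break
      fails <- fails + 1L
      n_retries <- n_retries + 1L
      if (fails >= 100L) {
        stop("100 consecutive degenerate subsamples at iteration ", i,
             ": ", conditionMessage(res), call. = FALSE)
      }
    }
    acc1[i, ] <- sign_correct(res$rotation$W_rot[, 1L], ref1)
    acc2[i, ] <- sign_correct(res$rotation$W_rot[, 2L], ref2)
  }

  mk_profile <- function(acc) {
    sds <- apply(acc, 2L, stats::sd)
    # a constant column has sd exactly 0, whatever rounding mean() incurs
    constant <- apply(acc, 2L, function(col) all(col == col[1L]))
    sds[constant] <- 0
    structure(list(analytes = panel$analytes,
                   mean_signal = colMeans(acc),
                   sd_signal = sds,
                   n_iterations = iterations,
                   subsample_fraction = fraction,
                   seed = seed),
              class = "lv_profile")
  }
  list(lv1 = mk_profile(acc1), lv2 = mk_profile(acc2),
       rotation = full$rotation, model = full$model,
       groups = full$groups, n_retries = n_retries)
}

#' @export
print.lv_profile <- function(x, ...) {
  ord <- order(-abs(x$mean_signal))
  top <- utils::head(ord, 5L)
  cat(sprintf("<lv_profile> %d analytes, %d iterations at %.0f%%\n",
              length(x$analytes), x$n_iterations,
              100 * x$subsample_fraction))
  cat("top |signal|:",
      paste(sprintf("%s(%.2f)", x$analytes[top], x$mean_signal[top]),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.lv_profile <- function(x, ...) {
  data.frame(analyte = x$analytes, mean_signal = x$mean_signal,
             sd_signal = x$sd_signal, row.names = NULL)
}
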