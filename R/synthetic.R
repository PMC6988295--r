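#' Ground truth for a synthetic cytokine panel
#'
#' Describes the generative model the pipeline is validated against:
#' log-normal analyte concentrations (immunoassay data are positive and
#' right-skewed) with per-group additive shifts on the log scale, an extra
#' cooperative interaction shift applied only to the designated
#' combined-pathology group, correlated analyte noise, optional
#' detection-limit censoring, and continuous phenotypes linearly coupled to
#' a latent inflammation factor (defined as a sample's mean injected log
#' shift across affected analytes).
#'
#' @param analytes analyte names (default: a 22-plex mouse cytokine/
#'   chemokine panel).
#' @param groups group labels in order.
#' @param group_sizes per-group sample counts (recycled; default 7).
#' @param combined_group which group receives `interaction_effects`
#'   (default: the last group).
#' @param baseline_log_mean per-analyte baseline of log concentration
#'   (log pg/mg); recycled.
#' @param baseline_log_sd per-analyte log-scale noise SD; recycled
#'   (default 0.5, a realistic biological coefficient of variation).
#' @param group_effects groups-by-analytes matrix of additive log-scale
#'   shifts (default all zero).
#' @param interaction_effects per-analyte extra shift for the combined
#'   group only (default all zero).
#' @param noise_correlation analyte correlation matrix (default compound
#'   symmetry with rho = 0.3, emulating co-regulated cytokines).
#' @param lod per-analyte lower detection limit on the concentration scale
#'   (default 0 = no censoring).
#' @param phenotype_coupling named list; each element
#'   `c(intercept, slope, noise_sd)` defines a phenotype as a linear
#'   function of the latent inflammation factor plus Gaussian noise.
#' @param seed default integer seed used by [generate_panel()].
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(analytes = mouse_panel_22(),
                            groups = c("APP_PS1", "DIAB", "APP_PS1-DIAB"),
                            group_sizes = 7L,
                            combined_group = groups[length(groups)],
                            baseline_log_mean = log(20),
                            baseline_log_sd = 0.5,
                            group_effects = NULL,
                            interaction_effects = NULL,
                            noise_correlation = NULL,
                            lod = 0,
                            phenotype_coupling = NULL,
                            seed = 1L) {
  p <- length(analytes)
  k <- length(groups)
  group_sizes <- rep_len(as.integer(group_sizes), k)
  if (any(group_sizes < 2L)) stop("group_sizes must be >= 2", call. = FALSE)
  if (!combined_group %in% groups) {
    stop("combined_group must be one of groups", call. = FALSE)
  }
  baseline_log_mean <- rep_len(baseline_log_mean, p)
  baseline_log_sd <- rep_len(baseline_log_sd, p)
  if (any(baseline_log_sd <= 0)) stop("baseline_log_sd must be > 0",
                                      call. = FALSE)
  if (is.null(group_effects)) {
    group_effects <- matrix(0, k, p)
  }
  group_effects <- as.matrix(group_effects)
  stopifnot(dim(group_effects) == c(k, p))
  dimnames(group_effects) <- list(groups, analytes)
  if (is.null(interaction_effects)) interaction_effects <- numeric(p)
  interaction_effects <- rep_len(interaction_effects, p)
  if (is.null(noise_correlation)) {
    noise_correlation <- matrix(0.3, p, p)
    diag(noise_correlation) <- 1
  }
  noise_correlation <- as.matrix(noise_correlation)
  stopifnot(dim(noise_correlation) == c(p, p))
  if (max(abs(noise_correlation - t(noise_correlation))) > 1e-12 ||
      any(abs(diag(noise_correlation) - 1) > 1e-12)) {
    stop("noise_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  lod <- rep_len(lod, p)
  if (any(lod < 0)) stop("lod must be >= 0", call. = FALSE)
  if (!is.null(phenotype_coupling)) {
    stopifnot(is.list(phenotype_coupling),
              all(lengths(phenotype_coupling) == 3L))
  }
  structure(
    list(analytes = analytes, groups = groups, group_sizes = group_sizes,
         combined_group = combined_group,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         group_effects = group_effects,
         interaction_effects = stats::setNames(interaction_effects, analytes),
         noise_correlation = noise_correlation,
         lod = stats::setNames(lod, analytes),
         phenotype_coupling = phenotype_coupling,
         seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' The default 22-analyte mouse cytokine/chemokine panel
#'
#' The standard mouse 23-plex bead panel minus G-CSF (the analyte that is
#' typically censored below background in brain lysates).
#'
#' @return character vector of 22 analyte names.
#' @export
mouse_panel_22 <- function() {
  c("IL-1a", "IL-1b", "IL-2", "IL-3", "IL-4", "IL-5", "IL-6", "IL-9",
    "IL-10", "IL-12p40", "IL-12p70", "IL-13", "IL-17", "Eotaxin",
    "GM-CSF", "IFN-g", "KC", "MCP-1", "MIP-1a", "MIP-1b", "RANTES",
    "TNF-a")
}

#' Generate a synthetic cytokine panel from a ground truth
#'
#' Per sample, log-concentration = baseline + group effect + interaction
#' (combined group only) + correlated Gaussian noise; concentrations are
#' exponentiated, and cells below the detection limit are censored (set
#' missing and flagged). Each phenotype is a linear function of the
#' sample's latent inflammation factor (mean injected shift across
#' affected analytes) plus Gaussian noise. Fully reproducible by seed.
#'
#' @param truth a [synthetic_truth].
#' @param seed integer seed (default: the truth's own).
#' @return list with `panel` (a [cytokine_panel], phenotypes attached),
#'   `phenotypes` (data.frame or NULL), and `truth` (echo).
#' @export
generate_panel <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(as.integer(seed))
  p <- length(truth$analytes)
  n <- sum(truth$group_sizes)
  chol_c <- tryCatch(chol(truth$noise_correlation),
                     error = function(e)
                       stop("noise_correlation is not positive definite",
                            call. = FALSE))
  group <- factor(rep(truth$groups, truth$group_sizes),
                  levels = truth$groups)
  shift <- truth$group_effects[as.integer(group), , drop = FALSE]
  combined <- group == truth$combined_group
  shift[combined, ] <- sweep(shift[combined, , drop = FALSE], 2L,
                             truth$interaction_effects, "+")

  eps <- matrix(stats::rnorm(n * p), n, p) %*% chol_c
  eps <- sweep(eps, 2L, truth$baseline_log_sd, "*")
  logv <- sweep(shift + eps, 2L, truth$baseline_log_mean, "+")
  values <- exp(logv)
  dimnames(values) <- list(sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", group),
                                   stats::ave(seq_len(n), group,
                                              FUN = seq_along)),
                           truth$analytes)

  below <- sweep(values, 2L, truth$lod, "<")
  values[below] <- NA_real_

  affected <- colSums(abs(truth$group_effects)) > 0 |
    abs(truth$interaction_effects) > 0
  factor_lat <- if (any(affected)) {
    rowMeans(shift[, affected, drop = FALSE])
  } else rep(0, n)

  phenotypes <- NULL
  if (!is.null(truth$phenotype_coupling)) {
    phenotypes <- as.data.frame(lapply(truth$phenotype_coupling, function(cf) {
      cf[1] + cf[2] * factor_lat + stats::rnorm(n, sd = cf[3])
    }))
    rownames(phenotypes) <- rownames(values)
  }

  panel <- cytokine_panel(values, group = group, units = "pg_per_mg",
                          lod = truth$lod, phenotypes = phenotypes)
  list(panel = panel, phenotypes = phenotypes, truth = truth,
       latent_factor = factor_lat)
}

#' Documented preset generative scenarios
#'
#' Qualitative emulations of combined amyloid + diabetes cohort designs:
#' three groups (amyloid-only, diabetes-only, combined) of 7 mice, a broad
#' moderate upregulation under each single pathology, and a cooperative
#' chemokine-skewed interaction confined to the combined group. The
#' `"null"` preset has no effects at all. Each preset includes G-CSF as a
#' 23rd analyte whose detection limit censors it in the majority of
#' samples, exercising the exclusion rule. Phenotype coupling follows the
#' usual metabolic sign structure: glucose and plasma amyloid positive and
#' negative couplings respectively, insulin negatively coupled in the
#' type-2-diabetes-like scenario.
#'
#' @param name one of `"null"`, `"stz_like"`, `"dbdb_like"`, `"hfd_like"`.
#' @param group_sizes per-group n (default 7).
#' @param seed default generation seed.
#' @return a [synthetic_truth].
#' @export
preset_scenarios <- function(name = c("null", "stz_like", "dbdb_like",
                                      "hfd_like"),
                             group_sizes = 7L, seed = 1L) {
  name <- match.arg(name)
  analytes <- c(mouse_panel_22(), "G-CSF")
  p <- length(analytes)
  # plausible pg/mg baselines spanning two orders of magnitude
  base <- log(c(40, 25, 8, 15, 10, 12, 30, 18, 22, 60, 9, 14, 11, 80,
                13, 16, 50, 35, 28, 26, 90, 20, 5))
  lod <- c(rep(0.5, p - 1L), 12)   # G-CSF sits mostly below its LOD

  pro_inflam <- c("IL-1a", "IL-1b", "IL-6", "TNF-a", "IFN-g", "IL-17",
                  "MCP-1", "MIP-1a", "MIP-1b", "KC")
  amyloid_set <- c("IL-6", "TNF-a", "MCP-1", "IL-1b", "GM-CSF", "IL-12p70")

  designated <- switch(name,
    null = character(0),
    stz_like = c("MCP-1", "IL-1a", "IL-3", "IL-17", "IFN-g"),
    dbdb_like = c("MIP-1a", "MIP-1b", "MCP-1", "GM-CSF", "IFN-g"),
    hfd_like = c("MIP-1a", "IL-1b", "Eotaxin", "IL-17", "MCP-1"))

  diab_label <- switch(name, null = "DIAB", stz_like = "STZ",
                       dbdb_like = "db-db", hfd_like = "HFD")
  groups <- c("APP_PS1", diab_label, paste0("APP_PS1-", diab_label))

  ge <- matrix(0, 3, p, dimnames = list(groups, analytes))
  ie <- stats::setNames(numeric(p), analytes)
  if (name != "null") {
    ge["APP_PS1", amyloid_set] <- 0.3
    ge[diab_label, pro_inflam] <- 0.5
    ge[3, ] <- ge[1, ] + ge[2, ]        # combined carries both main effects
    ie[designated] <- 1.2               # cooperative interaction
  }

  coupling <- switch(name,
    null = list(glucose = c(150, 0, 20), insulin = c(3, 0, 0.5)),
    stz_like = list(glucose = c(150, 60, 20), insulin = c(3, -1.0, 0.4),
                    abeta40 = c(150, -25, 15), abeta42 = c(100, -18, 10)),
    dbdb_like = list(glucose = c(180, 80, 20), insulin = c(4, -1.2, 0.4),
                     abeta40 = c(180, -40, 15), abeta42 = c(120, -30, 10)),
    hfd_like = list(glucose = c(140, 40, 15), insulin = c(5, 1.0, 0.5)))

  synthetic_truth(analytes = analytes, groups = groups,
                  group_sizes = group_sizes, combined_group = groups[3],
                  baseline_log_mean = base, baseline_log_sd = 0.5,
                  group_effects = ge, interaction_effects = ie,
                  lod = lod, phenotype_coupling = coupling, seed = seed)
}

#' Serialize a synthetic truth to JSON
#'
#' @param truth a [synthetic_truth].
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- truth
  obj$group_effects <- as.data.frame(truth$group_effects)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
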