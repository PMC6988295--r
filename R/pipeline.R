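#' Assemble a pipeline run configuration
#'
#' @param panel path to a panel CSV, or a [cytokine_panel] object.
#' @param metadata path to the metadata CSV (ignored when `panel` is an
#'   object).
#' @param mode analysis mode: `"plsda"`, `"plsr"` or `"univariate"`.
#' @param positive_group designated (combined-pathology) group for the
#'   contrast objective and orientation.
#' @param phenotype phenotype column name (PLSR mode).
#' @param objective rotation objective; defaults by mode.
#' @param fraction,iterations,seed Monte-Carlo subsampling parameters
#'   (defaults 0.8 / 1000).
#' @param grid_points rotation search grid size.
#' @param max_below_lod_fraction,impute detection-limit handling (see
#'   [filter_detectable()]).
#' @param outlier_q ROUT false discovery rate for univariate statistics.
#' @param sep panel/metadata field separator.
#' @param out output directory (created if needed); NULL disables writing.
#' @return a `run_config` list.
#' @export
run_config <- function(panel, metadata = NULL,
                       mode = c("plsda", "plsr", "univariate"),
                       positive_group = NULL, phenotype = NULL,
                       objective = NULL,
                       fraction = 0.8, iterations = 1000L, seed = 1L,
                       grid_points = 3601L,
                       max_below_lod_fraction = 0.5, impute = "half_lod",
                       outlier_q = 0.01, sep = ",", out = NULL) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]",
                                          call. = FALSE)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  structure(list(panel = panel, metadata = metadata, mode = mode,
                 positive_group = positive_group, phenotype = phenotype,
                 objective = objective, fraction = fraction,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 grid_points = as.integer(grid_points),
                 max_below_lod_fraction = max_below_lod_fraction,
                 impute = impute, outlier_q = outlier_q, sep = sep,
                 out = out),
            class = "run_config")
}

.load_panel <- function(config) {
  if (inherits(config$panel, "cytokine_panel")) return(config$panel)
  read_panel(config$panel, config$metadata, sep = config$sep)
}

.write_outputs <- function(config, files) {
  if (is.null(config$out)) return(invisible(NULL))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(files)) {
    path <- file.path(config$out, nm)
    x <- files[[nm]]
    if (is.data.frame(x)) {
      utils::write.csv(x, path, row.names = FALSE)
    } else {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
  }
  invisible(names(files))
}

.manifest <- function(config, extra = list()) {
  cfg <- unclass(config)
  cfg$panel <- if (inherits(config$panel, "cytokine_panel"))
    "<in-memory panel>" else config$panel
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(json, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  c(list(package = "cytolv",
         version = as.character(utils::packageVersion("cytolv")),
         r_version = R.version.string,
         seed = config$seed, config = cfg, config_md5 = hash),
    extra)
}

# shared front half: load, filter, build analysis spec
.prepare <- function(config) {
  panel <- .load_panel(config)
  filt <- filter_detectable(panel, config$max_below_lod_fraction,
                            impute = config$impute)
  spec <- if (config$mode == "univariate") NULL else lv_analysis(
    mode = config$mode,
    objective = config$objective,
    positive_group = config$positive_group,
    phenotype = config$phenotype,
    grid_points = config$grid_points)
  list(panel = filt$panel, exclusions = filt$full_report, spec = spec)
}

.profile_tables <- function(prof) {
  lv1 <- as.data.frame(prof$lv1)
  lv2 <- as.data.frame(prof$lv2)
  ord <- order(-lv1$mean_signal)   # export in descending LV1 signal
  list(lv1 = lv1[ord, ], lv2 = lv2[ord, ])
}

#' Run the PLSDA pipeline
#'
#' Full discriminant workflow: detection-limit filtering, z-scoring, NIPALS
#' PLSDA, LV-plane rotation toward the configured objective, orthogonality
#' check, Monte-Carlo subsampling profiles, and Welch ANOVA with Dunnett T3
#' on the rotated LV1 and LV2 composite scores. Writes profile, score and
#' statistics CSVs plus a JSON manifest when `config$out` is set.
#'
#' Note the rotation objective is optimized on the same samples the ANOVA
#' is then run on; the reported p values inherit that selection effect
#' (flagged in the manifest).
#'
#' @param config a [run_config] with `mode = "plsda"`.
#' @return list: `panel`, `model`, `rotation`, `profiles`, `scores`,
#'   `anova_lv1`, `anova_lv2`, `exclusions`, `manifest`.
#' @export
run_plsda <- function(config) {
  prep <- .prepare(config)
  prof <- subsample_profiles(prep$panel, prep$spec,
                             fraction = config$fraction,
                             iterations = config$iterations,
                             seed = config$seed)
  check_orthogonality(prof$rotation)
  scores <- prof$rotation$T_rot
  cmp1 <- group_comparison(scores[, 1L], prep$panel$group)
  cmp2 <- group_comparison(scores[, 2L], prep$panel$group)
  tabs <- .profile_tables(prof)
  manifest <- .manifest(config, list(
    theta = prof$rotation$theta,
    objective = prof$rotation$objective_name,
    objective_value = prof$rotation$objective_value,
    n_retries = prof$n_retries,
    note = paste("rotation objective and ANOVA use the same samples;",
                 "omnibus p values are optimistic under the null")))
  score_tab <- data.frame(sample = rownames(scores),
                          group = as.character(prep$panel$group),
                          LV1 = scores[, 1L], LV2 = scores[, 2L],
                          row.names = NULL)
  stats_tab <- rbind(
    data.frame(component = "LV1", .omnibus_row(cmp1$omnibus)),
    data.frame(component = "LV2", .omnibus_row(cmp2$omnibus)))
  pair_tab <- rbind(data.frame(component = "LV1", cmp1$pairwise),
                    data.frame(component = "LV2", cmp2$pairwise))
  .write_outputs(config, list(
    "lv1_profile.csv" = tabs$lv1, "lv2_profile.csv" = tabs$lv2,
    "scores.csv" = score_tab, "anova.csv" = stats_tab,
    "pairwise.csv" = pair_tab,
    "zscores.csv" = .zscore_table(prep$panel),
    "exclusions.json" = prep$exclusions,
    "manifest.json" = manifest))
  if (!is.null(config$out)) {
    write_pls_model(prof$model, file.path(config$out, "model"))
  }
  list(panel = prep$panel, model = prof$model, rotation = prof$rotation,
       profiles = prof, scores = scores, anova_lv1 = cmp1, anova_lv2 = cmp2,
       exclusions = prep$exclusions, manifest = manifest)
}

.zscore_table <- function(panel) {
  z <- zscore(panel)
  data.frame(sample = rownames(z), group = as.character(panel$group),
             z, check.names = FALSE)
}

.omnibus_row <- function(om) {
  data.frame(F_welch = om$F_welch, df1 = om$df1, df2 = om$df2,
             p = om$p_omnibus, stars = p_stars(om$p_omnibus))
}

#' Run the PLSR pipeline against a continuous phenotype
#'
#' As [run_plsda()] but regressing the panel on a continuous phenotype and
#' rotating LV1 toward maximum score-phenotype correlation; also reports
#' the Pearson correlation of rotated LV1 scores with the phenotype.
#'
#' @param config a [run_config] with `mode = "plsr"` and `phenotype` set.
#' @return list as in [run_plsda()] plus `correlation`.
#' @export
run_plsr <- function(config) {
  if (is.null(config$phenotype)) stop("plsr requires a phenotype",
                                      call. = FALSE)
  prep <- .prepare(config)
  ph <- prep$panel$phenotypes[[config$phenotype]]
  if (is.null(ph)) {
    stop("phenotype '", config$phenotype, "' not found; available: ",
         paste(names(prep$panel$phenotypes), collapse = ", "),
         call. = FALSE)
  }
  prof <- subsample_profiles(prep$panel, prep$spec,
                             fraction = config$fraction,
                             iterations = config$iterations,
                             seed = config$seed)
  check_orthogonality(prof$rotation)
  scores <- prof$rotation$T_rot
  corr <- pearson_cor(scores[, 1L], ph)
  tabs <- .profile_tables(prof)
  manifest <- .manifest(config, list(
    theta = prof$rotation$theta, objective = prof$rotation$objective_name,
    objective_value = prof$rotation$objective_value,
    n_retries = prof$n_retries,
    note = paste("LV1 is rotated to maximize |r| with the phenotype;",
                 "the reported r inherits that selection effect")))
  score_tab <- data.frame(sample = rownames(scores),
                          group = as.character(prep$panel$group),
                          phenotype = ph,
                          LV1 = scores[, 1L], LV2 = scores[, 2L],
                          row.names = NULL)
  .write_outputs(config, list(
    "lv1_profile.csv" = tabs$lv1, "lv2_profile.csv" = tabs$lv2,
    "scores.csv" = score_tab,
    "correlation.json" = list(phenotype = config$phenotype, r = corr$r,
                              n = corr$n, p = corr$p,
                              stars = p_stars(corr$p)),
    "exclusions.json" = prep$exclusions,
    "manifest.json" = manifest))
  list(panel = prep$panel, model = prof$model, rotation = prof$rotation,
       profiles = prof, scores = scores, correlation = corr,
       exclusions = prep$exclusions, manifest = manifest)
}

#' Per-analyte univariate statistics
#'
#' Welch ANOVA with Dunnett T3 per analyte, after ROUT outlier removal
#' within each analyte-group cell (outlier removal applies to univariate
#' statistics only; multivariate fits always use all samples).
#'
#' @param config a [run_config] with `mode = "univariate"`.
#' @return list: `panel`, `table` (per analyte omnibus + n outliers),
#'   `pairwise`, `manifest`.
#' @export
run_univariate <- function(config) {
  prep <- .prepare(config)
  panel <- prep$panel
  rows <- list(); pw <- list()
  for (a in panel$analytes) {
    vals <- panel$values[, a]
    gr <- panel$group
    keep <- rep(TRUE, length(vals))
    for (g in levels(gr)) {
      ix <- which(gr == g)
      if (length(ix) >= 4L) {
        keep[ix][rout_outliers(vals[ix], Q = config$outlier_q)] <- FALSE
      }
    }
    cmp <- group_comparison(vals[keep], droplevels(gr[keep]))
    rows[[a]] <- data.frame(analyte = a, n_outliers = sum(!keep),
                            .omnibus_row(cmp$omnibus))
    pw[[a]] <- data.frame(analyte = a, cmp$pairwise)
  }
  table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  pairwise <- do.call(rbind, c(pw, list(make.row.names = FALSE)))
  manifest <- .manifest(config)
  .write_outputs(config, list("univariate.csv" = table,
                              "univariate_pairwise.csv" = pairwise,
                              "exclusions.json" = prep$exclusions,
                              "manifest.json" = manifest))
  list(panel = panel, table = table, pairwise = pairwise,
       manifest = manifest)
}

#' Generate and write a synthetic scenario
#'
#' @param scenario preset name (see [preset_scenarios()]).
#' @param out output directory; receives `panel.csv`, `metadata.csv` and
#'   `truth.json`.
#' @param group_sizes,seed passed to the generator.
#' @return (invisibly) the generated panel bundle.
#' @export
run_simulate <- function(scenario, out, group_sizes = 7L, seed = 1L) {
  truth <- preset_scenarios(scenario, group_sizes = group_sizes, seed = seed)
  gen <- generate_panel(truth, seed = seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_panel(gen$panel, file.path(out, "panel.csv"),
              file.path(out, "metadata.csv"))
  write_truth_json(truth, file.path(out, "truth.json"))
  invisible(gen)
}
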