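#' Construct a cytokine panel
#'
#' A `cytokine_panel` bundles a sample-by-analyte concentration matrix with
#' per-sample metadata (group, optionally sex and continuous phenotypes) and
#' per-cell detection-limit information. It is the common currency of the
#' pipeline: reading, protein normalization, detection-limit filtering,
#' z-scoring and all downstream modelling operate on this object.
#'
#' @param values numeric matrix, samples in rows, analytes in columns. Row
#'   and column names are used as sample identifiers and analyte names; if
#'   absent they are synthesized.
#' @param group character or factor of per-sample group labels.
#' @param units concentration units, `"pg_per_mL"` (raw assay) or
#'   `"pg_per_mg"` (normalized to total protein).
#' @param sex optional per-sample sex labels.
#' @param lod optional lower limits of detection: a per-analyte vector or a
#'   full samples-by-analytes matrix (the latter arises after per-sample
#'   protein normalization). Stored internally as a matrix.
#' @param below_lod optional logical matrix flagging censored cells. If
#'   omitted and `lod` is given, it is computed as `values < lod` (missing
#'   values are also flagged).
#' @param phenotypes optional data.frame of continuous per-sample covariates
#'   (e.g. plasma glucose, insulin, amyloid-beta), rownames matching samples.
#'
#' @return an object of class `cytokine_panel`.
#' @export
cytokine_panel <- function(values, group,
                           units = c("pg_per_mg", "pg_per_mL"),
                           sex = NULL, lod = NULL, below_lod = NULL,
                           phenotypes = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) == 0L) {
    stop("panel has zero analytes", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("A", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (length(group) != nrow(values)) {
    stop("length(group) must equal the number of samples", call. = FALSE)
  }
  group <- factor(group)
  if (!is.null(sex) && length(sex) != nrow(values)) {
    stop("length(sex) must equal the number of samples", call. = FALSE)
  }

  if (!is.null(lod)) {
    if (is.matrix(lod)) {
      stopifnot(dim(lod) == dim(values))
    } else {
      if (length(lod) != ncol(values)) {
        stop("lod must have one entry per analyte", call. = FALSE)
      }
      lod <- matrix(lod, nrow = nrow(values), ncol = ncol(values),
                    byrow = TRUE, dimnames = dimnames(values))
    }
    if (any(lod < 0, na.rm = TRUE)) stop("lod must be >= 0", call. = FALSE)
  }
  if (is.null(below_lod)) {
    if (!is.null(lod)) {
      below_lod <- (values < lod) | is.na(values)
      below_lod[is.na(below_lod)] <- TRUE
    } else {
      # without detection limits, missing cells are the censoring flag
      below_lod <- is.na(values)
    }
  } else {
    below_lod <- as.matrix(below_lod)
    stopifnot(dim(below_lod) == dim(values))
    dimnames(below_lod) <- dimnames(values)
  }

  if (!is.null(phenotypes)) {
    phenotypes <- as.data.frame(phenotypes)
    if (nrow(phenotypes) != nrow(values)) {
      stop("phenotypes must have one row per sample", call. = FALSE)
    }
    rownames(phenotypes) <- rownames(values)
  }

  structure(
    list(values = values,
         samples = rownames(values),
         analytes = colnames(values),
         units = units,
         group = group,
         sex = sex,
         lod = lod,
         below_lod = below_lod,
         phenotypes = phenotypes),
    class = "cytokine_panel")
}

#' @export
print.cytokine_panel <- function(x, ...) {
  cat(sprintf("<cytokine_panel> %d samples x %d analytes [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  cat("groups:", paste(sprintf("%s(%d)", levels(x$group),
                               tabulate(x$group)), collapse = " "), "\n")
  n_cens <- sum(x$below_lod)
  if (n_cens > 0) cat("censored cells:", n_cens, "\n")
  if (!is.null(x$phenotypes)) {
    cat("phenotypes:", paste(names(x$phenotypes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cytokine_panel <- function(x) dim(x$values)

#' Read a cytokine panel from delimited text
#'
#' Reads a concentration table (one row per sample, one column per analyte,
#' header row of analyte names, first column of sample identifiers) plus a
#' metadata table keyed by sample identifier. Cells that do not parse as
#' numbers (e.g. `"n.d."`) are flagged missing, not coerced to zero.
#' Samples present in only one of the two files are dropped with a warning;
#' duplicate sample identifiers are an error.
#'
#' @param path path to the panel table.
#' @param metadata_path path to the metadata table; must contain the columns
#'   named by `sample_col` and `group_col`. Additional numeric columns are
#'   attached as phenotypes; a `sex` column is attached as sex.
#' @param sep field separator for both files (default comma; use `"\t"` for
#'   TSV).
#' @param sample_col,group_col,sex_col metadata column names.
#' @param units units of the stored concentrations.
#' @param lod optional per-analyte detection limits (named vector; names
#'   matched to analytes).
#' @param na_strings strings to treat as missing/not-detected.
#'
#' @return a [cytokine_panel].
#' @export
read_panel <- function(path, metadata_path, sep = ",",
                       sample_col = "sample_id", group_col = "group",
                       sex_col = "sex",
                       units = c("pg_per_mg", "pg_per_mL"),
                       lod = NULL,
                       na_strings = c("NA", "", "n.d.", "nd", "ND", "n/a")) {
  units <- match.arg(units)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("panel table has zero analytes", call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample identifiers in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals %in% na_strings] <- NA
  suppressWarnings(storage.mode(vals) <- "double")
  rownames(vals) <- ids

  meta <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c(sample_col, group_col) %in% names(meta))) {
    stop("metadata must contain columns '", sample_col, "' and '",
         group_col, "'", call. = FALSE)
  }
  if (anyDuplicated(meta[[sample_col]])) {
    stop("duplicate sample identifiers in metadata", call. = FALSE)
  }
  common <- intersect(ids, meta[[sample_col]])
  if (length(common) < length(ids) ||
      length(common) < nrow(meta)) {
    dropped <- setdiff(union(ids, meta[[sample_col]]), common)
    warning("samples without both panel and metadata rows dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(common) == 0L) stop("no samples shared between panel and metadata",
                                 call. = FALSE)
  vals <- vals[common, , drop = FALSE]
  meta <- meta[match(common, meta[[sample_col]]), , drop = FALSE]

  pheno_cols <- setdiff(names(meta), c(sample_col, group_col, sex_col))
  pheno_cols <- pheno_cols[vapply(meta[pheno_cols], is.numeric, logical(1))]
  phenotypes <- if (length(pheno_cols)) meta[, pheno_cols, drop = FALSE] else NULL

  if (!is.null(lod) && !is.null(names(lod))) {
    lod <- lod[colnames(vals)]
  }
  cytokine_panel(vals, group = meta[[group_col]], units = units,
                 sex = if (sex_col %in% names(meta)) meta[[sex_col]] else NULL,
                 lod = lod, phenotypes = phenotypes)
}

#' Write a panel and its metadata to CSV
#'
#' Inverse of [read_panel()]: emits the concentration table (first column
#' `sample_id`) and the metadata table (group, sex, phenotypes).
#'
#' @param panel a [cytokine_panel].
#' @param path,metadata_path output file paths.
#' @param sep field separator.
#' @export
write_panel <- function(panel, path, metadata_path, sep = ",") {
  tab <- data.frame(sample_id = panel$samples, panel$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  meta <- data.frame(sample_id = panel$samples,
                     group = as.character(panel$group),
                     check.names = FALSE)
  if (!is.null(panel$sex)) meta$sex <- panel$sex
  if (!is.null(panel$phenotypes)) meta <- cbind(meta, panel$phenotypes)
  utils::write.table(meta, metadata_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(c(path, metadata_path))
}

#' Normalize raw concentrations to total protein
#'
#' Converts pg/mL assay readout to pg/mg total protein:
#' `value * assay_volume_mL / protein_mg` per sample. The default well
#' loading is 50 uL of lysate normalized to 7.5 ug/uL protein, i.e.
#' 0.375 mg per well. Detection limits are transformed identically.
#'
#' @param panel a [cytokine_panel] in `pg_per_mL`.
#' @param protein_mg per-sample total protein mass (mg); scalar recycled.
#' @param assay_volume_mL assay volume per well in mL (default 0.05).
#' @return the panel in `pg_per_mg`.
#' @export
normalize_total_protein <- function(panel, protein_mg = 0.375,
                                    assay_volume_mL = 0.05) {
  stopifnot(inherits(panel, "cytokine_panel"))
  if (panel$units != "pg_per_mL") {
    stop("panel must be in pg_per_mL to normalize", call. = FALSE)
  }
  n <- nrow(panel$values)
  protein_mg <- rep_len(protein_mg, n)
  bad <- which(!is.finite(protein_mg) | protein_mg <= 0)
  if (length(bad)) {
    stop("nonpositive total protein for sample(s): ",
         paste(panel$samples[bad], collapse = ", "), call. = FALSE)
  }
  fac <- assay_volume_mL / protein_mg
  panel$values <- panel$values * fac
  if (!is.null(panel$lod)) panel$lod <- panel$lod * fac
  panel$units <- "pg_per_mg"
  panel
}

#' Exclude analytes that are mostly below the detection limit
#'
#' Mirrors the standard multiplex-assay practice of dropping analytes that
#' are not detectable above background in the majority of samples (the
#' default threshold 0.5 encodes "the majority"). Censored cells of
#' surviving analytes are imputed at LOD/2 by default (a common immunoassay
#' convention), at the LOD itself, or left missing.
#'
#' @param panel a [cytokine_panel] with its `below_lod` mask populated.
#' @param max_below_lod_fraction analytes with a larger censored fraction
#'   are removed.
#' @param impute how surviving censored cells are filled: `"half_lod"`
#'   (LOD/2), `"lod"`, or `"missing"` (NA).
#' @return list with elements `panel` (filtered) and `report` (data.frame
#'   of analyte, n_below, fraction, excluded).
#' @export
filter_detectable <- function(panel, max_below_lod_fraction = 0.5,
                              impute = c("half_lod", "lod", "missing")) {
  stopifnot(inherits(panel, "cytokine_panel"))
  impute <- match.arg(impute)
  mask <- panel$below_lod
  frac <- colMeans(mask)
  excluded <- frac > max_below_lod_fraction
  report <- data.frame(analyte = panel$analytes,
                       n_below = colSums(mask),
                       fraction = unname(frac),
                       excluded = unname(excluded),
                       row.names = NULL)
  if (all(excluded)) {
    stop("all analytes excluded at max_below_lod_fraction = ",
         max_below_lod_fraction, call. = FALSE)
  }
  keep <- !excluded
  panel$values <- panel$values[, keep, drop = FALSE]
  panel$below_lod <- mask[, keep, drop = FALSE]
  if (!is.null(panel$lod)) panel$lod <- panel$lod[, keep, drop = FALSE]
  panel$analytes <- colnames(panel$values)

  cens <- panel$below_lod
  if (any(cens)) {
    if (impute == "missing") {
      panel$values[cens] <- NA_real_
    } else {
      if (is.null(panel$lod)) {
        stop("cannot impute censored cells without detection limits",
             call. = FALSE)
      }
      fill <- if (impute == "half_lod") panel$lod / 2 else panel$lod
      panel$values[cens] <- fill[cens]
    }
  }
  list(panel = panel, report = report[report$excluded, , drop = FALSE],
       full_report = report)
}

#' Z-score a panel (or matrix) per analyte
#'
#' Column-standardizes using the sample standard deviation (denominator
#' n - 1), optionally within a subset of samples. Standardization is always
#' recomputed within the sample set of the analysis at hand, because each
#' group comparison defines its own reference population.
#'
#' @param x a [cytokine_panel] or numeric matrix.
#' @param subset optional sample selector (indices, logical, or sample
#'   names) defining the rows to standardize (and return).
#' @return numeric matrix with columns of mean 0 and sd 1, with attributes
#'   `center` and `scale`.
#' @export
zscore <- function(x, subset = NULL) {
  m <- if (inherits(x, "cytokine_panel")) x$values else as.matrix(x)
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  if (anyNA(m)) stop("z-scoring requires complete values; impute or drop first",
                     call. = FALSE)
  ctr <- colMeans(m)
  dev <- sweep(m, 2L, ctr, "-")
  sds <- sqrt(colSums(dev^2) / (nrow(m) - 1L))
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    stop("zero-variance analyte(s): ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  }
  z <- sweep(dev, 2L, sds, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- sds
  z
}
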