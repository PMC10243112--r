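# FeatureTable: the pipeline's spine. A features x samples peak-area matrix
# plus per-feature annotation and per-sample metadata, kept aligned by
# construction.

#' Construct a feature table
#'
#' Bundles a features x samples intensity matrix (peak areas, missing
#' allowed, never negative) with per-feature annotation and per-sample
#' metadata. Row order of `annotations` matches matrix rows; row order of
#' `samples` matches matrix columns.
#'
#' @param intensities Numeric matrix, features in rows, samples in columns;
#'   `NA` marks a missing (undetected) peak; no negative values.
#' @param annotations `data.frame` with columns `feature_id`, `lipid_name`,
#'   `adduct`, `rt_min`, `mz`, `ion_mode`, `confidence_level`.
#' @param samples `data.frame` with columns `sample_id`, `animal_id`,
#'   `group` (`DKO`/`control`), `role` (`study`/`qc`/`blank`), `age_weeks`,
#'   `lifespan_weeks`, `injection_order`, `event_observed`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, annotations, samples) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  validate_feature_table(intensities, annotations, samples)
  rownames(intensities) <- annotations$feature_id
  colnames(intensities) <- samples$sample_id
  structure(list(intensities = intensities,
                 annotations = as.data.frame(annotations),
                 samples = as.data.frame(samples)),
            class = "feature_table")
}

FEATURE_COLS <- c("feature_id", "lipid_name", "adduct", "rt_min", "mz",
                  "ion_mode", "confidence_level")
SAMPLE_COLS <- c("sample_id", "animal_id", "group", "role", "age_weeks",
                 "lifespan_weeks", "injection_order", "event_observed")

validate_feature_table <- function(intensities, annotations, samples) {
  missing_f <- setdiff(FEATURE_COLS, names(annotations))
  if (length(missing_f))
    stop("features table missing required column(s): ",
         paste(missing_f, collapse = ", "))
  missing_s <- setdiff(SAMPLE_COLS, names(samples))
  if (length(missing_s))
    stop("samples table missing required column(s): ",
         paste(missing_s, collapse = ", "))
  if (nrow(intensities) != nrow(annotations))
    stop("intensity rows (", nrow(intensities), ") != annotation rows (",
         nrow(annotations), ")")
  if (ncol(intensities) != nrow(samples))
    stop("intensity columns (", ncol(intensities), ") != sample rows (",
         nrow(samples), ")")
  neg <- which(!is.na(intensities) & intensities < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative intensity at feature row ", neg[1, 1], ", sample column ",
         neg[1, 2], " (", nrow(neg), " offending cell(s) total)")
  if (anyDuplicated(annotations$feature_id))
    stop("duplicated feature_id in annotations")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in samples")
  bad_role <- setdiff(unique(samples$role), c("study", "qc", "blank"))
  if (length(bad_role))
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))
  study <- samples[samples$role == "study", , drop = FALSE]
  if (nrow(study)) {
    over <- which(study$age_weeks > study$lifespan_weeks)
    if (length(over))
      stop("age_weeks > lifespan_weeks for sample(s): ",
           paste(utils::head(study$sample_id[over], 5), collapse = ", "))
  }
  if (anyDuplicated(samples$injection_order))
    stop("injection_order must be unique within a run")
  invisible(TRUE)
}

#' @export
print.feature_table <- function(x, ...) {
  roles <- table(factor(x$samples$role, c("study", "qc", "blank")))
  cat("feature_table:", nrow(x$intensities), "features x",
      ncol(x$intensities), "samples\n")
  cat("  samples: ", roles[["study"]], " study / ", roles[["qc"]], " QC / ",
      roles[["blank"]], " blank\n", sep = "")
  cat("  missing cells:", sum(is.na(x$intensities)), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table
#'
#' @param x A `feature_table`.
#' @param features Row selector (feature ids, indices or logical).
#' @param samples Column selector (sample ids, indices or logical).
#' @return A `feature_table` restricted to the selection.
#' @export
subset_features <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "feature_table"))
  fi <- if (is.null(features)) seq_len(nrow(x$intensities)) else {
    if (is.character(features)) match(features, x$annotations$feature_id)
    else features
  }
  si <- if (is.null(samples)) seq_len(ncol(x$intensities)) else {
    if (is.character(samples)) match(samples, x$samples$sample_id)
    else samples
  }
  if (anyNA(fi)) stop("unknown feature id(s) in selection")
  if (anyNA(si)) stop("unknown sample id(s) in selection")
  feature_table(x$intensities[fi, si, drop = FALSE],
                x$annotations[fi, , drop = FALSE],
                x$samples[si, , drop = FALSE])
}

#' Read a feature table from its CSV trio
#'
#' `intensities.csv` holds `feature_id` in the first column and one column
#' per sample (empty cells are missing values); `features.csv` and
#' `samples.csv` hold the annotation and metadata tables.
#'
#' @param intensity_path,annotation_path,sample_path CSV file paths.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(intensity_path, annotation_path, sample_path) {
  for (p in c(intensity_path, annotation_path, sample_path))
    if (!file.exists(p)) stop("file not found: ", p)
  intens <- utils::read.csv(intensity_path, check.names = FALSE)
  if (names(intens)[1] != "feature_id")
    stop("intensities file must have 'feature_id' as its first column")
  ann <- utils::read.csv(annotation_path)
  smp <- utils::read.csv(sample_path)
  smp$event_observed <- as.logical(smp$event_observed)
  mat <- as.matrix(intens[, -1, drop = FALSE])
  rownames(mat) <- intens$feature_id
  if (!identical(intens$feature_id, ann$feature_id))
    stop("feature_id order differs between intensities and features files")
  if (!identical(names(intens)[-1], as.character(smp$sample_id)))
    stop("sample_id order differs between intensities and samples files")
  feature_table(mat, ann, smp)
}

#' Write a feature table to its CSV trio
#'
#' Inverse of [read_feature_table()]; numeric intensities are written at
#' full precision so a write/read round trip reproduces the table exactly.
#'
#' @param table A `feature_table`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_feature_table <- function(table, dir) {
  stopifnot(inherits(table, "feature_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("intensities.csv", "features.csv", "samples.csv"))
  intens <- data.frame(feature_id = table$annotations$feature_id,
                       table$intensities, check.names = FALSE)
  write_csv_exact(intens, paths[1])
  write_csv_exact(table$annotations, paths[2])
  write_csv_exact(table$samples, paths[3])
  invisible(paths)
}

# CSV writer that renders doubles with 17 significant digits so a
# write/read round trip is bitwise exact
write_csv_exact <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      txt <- sprintf("%.17g", df[[j]])
      txt[is.na(df[[j]])] <- NA
      df[[j]] <- txt
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Impute missing intensities
#'
#' Replaces each feature's missing cells with half its minimum observed
#' positive intensity (a standard limit-of-detection surrogate in
#' metabolomics), applied immediately before statistics or classification;
#' QC handling upstream keeps missing values as missing.
#'
#' @param table A `feature_table`.
#' @return A `feature_table` with no missing study values.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$intensities
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    need <- is.na(row) | row == 0
    if (!any(need)) next
    pos <- row[!is.na(row) & row > 0]
    if (length(pos) == 0)
      stop("feature ", table$annotations$feature_id[i],
           " has no positive intensity to impute from")
    m[i, need] <- min(pos) / 2
  }
  table$intensities <- m
  table
}

# column-standardize (mean 0, sd 1); constant columns go to 0
autoscale <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  }
  scaled <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(scaled, "center") <- center
  attr(scaled, "scale") <- scale
  scaled
}
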