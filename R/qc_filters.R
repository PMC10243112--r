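# Feature curation filters and QC-anchored signal drift correction.
#
# Filter criteria are computed on raw (uncorrected) values, so the three
# removal sets are order-insensitive; the conventional order is
# blank -> QC presence -> QC RSD -> drift correction.

filter_result <- function(table, keep, removed_ids, reason, flagged = character(0)) {
  res <- list(table = subset_features(table, features = keep),
              removed = removed_ids, reason = reason, flagged = flagged)
  class(res) <- "qc_filter_result"
  res
}

#' @export
print.qc_filter_result <- function(x, ...) {
  cat("qc filter (", x$reason, "): removed ", length(x$removed),
      " feature(s), ", nrow(x$table$intensities), " retained\n", sep = "")
  invisible(x)
}

#' Blank (background) filter
#'
#' A feature is background if its mean study-sample peak area is less than
#' `fold_threshold` times its mean blank-injection area; such features are
#' removed. A feature at exactly the threshold is retained. Missing cells
#' are treated as zero area for the purpose of the means.
#'
#' @param table A `feature_table` containing at least one blank injection.
#' @param fold_threshold Required study/blank mean ratio; default 5.
#' @return A list with the filtered `table`, the `removed` feature ids and
#'   the filter `reason`.
#' @export
blank_filter <- function(table, fold_threshold = 5) {
  stopifnot(inherits(table, "feature_table"))
  blank <- table$samples$role == "blank"
  study <- table$samples$role == "study"
  if (!any(blank)) stop("blank_filter requires at least one blank sample")
  m <- table$intensities
  m[is.na(m)] <- 0
  blank_mean <- rowMeans(m[, blank, drop = FALSE])
  study_mean <- rowMeans(m[, study, drop = FALSE])
  keep <- study_mean >= fold_threshold * blank_mean
  filter_result(table, which(keep), table$annotations$feature_id[!keep],
                sprintf("study mean < %g x blank mean", fold_threshold))
}

#' QC presence filter
#'
#' Removes features not detected (nonmissing and positive) in at least
#' `min_fraction` of the QC injections; a feature detected in exactly that
#' fraction is retained.
#'
#' @param table A `feature_table` with at least two QC injections.
#' @param min_fraction Minimum detected fraction of QCs; default 0.5.
#' @return As [blank_filter()].
#' @export
qc_presence_filter <- function(table, min_fraction = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  qc <- table$samples$role == "qc"
  if (sum(qc) < 2) stop("qc_presence_filter requires at least 2 QC samples")
  qm <- table$intensities[, qc, drop = FALSE]
  present <- rowMeans(!is.na(qm) & qm > 0)
  keep <- present >= min_fraction
  filter_result(table, which(keep), table$annotations$feature_id[!keep],
                sprintf("detected in < %g%% of QC injections", 100 * min_fraction))
}

#' QC relative-standard-deviation filter
#'
#' Removes features whose QC-injection RSD (100 * sd/mean over nonmissing
#' QC values) exceeds `max_rsd` percent; a feature at exactly the threshold
#' is retained. A feature whose QC mean is zero cannot be assessed and is
#' removed, flagged in the result.
#'
#' @param table A `feature_table` with at least two QC injections.
#' @param max_rsd Maximum tolerated QC RSD in percent; default 30.
#' @return As [blank_filter()], plus `flagged` ids with undefined RSD.
#' @export
qc_rsd_filter <- function(table, max_rsd = 30) {
  stopifnot(inherits(table, "feature_table"))
  qc <- table$samples$role == "qc"
  if (sum(qc) < 2) stop("qc_rsd_filter requires at least 2 QC samples")
  qm <- table$intensities[, qc, drop = FALSE]
  mu <- rowMeans(qm, na.rm = TRUE)
  sdv <- apply(qm, 1, stats::sd, na.rm = TRUE)
  rsd <- ifelse(is.na(mu) | mu == 0, Inf, 100 * sdv / mu)
  keep <- rsd <= max_rsd
  keep[is.na(keep)] <- FALSE
  flagged <- table$annotations$feature_id[is.na(mu) | mu == 0]
  filter_result(table, which(keep), table$annotations$feature_id[!keep],
                sprintf("QC RSD > %g%%", max_rsd), flagged = flagged)
}

#' QC-anchored cubic-spline drift correction
#'
#' Per feature, fits a cubic spline of QC intensity against injection order
#' and divides every sample's intensity by the spline value at its own
#' injection order, rescaling by the feature's overall QC mean so corrected
#' values stay on the original intensity scale. With more than six QC
#' injections a smoothing spline (smoothness by generalized
#' cross-validation) is used; with four to six, an exact cubic interpolant
#' with Forsythe-Malcolm-Moler end conditions, which reproduces polynomial
#' trends up to degree three exactly.
#'
#' @param table A `feature_table` with >= 4 QC injections.
#' @return A list with the corrected `table` and `flagged`, a data frame of
#'   feature/sample pairs set missing because the fitted spline was
#'   nonpositive there.
#' @export
qc_drift_correct <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  qc <- which(table$samples$role == "qc")
  if (length(qc) < 4) stop("qc_drift_correct requires >= 4 QC injections")
  ord <- table$samples$injection_order
  m <- table$intensities
  flagged <- list()
  for (i in seq_len(nrow(m))) {
    qx <- ord[qc]
    qy <- m[i, qc]
    ok <- !is.na(qy)
    if (sum(ok) < 4) next  # too few observed QCs to model drift
    qx <- qx[ok]; qy <- qy[ok]
    qc_mean <- mean(qy)
    if (all(qy == qy[1])) next  # constant trend: correction is identity
    pred <- if (length(qx) > 6) {
      fit <- stats::smooth.spline(qx, qy, cv = FALSE)  # GCV smoothness
      stats::predict(fit, ord)$y
    } else {
      stats::splinefun(qx, qy, method = "fmm")(ord)
    }
    bad <- !is.na(m[i, ]) & pred <= 0
    good <- !is.na(m[i, ]) & pred > 0
    m[i, good] <- m[i, good] / pred[good] * qc_mean
    if (any(bad)) {
      m[i, bad] <- NA_real_
      flagged[[length(flagged) + 1L]] <- data.frame(
        feature_id = table$annotations$feature_id[i],
        sample_id = table$samples$sample_id[bad])
    }
  }
  table$intensities <- m
  list(table = table,
       flagged = if (length(flagged)) do.call(rbind, flagged)
                 else data.frame(feature_id = character(0),
                                 sample_id = character(0)))
}

#' Run the full feature-curation sequence
#'
#' Blank filter, QC presence filter, QC RSD filter, then optional drift
#' correction, with a per-step removal report.
#'
#' @param table A `feature_table`.
#' @param blank_fold,qc_presence,qc_rsd Filter thresholds (see the
#'   individual filters).
#' @param drift_correct Apply [qc_drift_correct()] after filtering?
#' @return A list with the curated `table` and a `report` data frame of
#'   removed feature ids and the step that removed them.
#' @export
curate_features <- function(table, blank_fold = 5, qc_presence = 0.5,
                            qc_rsd = 30, drift_correct = TRUE) {
  steps <- list()
  b <- blank_filter(table, blank_fold)
  steps$blank <- b$removed
  p <- qc_presence_filter(b$table, qc_presence)
  steps$qc_presence <- p$removed
  r <- qc_rsd_filter(p$table, qc_rsd)
  steps$qc_rsd <- r$removed
  out <- r$table
  if (drift_correct && sum(out$samples$role == "qc") >= 4)
    out <- qc_drift_correct(out)$table
  report <- data.frame(
    feature_id = unlist(steps, use.names = FALSE),
    step = rep(names(steps), lengths(steps)))
  list(table = out, report = report)
}
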