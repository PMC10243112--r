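# Stage-resolved differential statistics: log2 fold changes on raw
# (imputed) intensities, Welch's unequal-variance t-tests, BH correction
# for the global contrast only, upset-style intersections and recurrence.

#' Per-feature log2 fold change between two sample groups
#'
#' `log2(mean_A / mean_B)` on raw (imputed) intensities; the convention
#' throughout is A = DKO (or comparison stage), B = control (or reference
#' stage), so positive values mean elevated in A.
#'
#' @param table A `feature_table` (imputation applied internally).
#' @param groupA_ids,groupB_ids Sample ids of the two groups, both nonempty.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(table, groupA_ids, groupB_ids) {
  stopifnot(inherits(table, "feature_table"))
  if (length(groupA_ids) == 0 || length(groupB_ids) == 0)
    stop("both groups must be nonempty")
  table <- impute_missing(table)
  a <- rowMeans(table$intensities[, groupA_ids, drop = FALSE])
  b <- rowMeans(table$intensities[, groupB_ids, drop = FALSE])
  if (any(b <= 0)) stop("nonpositive group-B mean after imputation")
  stats::setNames(log2(a / b), table$annotations$feature_id)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided test with the Welch-Satterthwaite degrees of freedom.
#'
#' @param a_values,b_values Numeric vectors, each of length >= 2.
#' @return List with `t`, `df` and `p`.
#' @export
welch_test <- function(a_values, b_values) {
  if (length(a_values) < 2 || length(b_values) < 2)
    stop("welch_test needs >= 2 values per group")
  if (stats::var(a_values) == 0 && stats::var(b_values) == 0) {
    if (mean(a_values) == mean(b_values))
      return(list(t = 0, df = length(a_values) + length(b_values) - 2, p = 1))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(a_values, b_values, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# Welch tests for every row of a matrix split into two column sets
welch_test_rows <- function(m, a_idx, b_idx) {
  out <- t(apply(m, 1, function(row) {
    res <- welch_test(row[a_idx], row[b_idx])
    c(res$t, res$df, res$p)
  }))
  colnames(out) <- c("t", "df", "p")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Global DKO-vs-control differential table
#'
#' Welch's t-test on all study samples pooled across draws (DKO vs control),
#' with log2 fold changes and BH q-values. This is the only contrast that
#' carries a multiplicity correction; the stage-resolved sets use unadjusted
#' p < alpha.
#'
#' @param table A `feature_table`.
#' @return `data.frame`: `feature_id`, `log2_fc`, `t`, `df`, `p`, `q`,
#'   sorted by input feature order, with contrast label attribute.
#' @export
global_differential <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  dko <- table$samples$sample_id[table$samples$role == "study" &
                                 table$samples$group == "DKO"]
  ctl <- table$samples$sample_id[table$samples$role == "study" &
                                 table$samples$group == "control"]
  imp <- impute_missing(table)
  fc <- log2_fold_change(table, dko, ctl)
  wt <- welch_test_rows(imp$intensities,
                        match(dko, imp$samples$sample_id),
                        match(ctl, imp$samples$sample_id))
  res <- data.frame(feature_id = table$annotations$feature_id,
                    log2_fc = unname(fc),
                    t = wt[, "t"], df = wt[, "df"], p = wt[, "p"],
                    q = bh_adjust(wt[, "p"]))
  attr(res, "contrast") <- "all: DKO vs control"
  res
}

#' Stage-resolved significance sets
#'
#' Within each lifetime stage, DKO vs control Welch's t-test; a feature with
#' unadjusted p < `alpha` is significant for that stage.
#'
#' @param table A `feature_table`.
#' @param lifetimes Output of [annotate_lifetime()].
#' @param alpha Per-stage significance level; default 0.05.
#' @return Named list of feature-id character vectors, one per stage I-V,
#'   with a `"records"` attribute holding the per-stage statistics.
#' @export
stage_significance <- function(table, lifetimes, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  imp <- impute_missing(table)
  sets <- list()
  records <- list()
  for (st in STAGE_LEVELS) {
    sel <- lifetimes[lifetimes$stage == st, , drop = FALSE]
    a_ids <- sel$sample_id[sel$group == "DKO"]
    b_ids <- sel$sample_id[sel$group == "control"]
    if (length(a_ids) < 2 || length(b_ids) < 2)
      stop("stage ", st, " has fewer than 2 samples in a group")
    wt <- welch_test_rows(imp$intensities,
                          match(a_ids, imp$samples$sample_id),
                          match(b_ids, imp$samples$sample_id))
    fc <- log2_fold_change(table, a_ids, b_ids)
    rec <- data.frame(feature_id = table$annotations$feature_id,
                      log2_fc = unname(fc),
                      t = wt[, "t"], df = wt[, "df"], p = wt[, "p"])
    records[[st]] <- rec
    sets[[paste0("stage ", st)]] <-
      rec$feature_id[rec$p < alpha]
  }
  attr(sets, "records") <- records
  sets
}

#' Exclusive set intersections (upset semantics)
#'
#' Partitions the union of a family of sets by exclusive membership pattern:
#' each feature is assigned to the combination of sets that contain it and
#' to no other pattern.
#'
#' @param family Named list of character vectors.
#' @return Named list of feature sets; names are `&`-joined set names.
#' @export
exclusive_intersections <- function(family) {
  stopifnot(is.list(family), length(names(family)) == length(family))
  universe <- sort(unique(unlist(family, use.names = FALSE)))
  if (length(universe) == 0) return(list())
  membership <- vapply(family, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(family)))
  pattern <- apply(membership, 1, function(row)
    paste(names(family)[row], collapse = " & "))
  split(universe, pattern)
}

#' Features recurring across stage sets
#'
#' @param family Named list of feature sets (e.g. [stage_significance()]).
#' @param min_sets Minimum number of sets a feature must belong to;
#'   default 3.
#' @return Character vector of recurrent feature ids.
#' @export
recurrent_features <- function(family, min_sets = 3) {
  if (min_sets > length(family))
    stop("min_sets exceeds the number of sets")
  counts <- table(unlist(lapply(family, unique), use.names = FALSE))
  sort(names(counts)[counts >= min_sets])
}

#' Volcano selection
#'
#' Features with Welch p < `alpha` and |log2 FC| >= `min_abs_log2fc`, with
#' fold change computed as comparison over reference. The selected set is
#' unchanged if the two groups are swapped (|FC| is symmetric).
#'
#' @param table A `feature_table`.
#' @param ref_ids,cmp_ids Sample ids of the reference and comparison groups.
#' @param alpha Significance level; default 0.05.
#' @param min_abs_log2fc Minimum absolute log2 fold change; default 1.
#' @return Character vector of selected feature ids, with the full
#'   statistics table as attribute `"records"`.
#' @export
volcano_select <- function(table, ref_ids, cmp_ids, alpha = 0.05,
                           min_abs_log2fc = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (length(ref_ids) < 2 || length(cmp_ids) < 2)
    stop("both groups need >= 2 samples")
  imp <- impute_missing(table)
  fc <- log2_fold_change(table, cmp_ids, ref_ids)
  wt <- welch_test_rows(imp$intensities,
                        match(cmp_ids, imp$samples$sample_id),
                        match(ref_ids, imp$samples$sample_id))
  rec <- data.frame(feature_id = table$annotations$feature_id,
                    log2_fc = unname(fc), p = wt[, "p"])
  sel <- rec$feature_id[rec$p < alpha & abs(rec$log2_fc) >= min_abs_log2fc]
  attr(sel, "records") <- rec
  sel
}
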