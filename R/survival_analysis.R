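# Survival-based prognostic lipid screening: Kaplan-Meier product-limit
# and Nelson-Aalen estimators, log-rank comparison, restricted mean
# survival time, median-split grouping and the candidate screen.
#
# Risk tables come from survival::survfit / survival::survdiff; the
# Nelson-Aalen cumulative hazard and the RMST step-function integral are
# assembled from the risk table.

#' Survival records of a cohort
#'
#' @param animal_id Animal identifiers.
#' @param time Lifespan or censoring time in weeks, positive.
#' @param event Logical; `TRUE` if the death was observed, `FALSE` if the
#'   animal was censored (alive at study end).
#' @return `data.frame` of class `survival_records`.
#' @export
survival_records <- function(animal_id, time, event) {
  if (any(time <= 0)) stop("survival times must be positive")
  structure(data.frame(animal_id = animal_id, time = as.numeric(time),
                       event = as.logical(event)),
            class = c("survival_records", "data.frame"))
}

# shared risk table: event-time grid with at-risk and event counts
risk_table <- function(records) {
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = records, conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Kaplan-Meier product-limit survival curve
#'
#' `S(t)` multiplies by `(1 - d_i/n_i)` at each event time; censored times
#' reduce the risk set without a factor. The curve also carries the
#' Nelson-Aalen cumulative hazard `H(t) = sum d_i/n_i`.
#'
#' @param records A [survival_records()] data frame.
#' @return Object of class `survival_curve`: data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `cumhaz`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) < 1) stop("need at least one survival record")
  rt <- risk_table(records)
  rt$cumhaz <- cumsum(rt$n_event / rt$n_risk)
  structure(rt, class = c("survival_curve", "data.frame"))
}

#' Nelson-Aalen cumulative hazard
#'
#' `H(t) = sum_{t_i <= t} d_i / n_i` over the event-time grid.
#'
#' @param records A [survival_records()] data frame.
#' @return Data frame `time`, `cumhaz`.
#' @export
nelson_aalen <- function(records) {
  curve <- km_estimate(records)
  curve[, c("time", "cumhaz")]
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("survival curve over", nrow(x), "time point(s); final S =",
      signif(x$surv[nrow(x)], 4), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Log-rank test between two groups
#'
#' One-degree-of-freedom log-rank statistic over the pooled event times
#' with hypergeometric variance (ties handled by simultaneous risk-set
#' accounting).
#'
#' @param recordsA,recordsB [survival_records()] for the two groups.
#' @return List with `chi2`, `p`, and `degenerate = TRUE` when neither
#'   group has any event (chi2 undefined, reported as 0, p = 1).
#' @export
logrank_test <- function(recordsA, recordsB) {
  if (nrow(recordsA) == 0 || nrow(recordsB) == 0)
    stop("both groups must be nonempty")
  if (!any(recordsA$event) && !any(recordsB$event))
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  pooled <- rbind(cbind(recordsA, .grp = "A"), cbind(recordsB, .grp = "B"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ .grp, data = pooled)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Restricted mean survival time
#'
#' Exact step-function integral of `S(t)` from 0 to `tau` ("time lost" is
#' `tau` minus this area).
#'
#' @param curve A `survival_curve` from [km_estimate()].
#' @param tau Restriction time, at most the largest observed time.
#' @return RMST in the time unit of the records (weeks).
#' @export
rmst <- function(curve, tau) {
  stopifnot(inherits(curve, "survival_curve"))
  if (tau > max(curve$time))
    stop("tau exceeds the largest observed time")
  times <- c(0, curve$time[curve$time < tau], tau)
  s <- c(1, curve$surv[curve$time < tau])
  sum(diff(times) * s)
}

#' Difference in restricted mean survival time
#'
#' `RMST_A(tau) - RMST_B(tau)`; by default `tau` is the smaller of the two
#' groups' largest observed times, so both curves are integrated over a
#' range where each is defined.
#'
#' @param curveA,curveB `survival_curve` objects.
#' @param tau Restriction time; default `min(max t_A, max t_B)`.
#' @return Difference in weeks (antisymmetric under group swap).
#' @export
delta_rmst <- function(curveA, curveB, tau = NULL) {
  if (is.null(tau)) tau <- min(max(curveA$time), max(curveB$time))
  rmst(curveA, tau) - rmst(curveB, tau)
}

#' Median split of DKO animals by final-draw abundance
#'
#' Takes each DKO animal's abundance at its last serum collection (largest
#' age), and splits at the median: animals at or below the median form the
#' low group, above it the high group.
#'
#' @param table A `feature_table`.
#' @param lifetimes Output of [annotate_lifetime()].
#' @param feature_id Feature to split on.
#' @return List with `low` and `high` animal-id vectors, the per-animal
#'   `abundance`, and `degenerate = TRUE` if all abundances are identical
#'   (everything falls in the low group).
#' @export
median_split <- function(table, lifetimes, feature_id) {
  stopifnot(inherits(table, "feature_table"))
  imp <- impute_missing(table)
  lt <- lifetimes[lifetimes$group == "DKO", , drop = FALSE]
  last_ids <- vapply(split(lt, lt$animal_id), function(d)
    d$sample_id[which.max(d$pct_lifetime)], character(1))
  abund <- imp$intensities[feature_id, last_ids]
  names(abund) <- names(last_ids)
  med <- stats::median(abund)
  low <- names(abund)[abund <= med]
  high <- names(abund)[abund > med]
  list(low = low, high = high, abundance = abund,
       degenerate = length(high) == 0)
}

#' Prognostic lipid screen
#'
#' For each candidate feature: median split of the DKO animals by
#' final-draw abundance, Kaplan-Meier curve per group, log-rank test; the
#' candidates with p < `alpha` are kept and ranked by |delta RMST|
#' descending.
#'
#' @param table A `feature_table`.
#' @param lifetimes Output of [annotate_lifetime()].
#' @param records [survival_records()] covering the DKO animals.
#' @param candidates Candidate feature ids.
#' @param alpha Log-rank significance level; default 0.05.
#' @return `data.frame`: `feature_id`, `logrank_p`, `delta_rmst` (low minus
#'   high group), `n_low`, `n_high`, ranked by |delta RMST|; attribute
#'   `"all"` holds the unfiltered screen.
#' @export
prognostic_screen <- function(table, lifetimes, records, candidates,
                              alpha = 0.05) {
  rows <- lapply(candidates, function(fid) {
    sp <- median_split(table, lifetimes, fid)
    if (sp$degenerate)
      return(data.frame(feature_id = fid, logrank_p = NA_real_,
                        delta_rmst = NA_real_, n_low = length(sp$low),
                        n_high = 0L))
    rec_low <- records[records$animal_id %in% sp$low, , drop = FALSE]
    rec_high <- records[records$animal_id %in% sp$high, , drop = FALSE]
    lr <- logrank_test(rec_low, rec_high)
    dr <- delta_rmst(km_estimate(rec_low), km_estimate(rec_high))
    data.frame(feature_id = fid, logrank_p = lr$p, delta_rmst = dr,
               n_low = nrow(rec_low), n_high = nrow(rec_high))
  })
  all <- do.call(rbind, rows)
  hit <- all[!is.na(all$logrank_p) & all$logrank_p < alpha, , drop = FALSE]
  hit <- hit[order(-abs(hit$delta_rmst)), , drop = FALSE]
  rownames(hit) <- NULL
  attr(hit, "all") <- all
  hit
}

#' Prognostic candidate set
#'
#' The union of (i) volcano-selected features (p < 0.05, |log2 FC| >= 1,
#' DKO stage I as reference vs stages II-V) recurring in at least
#' `min_sets` of the four comparisons, and (ii) features significant in at
#' least `min_sets` of the five DKO-vs-control stage tests.
#'
#' @param table A `feature_table`.
#' @param lifetimes Output of [annotate_lifetime()].
#' @param stage_sets Output of [stage_significance()].
#' @param min_sets Recurrence threshold; default 3.
#' @return Character vector of candidate ids; attributes `"volcano_sets"`
#'   and the two component sets.
#' @export
prognostic_candidates <- function(table, lifetimes, stage_sets,
                                  min_sets = 3) {
  dko <- lifetimes[lifetimes$group == "DKO", , drop = FALSE]
  ref_ids <- dko$sample_id[dko$stage == "I"]
  volcano_sets <- list()
  for (st in c("II", "III", "IV", "V")) {
    cmp_ids <- dko$sample_id[dko$stage == st]
    volcano_sets[[paste0("I vs ", st)]] <-
      as.character(volcano_select(table, ref_ids, cmp_ids))
  }
  from_volcano <- recurrent_features(volcano_sets, min_sets = min_sets)
  from_stages <- recurrent_features(stage_sets, min_sets = min_sets)
  out <- sort(union(from_volcano, from_stages))
  attr(out, "volcano_sets") <- volcano_sets
  attr(out, "from_volcano") <- from_volcano
  attr(out, "from_stages") <- from_stages
  out
}
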