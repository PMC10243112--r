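# Percentage-lifetime alignment. Animals die at different ages, so draws
# are placed on a common 0-100% lifetime axis and binned into five stages.

STAGE_LEVELS <- c("I", "II", "III", "IV", "V")
STAGE_BREAKS <- c(0, 30, 45, 60, 75, 100)

#' Percentage lifetime of a draw
#'
#' `100 * age_weeks / lifespan_weeks`, where lifespan is the animal's age at
#' its final blood collection (death or study end).
#'
#' @param age_weeks Age at the draw, weeks; must satisfy
#'   `0 < age_weeks <= lifespan_weeks`.
#' @param lifespan_weeks Lifespan (or censoring age), weeks, positive.
#' @return Percent in (0, 100]. Vectorized.
#' @export
pct_lifetime <- function(age_weeks, lifespan_weeks) {
  if (any(lifespan_weeks <= 0)) stop("lifespan_weeks must be positive")
  if (any(age_weeks <= 0)) stop("age_weeks must be positive")
  if (any(age_weeks > lifespan_weeks))
    stop("age_weeks exceeds lifespan_weeks")
  # guard the terminal draw against floating-point overshoot of 100
  pmin(100 * age_weeks / lifespan_weeks, 100)
}

#' Lifetime stage of a percentage lifetime
#'
#' Five half-open bins partition \[0, 100\]: \[0,30) I, \[30,45) II,
#' \[45,60) III, \[60,75) IV, \[75,100\] V. A shared boundary belongs to the
#' later stage (a draw at exactly 30% is stage II), making the map a
#' deterministic partition.
#'
#' @param pct Percent lifetime in \[0, 100\]. Vectorized.
#' @return Factor with levels `I`-`V`.
#' @export
assign_stage <- function(pct) {
  if (any(is.na(pct)) || any(pct < 0 | pct > 100))
    stop("pct must lie in [0, 100]")
  idx <- findInterval(pct, STAGE_BREAKS, rightmost.closed = TRUE)
  factor(STAGE_LEVELS[idx], levels = STAGE_LEVELS)
}

#' Annotate study samples with percentage lifetime and stage
#'
#' @param samples Sample metadata (`data.frame` with `sample_id`, `role`,
#'   `age_weeks`, `lifespan_weeks`), or a `feature_table`.
#' @return `data.frame` with `sample_id`, `pct_lifetime`, `stage` for study
#'   samples (QC/blank injections have no lifetime position).
#' @export
annotate_lifetime <- function(samples) {
  if (inherits(samples, "feature_table")) samples <- samples$samples
  study <- samples[samples$role == "study", , drop = FALSE]
  pct <- pct_lifetime(study$age_weeks, study$lifespan_weeks)
  data.frame(sample_id = study$sample_id,
             animal_id = study$animal_id,
             group = study$group,
             pct_lifetime = pct,
             stage = assign_stage(pct))
}
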