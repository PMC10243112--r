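# Synthetic longitudinal lipidomics cohorts with the statistical structure
# the analysis assumes: 15 + 15 animals drawn biweekly from week 8 until
# death or week 46, ~1000 log-normal lipid features, four trajectory
# archetypes (A-D) on top of a null background, QC/blank injections with
# smooth multiplicative instrument drift, and prognostic lipids whose
# final-draw abundance is coupled to lifespan. Ground truth is returned for
# recovery scoring.

# stage-wise log2 effect archetypes (DKO over control, stages I-V):
# A and B both rise into stage II, dip into III and spike at V; A is
# dominated by its stage-II peak and partially recovers at IV, B stays
# depressed through IV and is dominated by its stage-V spike. C rises,
# dips, rises again, then eases off. D is flat until a sharp stage-V
# increase. All start near zero at stage I (early disease is metabolically
# quiet, so per-stage significance counts grow toward stage V), and the
# shapes are mutually distinguishable under correlation distance (pairwise
# pattern r <= 0.77).
ARCHETYPE_EFFECTS <- rbind(
  A = c(0.1, 2.6, 0.6, 1.2, 1.4),
  B = c(0.0, 2.2, 0.1, 0.3, 3.0),
  C = c(0.1, 1.8, 0.6, 2.2, 0.8),
  D = c(0.0, 0.2, 0.1, 0.4, 2.6)
)
colnames(ARCHETYPE_EFFECTS) <- STAGE_LEVELS

#' Synthetic cohort configuration
#'
#' Defaults encode the study design: 15 DKO and 15 control mice, biweekly
#' serum draws from week 8 to death or the 46-week study end, about 1000
#' lipid features, a pooled QC injected every 10 runs, blank injections,
#' smooth multiplicative signal drift over injection order, and a handful
#' of prognostic lipids whose final-draw abundance tracks lifespan.
#'
#' @param n_dko,n_control Animals per group.
#' @param draw_start,draw_interval,study_end Draw schedule in weeks.
#' @param dko_shape,dko_scale Weibull lifespan distribution of DKO mice
#'   (mean about 35 weeks at the defaults); lifespans are resampled below
#'   `min_lifespan` so every animal's first draw falls in stage I.
#' @param control_shape,control_scale Control lifespan distribution (most
#'   controls outlive the study and are censored at `study_end`).
#' @param min_lifespan Lower truncation for simulated lifespans, weeks.
#' @param n_features Total features.
#' @param archetype_fracs Named fractions of features assigned to trajectory
#'   archetypes A-D (remainder is null background).
#' @param effect_scale_range Per-feature multiplier range applied to the
#'   archetype effect vector.
#' @param frac_background Fraction of features that are blank-dominated
#'   background signals (removed by the blank filter).
#' @param frac_unstable Fraction with unstable QC behaviour (RSD filter).
#' @param frac_qc_absent Fraction undetected in most QCs (presence filter).
#' @param n_prognostic Features whose final-draw abundance is coupled to
#'   lifespan.
#' @param prognostic_beta Coupling: final-draw log2 abundance gains
#'   `beta * standardized lifespan`.
#' @param sigma_log2 Log2-scale multiplicative measurement noise of study
#'   samples.
#' @param qc_sigma_log2 Log2 noise of QC injections (pooled material).
#' @param baseline_log2_range Per-feature baseline log2 peak-area range.
#' @param qc_every QC injection spacing; `n_blank` blank injections.
#' @param drift_amplitude Amplitude of the smooth multiplicative drift.
#' @param miss_frac Fraction of study cells set missing at random.
#' @param seed Integer seed.
#' @return A config list for [simulate_cohort()].
#' @export
cohort_config <- function(n_dko = 15, n_control = 15,
                          draw_start = 8, draw_interval = 2, study_end = 46,
                          dko_shape = 6, dko_scale = 38,
                          control_shape = 6, control_scale = 52,
                          min_lifespan = 27,
                          n_features = 1000,
                          archetype_fracs = c(A = 0.02, B = 0.01,
                                              C = 0.02, D = 0.03),
                          effect_scale_range = c(0.8, 1.2),
                          frac_background = 0.02,
                          frac_unstable = 0.02,
                          frac_qc_absent = 0.01,
                          n_prognostic = 5,
                          prognostic_beta = 1.5,
                          sigma_log2 = 0.5,
                          qc_sigma_log2 = 0.1,
                          baseline_log2_range = c(13, 27),
                          qc_every = 10, n_blank = 3,
                          drift_amplitude = 0.15,
                          miss_frac = 0.02,
                          seed = 1) {
  cfg <- as.list(environment())
  if (sum(archetype_fracs) + frac_background + frac_unstable +
      frac_qc_absent > 1)
    stop("feature fractions sum to more than 1")
  if (dko_scale <= 0 || control_scale <= 0 || min_lifespan <= 0)
    stop("lifespan parameters must be positive")
  cfg
}

rtrunc_weibull <- function(n, shape, scale, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rweibull(n, shape, scale)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

#' Simulate a longitudinal lipidomics cohort
#'
#' @param config A [cohort_config()] list.
#' @return List with `table` (a [feature_table()] including QC and blank
#'   injections), `records` ([survival_records()] for all animals), and
#'   `truth`: feature `kind` (archetype letter, `null`, `background`,
#'   `unstable`, `qc_absent`), the per-feature x stage log2 `effects`
#'   matrix, `prognostic` ids and the per-animal lifespans.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- config
  set.seed(cfg$seed)

  ## animals and draw schedules
  dko_life <- pmin(rtrunc_weibull(cfg$n_dko, cfg$dko_shape, cfg$dko_scale,
                                  cfg$min_lifespan), cfg$study_end)
  ctl_life <- pmin(rtrunc_weibull(cfg$n_control, cfg$control_shape,
                                  cfg$control_scale, cfg$min_lifespan),
                   cfg$study_end)
  if (all(dko_life <= 0)) stop("infeasible config: zero lifespans")
  animals <- data.frame(
    animal_id = c(sprintf("DKO%02d", seq_len(cfg$n_dko)),
                  sprintf("CTL%02d", seq_len(cfg$n_control))),
    group = rep(c("DKO", "control"), c(cfg$n_dko, cfg$n_control)),
    lifespan = c(dko_life, ctl_life))
  animals$event <- animals$lifespan < cfg$study_end

  draws <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    a <- animals[i, ]
    ages <- seq(cfg$draw_start, a$lifespan, by = cfg$draw_interval)
    ages <- sort(unique(c(ages, a$lifespan)))  # terminal draw at death
    data.frame(animal_id = a$animal_id, group = a$group, age_weeks = ages,
               lifespan_weeks = a$lifespan, event_observed = a$event,
               draw = seq_along(ages))
  }))
  draws$sample_id <- sprintf("%s_d%02d", draws$animal_id, draws$draw)
  draws$pct <- pmin(100 * draws$age_weeks / draws$lifespan_weeks, 100)
  draws$stage <- assign_stage(draws$pct)

  ## feature universe and kinds
  nf <- cfg$n_features
  n_arch <- round(cfg$archetype_fracs * nf)
  n_bg <- round(cfg$frac_background * nf)
  n_un <- round(cfg$frac_unstable * nf)
  n_ab <- round(cfg$frac_qc_absent * nf)
  kind <- c(rep(names(n_arch), n_arch),
            rep("background", n_bg), rep("unstable", n_un),
            rep("qc_absent", n_ab))
  kind <- c(kind, rep("null", nf - length(kind)))
  feature_id <- sprintf("F%04d", seq_len(nf))
  names(kind) <- feature_id

  baseline <- stats::runif(nf, cfg$baseline_log2_range[1],
                           cfg$baseline_log2_range[2])
  effects <- matrix(0, nf, 5, dimnames = list(feature_id, STAGE_LEVELS))
  for (arch in rownames(ARCHETYPE_EFFECTS)) {
    rows <- which(kind == arch)
    if (!length(rows)) next
    amp <- stats::runif(length(rows), cfg$effect_scale_range[1],
                        cfg$effect_scale_range[2])
    effects[rows, ] <- outer(amp, ARCHETYPE_EFFECTS[arch, ])
  }
  # prognostic lipids must be discoverable by the candidate screen, which
  # admits only stage-differential features; archetype-A members recur in
  # enough stage comparisons to qualify, so couple those to lifespan (fall
  # back to null features when no archetypes are simulated)
  prog_pool <- c(feature_id[kind == "A"], feature_id[kind == "null"])
  prognostic <- utils::head(prog_pool, cfg$n_prognostic)

  ## injection sequence: randomized study order, QC every qc_every runs,
  ## blanks distributed across the run
  ns <- nrow(draws)
  study_order <- sample(ns)
  n_qc <- max(4L, floor(ns / cfg$qc_every))
  inj <- character(0)
  qi <- 0L
  for (i in seq_len(ns)) {
    if ((i - 1) %% cfg$qc_every == 0 && qi < n_qc) {
      qi <- qi + 1L
      inj <- c(inj, sprintf("QC%03d", qi))
    }
    inj <- c(inj, draws$sample_id[study_order[i]])
  }
  while (qi < n_qc) { qi <- qi + 1L; inj <- c(inj, sprintf("QC%03d", qi)) }
  blank_ids <- sprintf("BLANK%02d", seq_len(cfg$n_blank))
  blank_pos <- round(seq(1, length(inj), length.out = cfg$n_blank))
  for (b in seq_len(cfg$n_blank))
    inj <- append(inj, blank_ids[b], after = blank_pos[b] + b - 1L)
  injection_order <- stats::setNames(seq_along(inj), inj)

  n_inj <- length(inj)
  drift <- 1 + cfg$drift_amplitude *
    sin(pi * (seq_len(n_inj) - 1) / (n_inj - 1))

  ## intensity matrix
  all_ids <- inj
  m <- matrix(NA_real_, nf, n_inj, dimnames = list(feature_id, all_ids))
  is_qc <- startsWith(all_ids, "QC")
  is_blank <- startsWith(all_ids, "BLANK")
  stage_of <- stats::setNames(as.character(draws$stage), draws$sample_id)
  group_of <- stats::setNames(draws$group, draws$sample_id)
  life_z <- stats::setNames(
    (animals$lifespan - mean(animals$lifespan[animals$group == "DKO"])) /
      stats::sd(animals$lifespan[animals$group == "DKO"]),
    animals$animal_id)
  last_draw <- vapply(split(draws, draws$animal_id), function(d)
    d$sample_id[which.max(d$age_weeks)], character(1))

  for (j in seq_len(n_inj)) {
    id <- all_ids[j]
    if (is_blank[j]) {
      lvl <- ifelse(kind == "background", baseline - 1, baseline - 8)
      m[, j] <- 2^(lvl + stats::rnorm(nf, 0, cfg$qc_sigma_log2)) * drift[j]
    } else if (is_qc[j]) {
      sd_qc <- ifelse(kind == "unstable", 0.6, cfg$qc_sigma_log2)
      v <- 2^(baseline + stats::rnorm(nf, 0, sd_qc)) * drift[j]
      if (any(kind == "qc_absent")) {
        # detected in well under half of the QC injections
        absent <- kind == "qc_absent" & stats::runif(nf) < 0.8
        v[absent] <- NA_real_
      }
      m[, j] <- v
    } else {
      eff <- if (group_of[id] == "DKO") effects[, stage_of[id]] else 0
      lv <- baseline + eff + stats::rnorm(nf, 0, cfg$sigma_log2)
      aid <- draws$animal_id[draws$sample_id == id]
      if (id == last_draw[[aid]] && group_of[id] == "DKO")
        lv[match(prognostic, feature_id)] <-
          lv[match(prognostic, feature_id)] +
          cfg$prognostic_beta * life_z[[aid]]
      v <- 2^lv * drift[j]
      v[stats::runif(nf) < cfg$miss_frac] <- NA_real_
      m[, j] <- v
    }
  }

  ## metadata tables
  samples <- data.frame(sample_id = all_ids,
                        animal_id = NA_character_,
                        group = NA_character_,
                        role = ifelse(is_qc, "qc",
                                      ifelse(is_blank, "blank", "study")),
                        age_weeks = NA_real_, lifespan_weeks = NA_real_,
                        injection_order = unname(injection_order[all_ids]),
                        event_observed = NA)
  si <- match(draws$sample_id, samples$sample_id)
  samples$animal_id[si] <- draws$animal_id
  samples$group[si] <- draws$group
  samples$age_weeks[si] <- draws$age_weeks
  samples$lifespan_weeks[si] <- draws$lifespan_weeks
  samples$event_observed[si] <- draws$event_observed

  annotations <- data.frame(
    feature_id = feature_id,
    lipid_name = sprintf("synthetic-lipid-%04d", seq_len(nf)),
    adduct = "[M-H]-",
    rt_min = round(stats::runif(nf, 0.5, 9.5), 2),
    mz = round(stats::runif(nf, 150, 1200), 4),
    ion_mode = "negative",
    confidence_level = 3L)

  table <- feature_table(m, annotations, samples)
  records <- survival_records(animals$animal_id, animals$lifespan,
                              animals$event)
  truth <- list(kind = kind, effects = effects, prognostic = prognostic,
                lifespans = stats::setNames(animals$lifespan,
                                            animals$animal_id))
  list(table = table, records = records, truth = truth, config = cfg)
}

#' Score pipeline outputs against simulation ground truth
#'
#' @param truth The `truth` element of [simulate_cohort()].
#' @param stage_sets Optional [stage_significance()] output; scored per
#'   stage as sensitivity/FDR against features whose injected |log2 effect|
#'   at that stage is at least `min_effect`.
#' @param cluster_labels Optional named cluster labels over archetype
#'   features; scored by adjusted Rand index against the archetype letters.
#' @param selected Optional selected-feature set (any stage); scored as
#'   sensitivity against features with |effect| >= `min_effect` at
#'   `selected_stage`.
#' @param prognostic_hits Optional retained prognostic feature ids; scored
#'   as recall of the injected prognostic set.
#' @param min_effect Truth threshold on |log2 effect|; default 0.5.
#' @param selected_stage Stage for scoring `selected`; default `"V"`.
#' @return List of recovery metrics (only those whose inputs were given).
#' @export
truth_report <- function(truth, stage_sets = NULL, cluster_labels = NULL,
                         selected = NULL, prognostic_hits = NULL,
                         min_effect = 0.5, selected_stage = "V") {
  universe <- names(truth$kind)
  out <- list()
  if (!is.null(stage_sets)) {
    per_stage <- lapply(seq_along(STAGE_LEVELS), function(k) {
      st <- STAGE_LEVELS[k]
      found <- stage_sets[[paste0("stage ", st)]]
      if (any(!found %in% universe))
        stop("stage set contains features outside the truth universe")
      pos <- universe[abs(truth$effects[, st]) >= min_effect]
      tp <- length(intersect(found, pos))
      c(sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
        fdr = if (length(found)) 1 - tp / length(found) else 0)
    })
    names(per_stage) <- STAGE_LEVELS
    out$differential <- per_stage
  }
  if (!is.null(cluster_labels)) {
    ids <- names(cluster_labels)
    if (any(!ids %in% universe))
      stop("cluster labels contain features outside the truth universe")
    ref <- truth$kind[ids]
    out$clustering_ari <- mclust::adjustedRandIndex(cluster_labels, ref)
  }
  if (!is.null(selected)) {
    if (any(!selected %in% universe))
      stop("selected set contains features outside the truth universe")
    pos <- universe[abs(truth$effects[, selected_stage]) >= min_effect]
    out$selection_sensitivity <-
      if (length(pos)) length(intersect(selected, pos)) / length(pos)
      else NA_real_
  }
  if (!is.null(prognostic_hits)) {
    if (any(!prognostic_hits %in% universe))
      stop("prognostic hits contain features outside the truth universe")
    out$prognostic_recall <-
      length(intersect(prognostic_hits, truth$prognostic)) /
      length(truth$prognostic)
  }
  out
}
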