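# End-to-end orchestration: curation -> lifetime alignment -> differential
# statistics -> trajectory clustering -> per-stage classification ->
# prognostic survival screen, with every published constant surfaced as a
# named parameter and a manifest recording seeds, parameters and counts.

#' Pipeline configuration
#'
#' All thresholds default to the study's values: blank 5x, QC presence
#' 50%, QC RSD 30%, alpha 0.05, global BH q < 0.05, volcano |log2 FC| >= 1,
#' correlation pruning r > 0.8, 100-tree forests, SVM C = 1, 5 neighbors,
#' 70/30 split, 4 trajectory clusters, network r >= 0.5, 1000 permutations.
#'
#' @param simulate A [cohort_config()] list to generate the cohort, or
#'   `NULL` to read `input_dir`.
#' @param input_dir Directory holding `intensities.csv`, `features.csv`,
#'   `samples.csv` when `simulate` is `NULL`.
#' @param blank_fold,qc_presence,qc_rsd,drift_correct Curation settings.
#' @param alpha Significance level for all univariate tests.
#' @param q_threshold BH q threshold for the global contrast.
#' @param volcano_min_fc Volcano |log2 FC| threshold.
#' @param k_clusters Trajectory cluster count.
#' @param network_r Correlation-network edge threshold.
#' @param ml_stages Stages to classify (default all five).
#' @param ml_leakage Publication-faithful selection leakage flag.
#' @param ml_group_by_animal Split train/test by animal instead of sample.
#' @param ml_permutation Model to permutation-validate per stage, or `NULL`.
#' @param n_permutations Label permutations when validating.
#' @param seed Integer seed for split/forest/permutation randomness.
#' @return Config list for [run_lipidome_pipeline()].
#' @export
pipeline_config <- function(simulate = cohort_config(), input_dir = NULL,
                            blank_fold = 5, qc_presence = 0.5, qc_rsd = 30,
                            drift_correct = TRUE, alpha = 0.05,
                            q_threshold = 0.05, volcano_min_fc = 1,
                            k_clusters = 4, network_r = 0.5,
                            ml_stages = STAGE_LEVELS, ml_leakage = TRUE,
                            ml_group_by_animal = FALSE,
                            ml_permutation = NULL, n_permutations = 1000,
                            seed = 1) {
  if (is.null(simulate) && is.null(input_dir))
    stop("either a simulate block or an input_dir is required")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  as.list(environment())
}

#' Run the full lipidome time-course pipeline
#'
#' Executes curation, lifetime alignment, global and stage-resolved
#' differential statistics, trajectory clustering and networks, per-stage
#' classification, and the prognostic survival screen; optionally writes
#' all per-module files plus a manifest to `out_dir`.
#'
#' @param config A [pipeline_config()] list.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Object of class `lipidome_run`: all module outputs plus a
#'   `manifest` whose counts are recomputable from the emitted files.
#' @export
run_lipidome_pipeline <- function(config = pipeline_config(),
                                  out_dir = NULL) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    sim <- step("simulate", simulate_cohort(config$simulate))
    raw <- sim$table; records <- sim$records; truth <- sim$truth
  } else {
    raw <- step("ingest", read_feature_table(
      file.path(config$input_dir, "intensities.csv"),
      file.path(config$input_dir, "features.csv"),
      file.path(config$input_dir, "samples.csv")))
    st <- raw$samples[raw$samples$role == "study", , drop = FALSE]
    per_animal <- st[!duplicated(st$animal_id), , drop = FALSE]
    records <- survival_records(per_animal$animal_id,
                                per_animal$lifespan_weeks,
                                per_animal$event_observed)
    truth <- NULL
  }

  cur <- step("ingest_qc", curate_features(
    raw, blank_fold = config$blank_fold, qc_presence = config$qc_presence,
    qc_rsd = config$qc_rsd, drift_correct = config$drift_correct))
  table <- subset_features(cur$table,
                           samples = cur$table$samples$role == "study")

  lifetimes <- step("lifetime", annotate_lifetime(table))

  global <- step("differential", global_differential(table))
  sig_global <- global$feature_id[global$q < config$q_threshold]
  stage_sets <- step("differential",
                     stage_significance(table, lifetimes,
                                        alpha = config$alpha))
  upset <- exclusive_intersections(stage_sets)
  recurrent <- recurrent_features(stage_sets, min_sets = 3)

  traj <- NULL; clusters <- NULL; network <- NULL
  if (length(sig_global) >= config$k_clusters) {
    traj <- step("trajectory",
                 build_trajectories(table, lifetimes, sig_global))
    clusters <- step("trajectory", hca_complete(traj, k = config$k_clusters))
    network <- step("trajectory",
                    correlation_network(traj, clusters$labels,
                                        r_threshold = config$network_r))
  }

  ml <- step("stagewise_ml", lapply(
    stats::setNames(config$ml_stages, config$ml_stages),
    function(st) classify_stage(table, lifetimes, st, seed = config$seed,
                                leakage = config$ml_leakage,
                                group_by_animal = config$ml_group_by_animal,
                                permutation = config$ml_permutation,
                                n_permutations = config$n_permutations)))

  candidates <- step("survival",
                     prognostic_candidates(table, lifetimes, stage_sets))
  dko_records <- records[records$animal_id %in%
                           lifetimes$animal_id[lifetimes$group == "DKO"], ]
  prognostic <- if (length(candidates))
    step("survival", prognostic_screen(table, lifetimes, dko_records,
                                       candidates, alpha = config$alpha))
  else data.frame(feature_id = character(0), logrank_p = numeric(0),
                  delta_rmst = numeric(0), n_low = integer(0),
                  n_high = integer(0))

  manifest <- list(
    seed = config$seed,
    parameters = config[c("blank_fold", "qc_presence", "qc_rsd", "alpha",
                          "q_threshold", "volcano_min_fc", "k_clusters",
                          "network_r", "ml_leakage", "n_permutations")],
    n_features_raw = nrow(raw$intensities),
    n_features_curated = nrow(table$intensities),
    n_removed_by_step = as.list(table(cur$report$step)),
    n_study_samples = ncol(table$intensities),
    n_global_significant = length(sig_global),
    n_stage_significant = lapply(stage_sets, length),
    n_recurrent = length(recurrent),
    cluster_sizes = if (is.null(clusters)) NULL
                    else as.list(clusters$order_k),
    ml_auc = lapply(ml, function(m)
      if (is.null(m$evals)) NULL else lapply(m$evals, `[[`, "auc")),
    n_prognostic_candidates = length(candidates),
    n_prognostic_hits = nrow(prognostic))

  run <- structure(list(
    table = table, lifetimes = lifetimes, global = global,
    stage_sets = stage_sets, upset = upset, recurrent = recurrent,
    trajectories = traj, clusters = clusters, network = network,
    ml = ml, candidates = candidates, prognostic = prognostic,
    records = records, truth = truth, curation = cur$report,
    manifest = manifest, config = config), class = "lipidome_run")

  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' @export
print.lipidome_run <- function(x, ...) {
  m <- x$manifest
  cat("lipidome time-course run\n")
  cat("  features: ", m$n_features_raw, " raw -> ", m$n_features_curated,
      " curated; study samples: ", m$n_study_samples, "\n", sep = "")
  cat("  global q<", x$config$q_threshold, " lipids: ",
      m$n_global_significant, "\n", sep = "")
  cat("  per-stage significant (I-V):",
      paste(unlist(m$n_stage_significant), collapse = "/"), "\n")
  cat("  recurrent (>=3 stages):", m$n_recurrent, "\n")
  if (!is.null(m$cluster_sizes))
    cat("  trajectory clusters:",
        paste(names(m$cluster_sizes), unlist(m$cluster_sizes),
              sep = "=", collapse = ", "), "\n")
  for (st in names(m$ml_auc))
    if (!is.null(m$ml_auc[[st]]))
      cat("  stage ", st, " test AUC: ",
          paste(names(m$ml_auc[[st]]),
                sprintf("%.2f", unlist(m$ml_auc[[st]])),
                sep = "=", collapse = ", "), "\n", sep = "")
  cat("  prognostic candidates:", m$n_prognostic_candidates,
      "-> hits:", m$n_prognostic_hits, "\n")
  invisible(x)
}

#' @export
summary.lipidome_run <- function(object, ...) {
  print(object)
  if (nrow(object$prognostic)) {
    cat("\nprognostic lipids (log-rank p < ", object$config$alpha,
        ", ranked by |delta RMST|):\n", sep = "")
    print(object$prognostic, row.names = FALSE)
  }
  invisible(object$manifest)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$lifetimes, file.path(out_dir, "lifetime.csv"),
                   row.names = FALSE)
  utils::write.csv(run$global, file.path(out_dir, "differential.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$stage_sets, file.path(out_dir, "sets.json"))
  upset_counts <- data.frame(pattern = names(run$upset),
                             count = lengths(run$upset))
  utils::write.csv(upset_counts, file.path(out_dir, "upset.csv"),
                   row.names = FALSE)
  if (!is.null(run$clusters)) {
    utils::write.csv(data.frame(feature_id = names(run$clusters$labels),
                                cluster = unname(run$clusters$labels)),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    jsonlite::write_json(list(merge = run$clusters$merge,
                              height = run$clusters$height),
                         file.path(out_dir, "dendrogram.json"))
    jsonlite::write_json(run$network, file.path(out_dir, "network.json"),
                         dataframe = "rows")
  }
  for (st in names(run$ml)) {
    m <- run$ml[[st]]
    jsonlite::write_json(
      m$selection[c("stage", "survivors_p_filter", "survivors_corr_prune",
                    "gini_importances", "selected")],
      file.path(out_dir, sprintf("selection_stage%s.json", st)),
      auto_unbox = TRUE)
    if (!is.null(m$evals)) {
      jsonlite::write_json(
        lapply(m$evals, function(e)
          list(auc = e$auc, cv_scores = e$cv_scores)),
        file.path(out_dir, sprintf("eval_stage%s.json", st)),
        auto_unbox = TRUE)
      roc <- do.call(rbind, lapply(names(m$evals), function(nm)
        cbind(model = nm, m$evals[[nm]]$roc_points)))
      utils::write.csv(roc,
                       file.path(out_dir, sprintf("roc_stage%s.csv", st)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(data.frame(animal_id = run$records$animal_id,
                              time_weeks = run$records$time,
                              event = run$records$event),
                   file.path(out_dir, "survival.csv"), row.names = FALSE)
  utils::write.csv(run$prognostic, file.path(out_dir, "prognostic.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
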