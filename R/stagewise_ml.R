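# Per-stage DKO vs control classification: Welch p-filter -> correlation
# pruning -> random-forest Gini importance selection, then five classifiers
# (logistic, 100-tree random forest, RBF SVM with C = 1, 5-NN, soft voting)
# evaluated by ROC-AUC with 5-fold CV and a label-permutation test.
#
# The selection cascade deliberately reproduces the published ordering, in
# which the p-filter and correlation pruning see all stage samples before
# the 70/30 split (information leakage into the test set); `leakage = FALSE`
# restricts every selection step to the training portion instead.

#' Feature-selection cascade for one lifetime stage
#'
#' Within the stage: (1) keep features with Welch p < `alpha` (DKO vs
#' control); (2) greedy correlation pruning — scanning survivors in
#' ascending-p order, drop any feature with Pearson r > `r_prune` against an
#' already-kept one; (3) autoscale the training portion and fit a 100-tree
#' random forest; (4) keep features whose normalized Gini importance is at
#' least the mean importance.
#'
#' @param table A `feature_table`.
#' @param lifetimes Output of [annotate_lifetime()].
#' @param stage Stage label `"I"`..`"V"`.
#' @param seed Integer seed (split and forest).
#' @param alpha Welch p threshold; default 0.05.
#' @param r_prune Correlation-pruning threshold; default 0.8.
#' @param train_fraction Training share for the split; default 0.7.
#' @param leakage If `TRUE` (default, publication-faithful) the p-filter and
#'   pruning use all stage samples; if `FALSE`, training samples only.
#' @param group_by_animal Split train/test by animal instead of by sample,
#'   so repeated draws from one mouse stay on one side; default `FALSE`
#'   (publication-faithful).
#' @return List: `stage`, `survivors_p_filter`, `survivors_corr_prune`,
#'   `gini_importances` (normalized to sum 1), `selected`, `train_ids`,
#'   `test_ids`, `empty` flag.
#' @export
select_features <- function(table, lifetimes, stage, seed, alpha = 0.05,
                            r_prune = 0.8, train_fraction = 0.7,
                            leakage = TRUE, group_by_animal = FALSE) {
  stopifnot(inherits(table, "feature_table"), stage %in% STAGE_LEVELS)
  sel <- lifetimes[lifetimes$stage == stage, , drop = FALSE]
  labels <- stats::setNames(sel$group, sel$sample_id)
  split <- split_train_test(sel$sample_id, labels,
                            train_fraction = train_fraction, seed = seed,
                            animals = if (group_by_animal)
                              stats::setNames(sel$animal_id, sel$sample_id))
  imp <- impute_missing(subset_features(table, samples = sel$sample_id))

  stat_ids <- if (leakage) sel$sample_id else split$train
  a_ids <- intersect(stat_ids, sel$sample_id[sel$group == "DKO"])
  b_ids <- intersect(stat_ids, sel$sample_id[sel$group == "control"])
  if (length(a_ids) < 2 || length(b_ids) < 2)
    stop("stage ", stage, " has fewer than 2 samples per group")
  wt <- welch_test_rows(imp$intensities,
                        match(a_ids, imp$samples$sample_id),
                        match(b_ids, imp$samples$sample_id))
  pvals <- stats::setNames(wt[, "p"], imp$annotations$feature_id)
  surv_p <- names(pvals)[pvals < alpha]

  empty_result <- function(stage, surv_p, surv_r) {
    list(stage = stage, survivors_p_filter = surv_p,
         survivors_corr_prune = surv_r,
         gini_importances = stats::setNames(numeric(0), character(0)),
         selected = character(0), train_ids = split$train,
         test_ids = split$test, empty = TRUE)
  }
  if (length(surv_p) == 0) return(empty_result(stage, surv_p, character(0)))

  # greedy pruning: ascending p, keep the lower-p member of each r>0.8 pair
  ord <- surv_p[order(pvals[surv_p])]
  x_stat <- t(imp$intensities[ord, stat_ids, drop = FALSE])
  kept <- character(0)
  for (f in ord) {
    if (length(kept) == 0) { kept <- f; next }
    r <- suppressWarnings(stats::cor(x_stat[, f],
                                     x_stat[, kept, drop = FALSE]))
    r[is.na(r)] <- 0
    if (all(r <= r_prune)) kept <- c(kept, f)
  }
  surv_r <- kept

  train_x <- autoscale(t(imp$intensities[surv_r, split$train, drop = FALSE]))
  train_y <- factor(labels[split$train], levels = c("control", "DKO"))
  set.seed(seed)
  rf <- randomForest::randomForest(x = train_x, y = train_y, ntree = 100)
  gini <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  total <- sum(gini)
  gini <- if (total > 0) gini / total else gini
  selected <- names(gini)[gini >= mean(gini)]

  list(stage = stage, survivors_p_filter = surv_p,
       survivors_corr_prune = surv_r, gini_importances = gini,
       selected = selected, train_ids = split$train, test_ids = split$test,
       empty = length(selected) == 0)
}

#' Stratified train/test split
#'
#' Splits samples into disjoint train and test sets, stratified by class
#' label, reproducibly under `seed`. When `animals` is supplied the split
#' is performed over animals instead, so repeated draws from one mouse
#' never straddle the train/test boundary.
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels Class labels, named by or aligned with `sample_ids`.
#' @param train_fraction Training share; default 0.7.
#' @param seed Integer seed.
#' @param animals Optional animal ids, named by or aligned with
#'   `sample_ids`, to split by animal rather than by sample.
#' @return List with `train` and `test` id vectors.
#' @export
split_train_test <- function(sample_ids, labels, train_fraction = 0.7, seed,
                             animals = NULL) {
  if (!is.null(names(labels))) labels <- labels[sample_ids]
  if (anyNA(labels)) stop("every sample needs a class label")
  if (!is.null(animals)) {
    if (!is.null(names(animals))) animals <- animals[sample_ids]
    uniq <- !duplicated(animals)
    sp <- split_train_test(animals[uniq], stats::setNames(labels[uniq],
                                                          animals[uniq]),
                           train_fraction = train_fraction, seed = seed)
    return(list(train = sample_ids[animals %in% sp$train],
                test = sample_ids[animals %in% sp$test]))
  }
  classes <- split(sample_ids, labels)
  if (any(lengths(classes) < 2))
    stop("every class needs >= 2 samples to split")
  set.seed(seed)
  train <- unlist(lapply(classes, function(ids) {
    n_tr <- round(train_fraction * length(ids))
    n_tr <- max(1L, min(length(ids) - 1L, n_tr))
    sample(ids, n_tr)
  }), use.names = FALSE)
  list(train = train, test = setdiff(sample_ids, train))
}

#' Train the five stage classifiers
#'
#' Logistic regression (sigmoid probability, 0.5 threshold), 100-tree
#' random forest with Gini splits, RBF-kernel SVM with `C = 1` and
#' probability outputs (kernel coefficient gamma = 1/(d * mean feature
#' variance), recorded in the result), 5-nearest-neighbors with uniform
#' weights, and a soft-voting ensemble whose probability is the arithmetic
#' mean of the four members' probabilities.
#'
#' @param train_x Autoscaled numeric matrix (samples x features).
#' @param train_y Factor with levels `control`, `DKO`.
#' @param seed Integer seed (forest bootstrap).
#' @return Object of class `stage_models`; use [predict_prob()] for P(DKO).
#' @export
train_models <- function(train_x, train_y, seed) {
  train_x <- as.matrix(train_x)
  train_y <- factor(train_y, levels = c("control", "DKO"))
  if (nlevels(droplevels(train_y)) < 2)
    stop("training data must contain both classes")
  df <- data.frame(.y = train_y, train_x, check.names = FALSE)
  logit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  set.seed(seed)
  rf <- randomForest::randomForest(x = train_x, y = train_y, ntree = 100)
  gamma <- 1 / (ncol(train_x) * max(mean(apply(train_x, 2, stats::var)),
                                    .Machine$double.eps))
  svm <- e1071::svm(x = train_x, y = train_y, kernel = "radial", cost = 1,
                    gamma = gamma, probability = TRUE)
  structure(list(logistic = logit, random_forest = rf, svm_rbf = svm,
                 knn_k = 5L, train_x = train_x, train_y = train_y,
                 gamma = gamma, seed = seed),
            class = "stage_models")
}

MODEL_NAMES <- c("logistic", "random_forest", "knn", "svm_rbf", "voting")

#' Predicted probability of the DKO class
#'
#' @param models A `stage_models` object from [train_models()].
#' @param newdata Matrix of samples x features on the training scale.
#' @param model One of `"logistic"`, `"random_forest"`, `"knn"`,
#'   `"svm_rbf"`, `"voting"`.
#' @return Numeric vector of P(DKO) per sample.
#' @export
predict_prob <- function(models, newdata, model = "voting") {
  stopifnot(inherits(models, "stage_models"), model %in% MODEL_NAMES)
  newdata <- as.matrix(newdata)
  nd <- as.data.frame(newdata, check.names = FALSE)
  p <- switch(model,
    logistic = unname(stats::predict(models$logistic, newdata = nd,
                                     type = "response")),
    random_forest = unname(stats::predict(models$random_forest,
                                          newdata = newdata,
                                          type = "prob")[, "DKO"]),
    svm_rbf = {
      pr <- stats::predict(models$svm_rbf, newdata = newdata,
                           probability = TRUE)
      unname(attr(pr, "probabilities")[, "DKO"])
    },
    knn = {
      kn <- class::knn(train = models$train_x, test = newdata,
                       cl = models$train_y, k = models$knn_k, prob = TRUE)
      win <- attr(kn, "prob")
      ifelse(kn == "DKO", win, 1 - win)
    },
    voting = {
      member <- vapply(c("logistic", "random_forest", "knn", "svm_rbf"),
                       function(mm) predict_prob(models, newdata, mm),
                       numeric(nrow(newdata)))
      rowMeans(member)
    })
  as.numeric(p)
}

#' ROC curve and trapezoidal AUC
#'
#' Enumerates all score thresholds: the curve steps from (0,0) to (1,1)
#' through the (FPR, TPR) points obtained by classifying scores above each
#' threshold as DKO; the AUC is the trapezoidal area under those points.
#'
#' @param scores Numeric scores (higher = more DKO-like).
#' @param labels Factor/character with both classes present (`DKO`
#'   positive).
#' @return List with `roc_points` (data frame FPR, TPR) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- labels == "DKO"
  if (!any(y) || all(y)) stop("both classes required to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(!y) / sum(!y))
  # collapse tied scores to the last point of each tie run
  s <- scores[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)
  roc <- data.frame(FPR = c(0, fpr[-1][keep]), TPR = c(0, tpr[-1][keep]))
  auc <- sum(diff(roc$FPR) * (utils::head(roc$TPR, -1) + utils::tail(roc$TPR, -1)) / 2)
  list(roc_points = roc, auc = auc)
}

#' Evaluate a trained model on a held-out test set
#'
#' ROC-AUC on the test samples plus 5-fold cross-validated accuracy on the
#' training data.
#'
#' @param models `stage_models` object.
#' @param model Model name (see [predict_prob()]).
#' @param test_x,test_y Held-out samples (training scale) and labels; both
#'   classes must be present.
#' @param cv_folds Folds for the training-set CV accuracy; default 5.
#' @param seed Integer seed (fold assignment and refits).
#' @return List with `model`, `roc_points`, `auc`, `cv_scores`.
#' @export
evaluate_roc <- function(models, model, test_x, test_y, cv_folds = 5,
                         seed = 1) {
  test_y <- factor(test_y, levels = c("control", "DKO"))
  if (nlevels(droplevels(test_y)) < 2)
    stop("test set must contain both classes")
  scores <- predict_prob(models, test_x, model)
  roc <- roc_auc(scores, test_y)
  cv <- cv_accuracy(models$train_x, models$train_y, model, folds = cv_folds,
                    seed = seed)
  list(model = model, roc_points = roc$roc_points, auc = roc$auc,
       cv_scores = cv)
}

# stratified k-fold cross-validated accuracy of one model spec
cv_accuracy <- function(x, y, model, folds = 5, seed = 1, shuffle_seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("control", "DKO"))
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- train_models(x[tr, , drop = FALSE], y[tr], seed = seed + f)
    p <- predict_prob(fit, x[!tr, , drop = FALSE], model)
    mean((p >= 0.5) == (y[!tr] == "DKO"))
  }, numeric(1))
}

#' Label-permutation validation of a classifier
#'
#' Cross-validated accuracy on the true labels, compared with a null
#' distribution of accuracies obtained on `n_permutations` random label
#' permutations (features unchanged). The empirical p-value is
#' `(#{perm >= true} + 1) / (n_permutations + 1)`, so its floor at
#' `n_permutations = 1000` is 1/1001.
#'
#' @param x Autoscaled matrix (samples x features).
#' @param y Labels (`control`/`DKO`).
#' @param model Model name (see [predict_prob()]).
#' @param n_permutations Number of label permutations; default 1000.
#' @param cv_folds CV folds; default 5.
#' @param seed Integer seed.
#' @return List with `accuracy`, `null_accuracies`, `p_value`.
#' @export
permutation_validate <- function(x, y, model = "logistic",
                                 n_permutations = 1000, cv_folds = 5, seed) {
  stopifnot(n_permutations >= 1)
  y <- factor(y, levels = c("control", "DKO"))
  true_acc <- mean(cv_accuracy(x, y, model, folds = cv_folds, seed = seed))
  set.seed(seed + 1L)
  perms <- replicate(n_permutations, sample(seq_along(y)))
  null_acc <- vapply(seq_len(n_permutations), function(i) {
    mean(cv_accuracy(x, y[perms[, i]], model, folds = cv_folds, seed = seed))
  }, numeric(1))
  list(accuracy = true_acc, null_accuracies = null_acc,
       p_value = (sum(null_acc >= true_acc) + 1) / (n_permutations + 1))
}

#' Full per-stage classification run
#'
#' Feature selection, training of the five classifiers on the 70% training
#' split, ROC-AUC on the 30% test split, and optional permutation
#' validation of a chosen model.
#'
#' @param table A `feature_table`.
#' @param lifetimes Output of [annotate_lifetime()].
#' @param stage Stage label `"I"`..`"V"`.
#' @param seed Integer seed.
#' @param leakage,group_by_animal See [select_features()].
#' @param permutation Model name to permutation-validate, or `NULL` to skip.
#' @param n_permutations Permutations if validating; default 1000.
#' @return List: `selection`, `evals` (per model: auc, cv mean), and
#'   `permutation` if requested.
#' @export
classify_stage <- function(table, lifetimes, stage, seed, leakage = TRUE,
                           group_by_animal = FALSE, permutation = NULL,
                           n_permutations = 1000) {
  selrep <- select_features(table, lifetimes, stage, seed = seed,
                            leakage = leakage,
                            group_by_animal = group_by_animal)
  if (selrep$empty)
    return(list(selection = selrep, evals = NULL, permutation = NULL))
  imp <- impute_missing(subset_features(
    table, features = selrep$selected,
    samples = c(selrep$train_ids, selrep$test_ids)))
  labels <- stats::setNames(imp$samples$group, imp$samples$sample_id)
  xs <- autoscale(t(imp$intensities[, selrep$train_ids, drop = FALSE]))
  xt <- autoscale(t(imp$intensities[, selrep$test_ids, drop = FALSE]),
                  center = attr(xs, "center"), scale = attr(xs, "scale"))
  fits <- train_models(xs, labels[selrep$train_ids], seed = seed)
  evals <- lapply(MODEL_NAMES, function(mm)
    evaluate_roc(fits, mm, xt, labels[selrep$test_ids], seed = seed))
  names(evals) <- MODEL_NAMES
  perm <- NULL
  if (!is.null(permutation)) {
    all_ids <- c(selrep$train_ids, selrep$test_ids)
    xa <- autoscale(t(imp$intensities[, all_ids, drop = FALSE]))
    perm <- permutation_validate(xa, labels[all_ids], model = permutation,
                                 n_permutations = n_permutations, seed = seed)
  }
  list(selection = selrep, evals = evals, permutation = perm)
}
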