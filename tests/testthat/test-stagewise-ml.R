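# Feature-selection cascade, stratified splitting, the five classifiers,
# ROC-AUC and permutation validation.

# a stage fixture: n per group at stage III, given per-feature DKO shifts
# (log2 units); remaining features are pure noise
make_stage_fixture <- function(n_per_group = 30, shifts = c(F01 = 2),
                               n_noise = 5, sigma = 0.5, seed = 1) {
  set.seed(seed)
  n_feat <- length(shifts) + n_noise
  ids <- sprintf("F%02d", seq_len(n_feat))
  dko <- matrix(rnorm(n_feat * n_per_group, 10, sigma), n_feat)
  ctl <- matrix(rnorm(n_feat * n_per_group, 10, sigma), n_feat)
  dko[seq_along(shifts), ] <- dko[seq_along(shifts), ] + shifts
  m <- 2^cbind(dko, ctl)
  rownames(m) <- ids
  tab <- make_group_table(2^dko, 2^ctl, stage_pcts = rep(50, 2 * n_per_group))
  rownames(tab$intensities) <- ids
  tab$annotations$feature_id <- ids
  list(table = tab, lifetimes = annotate_lifetime(tab))
}

test_that("stratified split has the right arithmetic and determinism", {
  ids <- sprintf("S%02d", 1:60)
  labels <- setNames(rep(c("DKO", "control"), each = 30), ids)
  sp <- split_train_test(ids, labels, seed = 5)
  expect_length(sp$train, 42)
  expect_length(sp$test, 18)
  expect_identical(sum(labels[sp$train] == "DKO"), 21L)
  expect_identical(sum(labels[sp$test] == "control"), 9L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- split_train_test(ids, labels, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_test(ids, labels, seed = 6)))
  expect_error(split_train_test(ids[1:3],
                                setNames(c("DKO", "DKO", "control"),
                                         ids[1:3]), seed = 1),
               ">= 2 samples")
})

test_that("animal-grouped splits never place one mouse on both sides", {
  ids <- sprintf("S%02d", 1:40)
  animals <- setNames(rep(sprintf("A%02d", 1:10), each = 4), ids)
  labels <- setNames(rep(rep(c("DKO", "control"), each = 4), 5), ids)
  sp <- split_train_test(ids, labels, seed = 3, animals = animals)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(unique(animals[sp$train]),
                          unique(animals[sp$test])), 0L)
})

test_that("correlation pruning keeps the lower-p member of a duplicated pair", {
  set.seed(77)
  n <- 24
  base <- rnorm(n, 0, 0.3)
  grp_shift <- rep(c(2, 0), each = n / 2)
  # F01 and F02 nearly duplicated (r ~ 1); F02's extra between-group noise
  # dilutes its test statistic
  m <- 2^rbind(F01 = 10 + base + grp_shift,
               F02 = 10 + base + grp_shift + rnorm(n, 0, 0.05) +
                 rep(c(-0.3, 0.3), each = n / 2),
               F03 = rnorm(n, 10, 1))
  tab <- make_group_table(m[, 1:(n / 2)], m[, (n / 2 + 1):n],
                          stage_pcts = rep(50, n))
  rownames(tab$intensities) <- rownames(m)
  tab$annotations$feature_id <- rownames(m)
  lt <- annotate_lifetime(tab)
  rep1 <- select_features(tab, lt, "III", seed = 2)
  expect_true(all(c("F01", "F02") %in% rep1$survivors_p_filter))
  kept <- intersect(rep1$survivors_corr_prune, c("F01", "F02"))
  expect_length(kept, 1L)
  # the kept member is the one with the smaller stage-wide Welch p
  p1 <- welch_test(m["F01", 1:12], m["F01", 13:24])$p
  p2 <- welch_test(m["F02", 1:12], m["F02", 13:24])$p
  expect_identical(kept, if (p1 <= p2) "F01" else "F02")
})

test_that("a perfectly separating feature survives the cascade and importances sum to 1", {
  fix <- make_stage_fixture(shifts = c(F01 = 4, F02 = 0.8), seed = 9)
  rep1 <- select_features(fix$table, fix$lifetimes, "III", seed = 3)
  expect_true("F01" %in% rep1$selected)
  expect_equal(sum(rep1$gini_importances), 1)
  expect_true(all(rep1$selected %in% rep1$survivors_corr_prune))
  expect_true(all(rep1$survivors_corr_prune %in% rep1$survivors_p_filter))
  expect_true(all(rep1$gini_importances[rep1$selected] >=
                    mean(rep1$gini_importances)))
})

test_that("null features pass the p-filter at about the alpha rate", {
  fix <- make_stage_fixture(n_per_group = 40, shifts = c(F001 = 0),
                            n_noise = 399, seed = 13)
  rep1 <- select_features(fix$table, fix$lifetimes, "III", seed = 4)
  # 400 null features at alpha 0.05: expect about 20, binomial 3 sigma
  expect_lt(abs(length(rep1$survivors_p_filter) - 20),
            3 * sqrt(400 * 0.05 * 0.95) + 1)
})

test_that("all five models separate a linearly separable fixture and vote by averaging", {
  set.seed(15)
  n <- 40
  x <- cbind(a = c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3)),
             b = rnorm(n))
  y <- factor(rep(c("control", "DKO"), each = n / 2),
              levels = c("control", "DKO"))
  fits <- train_models(autoscale(x), y, seed = 7)
  xs <- autoscale(x)
  for (mm in c("logistic", "random_forest", "knn", "svm_rbf", "voting")) {
    p <- predict_prob(fits, xs, mm)
    expect_identical(unname((p >= 0.5)), y == "DKO")
  }
  # voting probability is the arithmetic mean of the four members
  members <- sapply(c("logistic", "random_forest", "knn", "svm_rbf"),
                    function(mm) predict_prob(fits, xs, mm))
  expect_equal(predict_prob(fits, xs, "voting"), unname(rowMeans(members)),
               tolerance = 1e-12)
  expect_error(train_models(xs, factor(rep("DKO", n),
                                       levels = c("control", "DKO")),
                            seed = 1), "both classes")
})

test_that("ROC is a monotone step curve with trapezoidal AUC and symmetries", {
  y <- factor(c("control", "control", "DKO", "DKO"),
              levels = c("control", "DKO"))
  perfect <- roc_auc(c(0.1, 0.2, 0.8, 0.9), y)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$roc_points[1, ], data.frame(FPR = 0, TPR = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(perfect$roc_points[nrow(perfect$roc_points), ]),
               c(FPR = 1, TPR = 1))
  set.seed(20)
  scores <- rnorm(400)
  labels <- factor(sample(rep(c("control", "DKO"), 200)),
                   levels = c("control", "DKO"))
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$roc_points$FPR) >= 0))
  expect_true(all(diff(r$roc_points$TPR) >= 0))
  # label-independent scores give AUC near 1/2 (3 sigma of U-statistic sd)
  expect_lt(abs(r$auc - 0.5), 3 * sqrt((400 + 1) / (12 * 200 * 200)))
  # reversing scores reflects the AUC
  expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc, tolerance = 1e-12)
  # agreement with an independent ROC implementation
  skip_if_not_installed("pROC")
  proc <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                               levels = c("control", "DKO"),
                                               direction = "<")))
  expect_equal(r$auc, as.numeric(proc), tolerance = 1e-12)
})

test_that("permutation validation floors at 1/(n+1) on separable data and is null-calibrated", {
  set.seed(25)
  n <- 30
  x <- cbind(f = c(rnorm(n / 2, -3, 0.4), rnorm(n / 2, 3, 0.4)))
  y <- factor(rep(c("control", "DKO"), each = n / 2),
              levels = c("control", "DKO"))
  res <- permutation_validate(autoscale(x), y, model = "logistic",
                              n_permutations = 99, seed = 2)
  expect_equal(res$p_value, 1 / 100)
  expect_equal(res$accuracy, 1)
  # label-independent features: permutation p is not extreme
  x0 <- cbind(f = rnorm(n))
  res0 <- permutation_validate(autoscale(x0), y, model = "logistic",
                               n_permutations = 99, seed = 3)
  expect_gt(res0$p_value, 0.05)
})

test_that("the per-stage pipeline is reproducible under a fixed seed", {
  fix <- make_stage_fixture(shifts = c(F01 = 2, F02 = 1.5), seed = 31)
  r1 <- classify_stage(fix$table, fix$lifetimes, "III", seed = 17)
  r2 <- classify_stage(fix$table, fix$lifetimes, "III", seed = 17)
  expect_identical(r1$selection$selected, r2$selection$selected)
  expect_identical(sapply(r1$evals, `[[`, "auc"),
                   sapply(r2$evals, `[[`, "auc"))
  expect_gte(r1$evals$voting$auc, 0.9)
})
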