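# Fold changes, Welch tests, BH adjustment, stage sets, upset partitions,
# recurrence and volcano selection.

test_that("log2 fold change has the expected algebra", {
  m <- rbind(F1 = c(4, 4, 1, 1),
             F2 = c(8, 8, 2, 2),
             F3 = c(3, 5, 3, 5))
  tab <- make_table(m, groups = c("DKO", "DKO", "control", "control"))
  a <- tab$samples$sample_id[1:2]; b <- tab$samples$sample_id[3:4]
  fc <- log2_fold_change(tab, a, b)
  expect_equal(unname(fc), c(2, 2, 0))
  expect_equal(unname(log2_fold_change(tab, b, a)), -unname(fc))
})

test_that("welch_test matches the closed-form Welch formulas", {
  res <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4.0)
  # identical multisets give t = 0, p = 1
  same <- welch_test(c(2, 1, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  # oracle equivalence on random draws (direct formula transcription)
  set.seed(11)
  for (i in 1:100) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
    got <- welch_test(a, b); want <- welch_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(welch_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_test(1, c(2, 3)), ">= 2")
})

test_that("welch_test is invariant under within-group permutation and antisymmetric", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(6)
  r1 <- welch_test(a, b)
  r2 <- welch_test(sample(a), rev(b))
  expect_equal(r1$t, r2$t)
  expect_equal(welch_test(b, a)$t, -r1$t)
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone in p after sorting
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("stage significance is type-I calibrated on null data", {
  # all effect sizes zero: each stage set is a binomial(n_features, alpha)
  cfg <- cohort_config(n_features = 1000, seed = 19,
                       archetype_fracs = c(A = 0, B = 0, C = 0, D = 0),
                       frac_background = 0, frac_unstable = 0,
                       frac_qc_absent = 0, n_prognostic = 0)
  sim <- simulate_cohort(cfg)
  tab <- subset_features(sim$table,
                         samples = sim$table$samples$role == "study")
  lt <- annotate_lifetime(tab)
  sets <- stage_significance(tab, lt, alpha = 0.05)
  expect_named(sets, paste("stage", c("I", "II", "III", "IV", "V")))
  sigma3 <- 3 * sqrt(1000 * 0.05 * 0.95)
  for (s in sets)
    expect_lt(abs(length(s) - 50), sigma3)
  # alpha = 0 empties every set
  expect_true(all(lengths(stage_significance(tab, lt, alpha = 0)) == 0))
})

test_that("stage-restricted effects appear only in their stage set", {
  # features with a designed stage-V-only effect
  cfg <- cohort_config(n_features = 200, seed = 23,
                       archetype_fracs = c(A = 0, B = 0, C = 0, D = 0.1),
                       frac_background = 0, frac_unstable = 0,
                       frac_qc_absent = 0, n_prognostic = 0)
  sim <- simulate_cohort(cfg)
  tab <- subset_features(sim$table,
                         samples = sim$table$samples$role == "study")
  lt <- annotate_lifetime(tab)
  sets <- stage_significance(tab, lt)
  d_ids <- names(sim$truth$kind)[sim$truth$kind == "D"]
  hit_v <- mean(d_ids %in% sets[["stage V"]])
  hit_i <- mean(d_ids %in% sets[["stage I"]])
  expect_gt(hit_v, 0.9)   # late-spike features found at stage V
  expect_lt(hit_i, 0.3)   # and essentially absent from stage I
})

test_that("exclusive intersections partition the union (upset semantics)", {
  fam <- list(A = c("1", "2"), B = c("2", "3"))
  ex <- exclusive_intersections(fam)
  expect_setequal(ex[["A"]], "1")
  expect_setequal(ex[["B"]], "3")
  expect_setequal(ex[["A & B"]], "2")
  # disjoint sets give only singleton patterns
  ex2 <- exclusive_intersections(list(X = "a", Y = "b"))
  expect_named(ex2, c("X", "Y"), ignore.order = TRUE)
  # partition property on random families
  set.seed(9)
  for (i in 1:10) {
    fam <- lapply(1:4, function(j) as.character(sample(1:30, sample(5:15, 1))))
    names(fam) <- paste0("S", 1:4)
    ex <- exclusive_intersections(fam)
    expect_identical(sum(lengths(ex)), length(unique(unlist(fam))))
    expect_false(anyDuplicated(unlist(ex)) > 0)
  }
})

test_that("recurrence respects the at-least-k rule", {
  fam <- list(a = c("x", "y"), b = c("x", "z"), c = c("x", "y"),
              d = character(0), e = c("w"))
  expect_identical(recurrent_features(fam, 3), "x")      # x in 3 sets
  expect_false("y" %in% recurrent_features(fam, 3))      # y in 2 sets
  expect_setequal(recurrent_features(fam, 1), c("w", "x", "y", "z"))
  expect_error(recurrent_features(fam, 6), "exceeds")
})

test_that("volcano selection applies both thresholds and is swap-stable", {
  set.seed(31)
  n <- 12
  # F1: big shift (selected); F2: significant but small FC; F3: big FC in
  # mean but noisy (not significant)
  dko <- rbind(F1 = rlnorm(n, log(400), 0.1),
               F2 = rlnorm(n, log(130), 0.05),
               F3 = rlnorm(n, log(100), 1.5))
  ctl <- rbind(F1 = rlnorm(n, log(100), 0.1),
               F2 = rlnorm(n, log(100), 0.05),
               F3 = rlnorm(n, log(100), 1.5))
  tab <- make_group_table(dko, ctl)
  ref <- tab$samples$sample_id[tab$samples$group == "control"]
  cmp <- tab$samples$sample_id[tab$samples$group == "DKO"]
  sel <- volcano_select(tab, ref, cmp)
  expect_true("F1" %in% sel)
  expect_false("F2" %in% sel)
  rec <- attr(sel, "records")
  expect_true(rec$p[rec$feature_id == "F2"] < 0.05)  # fails only the FC rule
  # swapping reference and comparison selects the same features
  sel_swap <- volcano_select(tab, cmp, ref)
  expect_setequal(as.character(sel), as.character(sel_swap))
})
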