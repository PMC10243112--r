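# Kaplan-Meier, Nelson-Aalen, log-rank, RMST, median splits and the
# prognostic screen, checked against hand-computed oracles.

# the 4-animal fixture: deaths at 1 and 2, censoring at 3, death at 4
fixture4 <- function() survival_records(paste0("m", 1:4), c(1, 2, 3, 4),
                                        c(TRUE, TRUE, FALSE, TRUE))

test_that("Kaplan-Meier matches the hand product-limit on the 4-animal fixture", {
  curve <- km_estimate(fixture4())
  expect_equal(curve$time, c(1, 2, 3, 4))
  expect_equal(curve$surv, c(0.75, 0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(curve$n_risk, c(4, 3, 2, 1))
  expect_equal(curve$n_event, c(1, 1, 0, 1))
  # all censored: survival stays 1
  allc <- km_estimate(survival_records(paste0("m", 1:3), c(5, 6, 7),
                                       rep(FALSE, 3)))
  expect_true(all(allc$surv == 1))
  # simultaneous deaths: one step from 1 to 0
  drop <- km_estimate(survival_records(paste0("m", 1:3), c(4, 4, 4),
                                       rep(TRUE, 3)))
  expect_equal(drop$surv, 0)
  expect_error(survival_records("m1", 0, TRUE), "positive")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(41)
  times <- sample(1:20, 12, replace = TRUE)
  curve <- km_estimate(survival_records(paste0("m", 1:12), times,
                                        rep(TRUE, 12)))
  for (i in seq_len(nrow(curve)))
    expect_equal(curve$surv[i], mean(times > curve$time[i]),
                 tolerance = 1e-12)
})

test_that("Nelson-Aalen matches the hand sum and bounds KM from above", {
  na <- nelson_aalen(fixture4())
  expect_equal(na$cumhaz[na$time == 2], 1 / 4 + 1 / 3, tolerance = 1e-12)
  set.seed(43)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    rec <- survival_records(paste0("m", 1:n),
                            sample(1:25, n, replace = TRUE),
                            runif(n) < 0.7)
    curve <- km_estimate(rec)
    expect_true(all(diff(curve$cumhaz) >= -1e-12))
    expect_true(all(diff(curve$surv) <= 1e-12))
    # exp(-H) >= S pointwise (product-limit vs exponential inequality)
    expect_true(all(exp(-curve$cumhaz) >= curve$surv - 1e-12))
  }
})

test_that("log-rank matches the hand oracle on an 8-animal fixture", {
  recA <- survival_records(paste0("a", 1:4), c(2, 4, 5, 9),
                           c(TRUE, TRUE, FALSE, TRUE))
  recB <- survival_records(paste0("b", 1:4), c(6, 7, 10, 12),
                           c(TRUE, FALSE, TRUE, TRUE))
  got <- logrank_test(recA, recB)
  expect_equal(got$chi2, logrank_oracle(recA, recB), tolerance = 1e-9)
  expect_equal(got$p, pchisq(got$chi2, 1, lower.tail = FALSE))
  # symmetry under label swap
  expect_equal(logrank_test(recB, recA)$chi2, got$chi2, tolerance = 1e-12)
  # identical groups: no signal
  same <- logrank_test(recA, recA)
  expect_lt(same$chi2, 1e-12)
  # no events anywhere: degenerate, flagged
  cens <- survival_records(paste0("c", 1:3), c(5, 6, 7), rep(FALSE, 3))
  deg <- logrank_test(cens, cens)
  expect_true(deg$degenerate)
  expect_identical(deg$p, 1)
})

test_that("RMST is the exact step-function integral", {
  curve <- km_estimate(fixture4())
  # rectangles: 1x1 + 0.75x1 + 0.5x2
  expect_equal(rmst(curve, 4), 2.75, tolerance = 1e-12)
  allc <- km_estimate(survival_records(paste0("m", 1:3), c(10, 11, 12),
                                       rep(FALSE, 3)))
  expect_equal(rmst(allc, 10), 10)
  expect_error(rmst(curve, 5), "exceeds")
  # nondecreasing in tau; antisymmetric delta
  expect_lte(rmst(curve, 2), rmst(curve, 3))
  other <- km_estimate(survival_records(paste0("x", 1:4), c(2, 3, 4, 4),
                                        rep(TRUE, 4)))
  expect_equal(delta_rmst(curve, other), -delta_rmst(other, curve))
  expect_equal(delta_rmst(curve, curve), 0)
})

# study table where one feature's final-draw abundance tracks lifespan
prognostic_fixture <- function(beta = 1.5, seed = 1, n_dko = 15) {
  set.seed(seed)
  life <- round(runif(n_dko, 28, 45), 1)
  rows <- lapply(seq_len(n_dko), function(i) {
    ages <- c(life[i] / 2, life[i])
    data.frame(animal_id = sprintf("D%02d", i), age = ages,
               lifespan = life[i])
  })
  draws <- do.call(rbind, rows)
  n <- nrow(draws)
  z <- (life - mean(life)) / sd(life)
  m <- matrix(2^rnorm(2 * n, 15, 0.4), 2, n,
              dimnames = list(c("Fprog", "Fnull"),
                              sprintf("S%03d", seq_len(n))))
  final <- draws$age == draws$lifespan
  m["Fprog", final] <- 2^(15 + beta * z + rnorm(n_dko, 0, 0.4))
  tab <- make_table(m, roles = rep("study", n),
                    groups = rep("DKO", n), ages = draws$age,
                    lifespans = draws$lifespan)
  tab$samples$animal_id <- draws$animal_id
  list(table = tab, lifetimes = annotate_lifetime(tab),
       records = survival_records(sprintf("D%02d", seq_len(n_dko)), life,
                                  rep(TRUE, n_dko)))
}

test_that("median split uses final draws with ties going low", {
  fix <- prognostic_fixture(seed = 3)
  sp <- median_split(fix$table, fix$lifetimes, "Fprog")
  expect_length(sp$low, 8)   # 15 animals: 8 low (median inclusive), 7 high
  expect_length(sp$high, 7)
  expect_setequal(c(sp$low, sp$high), sprintf("D%02d", 1:15))
  expect_true(all(sp$abundance[sp$low] <= median(sp$abundance)))
  expect_true(all(sp$abundance[sp$high] > median(sp$abundance)))
  # explicit tie at the median goes to the low group
  m <- matrix(2^10, 1, 6, dimnames = list("F1", sprintf("S%d", 1:6)))
  m[1, ] <- c(1, 2, 2, 3, 4, 5)
  tab <- make_table(m, roles = rep("study", 6), groups = rep("DKO", 6),
                    ages = rep(40, 6), lifespans = rep(40, 6))
  tab$samples$animal_id <- paste0("A", 1:6)
  sp2 <- median_split(tab, annotate_lifetime(tab), "F1")
  expect_length(sp2$low, 3)
  # degenerate: constant abundance puts everyone low and flags it
  m[1, ] <- 7
  tab$intensities <- m
  sp3 <- median_split(tab, annotate_lifetime(tab), "F1")
  expect_true(sp3$degenerate)
  expect_length(sp3$low, 6)
})

test_that("the prognostic screen retains the coupled lipid and ranks by |delta RMST|", {
  fix <- prognostic_fixture(beta = 2, seed = 5)
  hits <- prognostic_screen(fix$table, fix$lifetimes, fix$records,
                            c("Fprog", "Fnull"))
  expect_true("Fprog" %in% hits$feature_id)
  expect_lt(hits$logrank_p[hits$feature_id == "Fprog"], 0.05)
  all_rows <- attr(hits, "all")
  expect_identical(nrow(all_rows), 2L)
  # ranking: larger |delta RMST| first
  if (nrow(hits) > 1)
    expect_true(all(diff(abs(hits$delta_rmst)) <= 1e-12))
})

test_that("a survival-independent lipid is retained at about the alpha rate", {
  keep <- vapply(1:30, function(r) {
    fix <- prognostic_fixture(beta = 0, seed = 100 + r)
    hits <- prognostic_screen(fix$table, fix$lifetimes, fix$records, "Fprog")
    nrow(hits) > 0
  }, logical(1))
  # null retention frequency should look like alpha = 0.05, not certainty;
  # with 30 replicates allow up to binomial 3 sigma above 0.05
  expect_lt(mean(keep), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))
})
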