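# Fixture builders shared across the suite. All fixtures are constructed in
# code; nothing is read from disk except explicit round-trip tests.

# minimal annotation/metadata frames around an intensity matrix;
# roles: named vector sample_id -> role ("study"/"qc"/"blank")
make_table <- function(intensities, roles = NULL, groups = NULL,
                       ages = NULL, lifespans = NULL) {
  n_f <- nrow(intensities)
  n_s <- ncol(intensities)
  sample_ids <- colnames(intensities)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n_s))
  feature_ids <- rownames(intensities)
  if (is.null(feature_ids)) feature_ids <- sprintf("F%02d", seq_len(n_f))
  if (is.null(roles)) roles <- rep("study", n_s)
  if (is.null(groups))
    groups <- ifelse(roles == "study",
                     rep(c("DKO", "control"), length.out = n_s), NA)
  if (is.null(lifespans)) lifespans <- ifelse(roles == "study", 40, NA)
  if (is.null(ages)) ages <- ifelse(roles == "study", 20, NA)
  ann <- data.frame(feature_id = feature_ids,
                    lipid_name = paste0("synthetic-", feature_ids),
                    adduct = "[M-H]-", rt_min = 1, mz = 500,
                    ion_mode = "negative", confidence_level = 3L)
  smp <- data.frame(sample_id = sample_ids, animal_id = sample_ids,
                    group = groups, role = roles, age_weeks = ages,
                    lifespan_weeks = lifespans,
                    injection_order = seq_len(n_s),
                    event_observed = ifelse(roles == "study", TRUE, NA))
  feature_table(matrix(as.numeric(intensities), n_f, n_s,
                       dimnames = list(feature_ids, sample_ids)),
                ann, smp)
}

# two-group study table from per-group matrices (features x samples)
make_group_table <- function(dko, ctl, stage_pcts = NULL) {
  m <- cbind(dko, ctl)
  n_d <- ncol(dko); n_c <- ncol(ctl)
  colnames(m) <- c(sprintf("D%03d", seq_len(n_d)), sprintf("C%03d", seq_len(n_c)))
  groups <- rep(c("DKO", "control"), c(n_d, n_c))
  lifespans <- rep(40, n_d + n_c)
  pct <- if (is.null(stage_pcts)) rep(50, n_d + n_c) else stage_pcts
  make_table(m, roles = rep("study", n_d + n_c), groups = groups,
             ages = pct / 100 * lifespans, lifespans = lifespans)
}

# independent Welch oracle: direct formula transcription
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# independent BH oracle: literal step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- Inf
  for (k in rev(seq_len(m))) {
    running_min <- min(running_min, p[ord[k]] * m / k)
    q[ord[k]] <- min(running_min, 1)
  }
  q
}

# hand log-rank oracle: observed-minus-expected with hypergeometric variance
logrank_oracle <- function(recA, recB) {
  pooled <- rbind(data.frame(t = recA$time, e = recA$event, g = 0),
                  data.frame(t = recB$time, e = recB$event, g = 1))
  times <- sort(unique(pooled$t[pooled$e]))
  o_minus_e <- 0; v <- 0
  for (tt in times) {
    at_risk <- pooled$t >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & pooled$g == 1)
    d <- sum(pooled$t == tt & pooled$e)
    d1 <- sum(pooled$t == tt & pooled$e & pooled$g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# noisy archetype trajectory profiles with known labels
make_archetype_profiles <- function(n_per = c(A = 20, B = 10, C = 20, D = 30),
                                    sigma = 0.2, seed = 1) {
  set.seed(seed)
  arch <- lipicourse:::ARCHETYPE_EFFECTS
  labs <- rep(names(n_per), n_per)
  prof <- t(vapply(labs, function(l)
    arch[l, ] * runif(1, 0.8, 1.2) + rnorm(5, 0, sigma), numeric(5)))
  rownames(prof) <- sprintf("F%03d", seq_along(labs))
  list(profiles = prof, labels = setNames(labs, rownames(prof)))
}
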