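# Cohort-level biomarker statistics.

test_that("AUC equals all-pairs concordance counting", {
  expect_equal(roc_auc(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(3, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  set.seed(21)
  scores <- c(2.1, 0.3, 5, 5, 1.2, 4.4, 0.3, 3)
  pos <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(roc_auc(scores, pos), auc_pairs(scores, pos))
  for (i in 1:20) {
    n <- sample(6:50, 1)
    s <- round(rnorm(n), 1)  # rounding forces ties
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(lab) == 0 || sum(!lab) == 0) next
    expect_equal(roc_auc(s, lab), auc_pairs(s, lab), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(3)
  s <- rexp(40); lab <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  a <- roc_auc(s, lab)
  expect_equal(roc_auc(log10(s + 0.01), lab), a)
  expect_equal(roc_auc(rank(s), lab), a)
  expect_equal(roc_auc(s^3, lab), a)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(33)
  s <- rnorm(60)
  lab <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  r <- pROC::roc(lab, s, quiet = TRUE, direction = "<")
  expect_equal(roc_auc(s, lab), as.numeric(pROC::auc(r)), tolerance = 1e-12)
})

test_that("Youden cutoff maximizes sensitivity + specificity - 1", {
  y <- youden_cutoff(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE))
  expect_gt(y$cutoff, 2); expect_lt(y$cutoff, 9)
  expect_equal(y$youden, 1)
  expect_warning(flat <- youden_cutoff(rep(2, 6), rep(c(TRUE, FALSE), 3)),
                 "separate")
  expect_equal(flat$youden, 0)
  set.seed(14)
  for (i in 1:20) {
    s <- round(rnorm(20), 1)
    lab <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (sum(lab) == 0 || sum(!lab) == 0) next
    y <- suppressWarnings(youden_cutoff(s, lab))
    expect_equal(y$youden, youden_scan(s, lab)$max_j, tolerance = 1e-9)
    # reported sensitivity/specificity reproduce the dichotomization
    expect_equal(y$sensitivity, mean(s[lab] > y$cutoff))
    expect_equal(y$specificity, mean(s[!lab] <= y$cutoff))
  }
})

test_that("two-sided Fisher matches hypergeometric enumeration", {
  set.seed(8)
  for (i in 1:200) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab), fisher_enum(tab),
                 tolerance = 1e-9)
  }
  expect_warning(p <- fisher_exact_two_sided(matrix(c(0, 5, 0, 9), 2)),
                 "margin")
  expect_equal(p, 1)
  expect_error(fisher_exact_two_sided(c(1.5, 2, 3, 4)), "integers")
})

test_that("Mann-Whitney U uses the exact tail for small untied samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)  # 2/choose(6,3)
  same <- mann_whitney_u(1:10, 1:10)
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum rejection rate matches an independent U-statistic oracle", {
  # hand-written tie-corrected normal approximation as the oracle
  mw_oracle_p <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 *
      (n1 + n2 + 1 - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    2 * stats::pnorm(-abs(z))
  }
  set.seed(19)
  rej_impl <- rej_orac <- logical(200)
  for (i in 1:200) {
    x <- rnorm(50); y <- rnorm(50, mean = 1)
    rej_impl[i] <- mann_whitney_u(x, y)$p_value < 0.05
    rej_orac[i] <- mw_oracle_p(x, y) < 0.05
  }
  se <- sqrt(mean(rej_orac) * (1 - mean(rej_orac)) / 200)
  expect_lt(abs(mean(rej_impl) - mean(rej_orac)), 3 * se + 0.01)
})

test_that("Kaplan-Meier medians and log-rank behave on separated groups", {
  time <- c(rep(10, 5), rep(100, 5))
  event <- rep(1, 10)
  grp <- rep(c("A", "B"), each = 5)
  km <- km_logrank(time, event, grp)
  expect_equal(unname(km$medians["A"]), 10)
  expect_equal(unname(km$medians["B"]), 100)
  expect_lt(km$logrank_p, 0.01)

  same <- km_logrank(rep(c(5, 10, 15), 2), rep(1, 6),
                     rep(c("A", "B"), each = 3))
  expect_gt(same$logrank_p, 0.9)
})

test_that("log-rank p matches a by-hand risk-table computation", {
  # 12 patients with censoring
  time <- c(3, 5, 7, 7, 9, 14, 4, 6, 8, 12, 15, 20)
  event <- c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 6)
  km <- km_logrank(time, event, grp)
  expect_equal(km$logrank_p, logrank_oracle(time, event, grp),
               tolerance = 1e-9)
})

test_that("Cox hazard ratio is near 1 under identical hazards", {
  set.seed(55)
  time <- rexp(200, 0.02)
  grp <- rep(0:1, each = 100)
  r <- cox_hr(grp, time, rep(1, 200))
  expect_gt(r$hr, 0.7); expect_lt(r$hr, 1.4)
  expect_error(cox_hr(rep(1, 10), rexp(10), rep(1, 10)), "constant")
  expect_error(cox_hr(rep(0:1, 5), rexp(10), rep(0, 10)), "event")
})

test_that("Cox flags monotone-likelihood separation", {
  time <- c(1:5, 101:105)
  event <- rep(1, 10)
  grp <- rep(0:1, each = 5)
  expect_warning(r <- cox_hr(grp, time, event), "separation|unbounded")
  expect_true(r$separation)
})

test_that("correlation: Pearson on linear, Spearman on monotone", {
  x <- 1:10
  expect_equal(correlation(x, 2 * x, "pearson")$estimate, 1)
  expect_equal(correlation(x, exp(x), "spearman")$estimate, 1)
  set.seed(4)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(correlation(a, b, "spearman")$estimate,
               correlation(rank(a), rank(b), "pearson")$estimate,
               tolerance = 1e-12)
  expect_warning(r <- correlation(rep(1, 5), rnorm(5)), "constant")
  expect_true(r$degenerate)
})

test_that("editing-cutoff grid search returns the requested grid point", {
  builder <- function(ct) {
    data.frame(iotnl = c(1, 2, 3, 10, 11, 12),
               orr_label = c("NOR", "NOR", "NOR", "ORR", "ORR", "ORR"))
  }
  single <- optimize_editing_cutoff(builder, grid_start = 0.8,
                                    grid_stop = 0.8, grid_step = 0.1)
  expect_equal(single$best_cutoff, 0.8)
  # flat profile: smallest grid value wins the tie
  flat <- optimize_editing_cutoff(builder)
  expect_equal(flat$best_cutoff, 0.5)
  expect_equal(nrow(flat$auc_per_cutoff), 11L)
  expect_true(all(flat$auc_per_cutoff$auc == 1))
})

test_that("cohort dichotomization reproduces its own cutoff statistics", {
  sim <- simulate_cohort(sim_config(n_patients = 80), seed = 6)
  d <- dichotomize_cohort(sim$cohort, label = "ORR", endpoint = "PFS")
  lab <- sim$cohort$orr_label == "ORR"
  expect_equal(d$sensitivity,
               mean(sim$cohort$iotnl[lab] > d$cutoff))
  expect_equal(d$specificity,
               mean(sim$cohort$iotnl[!lab] <= d$cutoff))
  expect_equal(d$n_high + d$n_low, d$n_evaluable)
  expect_equal(sum(d$response_table), d$n_evaluable)
  expect_true(d$auc >= 0 && d$auc <= 1)
})
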