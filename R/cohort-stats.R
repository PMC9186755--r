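# Cohort-level biomarker statistics: ROC/AUC, Youden dichotomization,
# editing-score cutoff optimization, and the group-comparison and
# survival tests used to evaluate the ioTNL against clinical outcomes.

#' Area under the ROC curve
#'
#' AUC computed as the probability that a randomly chosen positive
#' outscores a randomly chosen negative, counting ties as 1/2 (the
#' Mann-Whitney formulation via midranks, equivalent to all-pairs
#' counting).
#'
#' @param scores numeric biomarker values.
#' @param labels outcome labels; logical, 0/1, or clinical labels with
#'   the positive class inferable (ORR/DCB/positive) or given via
#'   `positive`.
#' @param positive optional explicit positive-class value(s).
#' @return the AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stopf("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Youden-index dichotomization cutoff
#'
#' Scans candidate cutoffs (midpoints of adjacent sorted unique scores,
#' plus -Inf/+Inf sentinels) and returns the one maximizing
#' J = sensitivity + specificity - 1, where scores strictly above the
#' cutoff predict the positive class. Ties go to the smallest cutoff.
#'
#' @inheritParams roc_auc
#' @return a list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(scores, labels, positive = NULL) {
  pos <- as_binary_labels(labels, positive)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  if (sum(pos) == 0 || sum(!pos) == 0) {
    stopf("both classes must be present to choose a cutoff")
  }
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) {
    c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  } else c(-Inf, Inf)
  sens <- vapply(cand, function(ct) mean(scores[pos] > ct), numeric(1))
  spec <- vapply(cand, function(ct) mean(scores[!pos] <= ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # candidates ascending: smallest wins
  if (max(j) <= 1e-12) {
    warnf("scores do not separate the classes; sentinel cutoff returned")
  }
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

#' Grid search for the best immune-editing-score cutoff
#'
#' Recomputes every patient's ioTNL at each editing-score cutoff on the
#' grid (default 0.5 to 1.5 in increments of 0.1) and returns the cutoff
#' whose ioTNL best predicts the clinical label by ROC AUC. AUC ties go
#' to the smaller cutoff.
#'
#' @param cohort_builder a function taking one editing-score cutoff and
#'   returning a cohort table with columns `iotnl` and `orr_label`
#'   (ORR/NOR) and/or `dcb_label` (DCB/NDB); `NE`/`NA` rows are dropped.
#' @param grid_start,grid_stop,grid_step the cutoff grid.
#' @param label which clinical label the AUC is computed against.
#' @return a list with `best_cutoff`, `best_auc` and `auc_per_cutoff`
#'   (data.frame of cutoff and auc).
#' @export
optimize_editing_cutoff <- function(cohort_builder,
                                    grid_start = 0.5, grid_stop = 1.5,
                                    grid_step = 0.1,
                                    label = c("ORR", "DCB")) {
  label <- match.arg(label)
  if (grid_step <= 0 || grid_stop < grid_start) {
    stopf("cutoff grid is malformed")
  }
  grid <- round(seq(grid_start, grid_stop, by = grid_step), 10)
  auc <- vapply(grid, function(ct) {
    tab <- cohort_builder(ct)
    lab <- if (label == "ORR") tab$orr_label else tab$dcb_label
    keep <- !is.na(lab) & lab != "NE"
    roc_auc(tab$iotnl[keep], lab[keep], positive = label)
  }, numeric(1))
  best <- which(auc >= max(auc) - 1e-12)[1]
  list(best_cutoff = grid[best], best_auc = auc[best],
       auc_per_cutoff = data.frame(cutoff = grid, auc = auc))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value under the minimum-likelihood definition: the
#' sum of hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table.
#'
#' @param table a 2x2 matrix of non-negative integer counts, or a
#'   length-4 vector filled by row.
#' @return the p-value; a table with a zero margin carries no
#'   information and returns 1 with a warning.
#' @export
fisher_exact_two_sided <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2, byrow = TRUE)
  if (!all(dim(table) == 2)) stopf("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stopf("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warnf("a margin of the 2x2 table is zero; p = 1")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Mann-Whitney U test (two-sided)
#'
#' Unpaired rank-sum comparison of two groups. The exact distribution is
#' used when the combined sample size is at most 20 and there are no
#' ties; otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return a list with `U` (number of (x, y) pairs with x > y, ties
#'   counting 1/2) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(U = unname(res$statistic), p_value = res$p.value)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group, group medians (first time
#' the survival curve drops to 0.5 or below; `NA` = not reached) and the
#' unweighted (Mantel-Haenszel) log-rank test.
#'
#' @param time follow-up times (>= 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param group group labels (>= 2 groups for the test).
#' @return a list with `medians` (named by group), `logrank_p`,
#'   `curves` (data.frame: group, time, n_risk, n_event, surv) and the
#'   `survfit` object. With no events the p-value is `NA` and
#'   `no_events = TRUE` is flagged.
#' @export
km_logrank <- function(time, event, group) {
  if (any(time < 0, na.rm = TRUE)) stopf("survival times must be >= 0")
  group <- factor(group)
  if (nlevels(group) < 2) stopf("need at least two groups")
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  smry <- summary(fit)$table
  medians <- stats::setNames(smry[, "median"],
                             sub("^group=", "", rownames(smry)))
  if (sum(event, na.rm = TRUE) == 0) {
    warnf("no events observed; log-rank p undefined")
    p <- NA_real_
    no_events <- TRUE
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    p <- stats::pchisq(sd$chisq, df = nlevels(group) - 1, lower.tail = FALSE)
    no_events <- FALSE
  }
  curves <- data.frame(
    group = rep(sub("^group=", "", names(fit$strata)), fit$strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv)
  list(medians = medians, logrank_p = p, curves = curves, fit = fit,
       no_events = no_events)
}

#' Cox proportional-hazards hazard ratio
#'
#' Univariable Cox model (Efron tie handling) of survival on a score or
#' binary group; returns the hazard ratio with Wald 95% CI and p-value.
#' Monotone-likelihood separation (the partial likelihood has no interior
#' maximum) is flagged and the CI reported as unbounded.
#'
#' @param x covariate: numeric score, or a 2-level factor/character whose
#'   second level is the comparison group.
#' @param time,event survival times and event indicators.
#' @return a list with `hr`, `ci` (length 2), `p_value`, `coef`,
#'   `separation` flag.
#' @export
cox_hr <- function(x, time, event) {
  if (sum(event, na.rm = TRUE) < 1) stopf("need at least one event")
  if (length(unique(x[!is.na(x)])) < 2) stopf("covariate is constant")
  if (is.character(x)) x <- factor(x)
  df <- data.frame(x = x, time = time, event = event)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, data = df,
                    ties = "efron"))
  sm <- summary(fit)
  coef <- unname(stats::coef(fit)[1])
  se <- sm$coefficients[1, "se(coef)"]
  separation <- !is.finite(coef) || abs(coef) > 15 || se > 100
  if (separation) {
    warnf("monotone likelihood (separation): hazard ratio unbounded")
    ci <- c(0, Inf)
  } else {
    ci <- exp(coef + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  list(hr = exp(coef), ci = ci,
       p_value = sm$coefficients[1, "Pr(>|z|)"],
       coef = coef, separation = separation)
}

#' Correlation coefficient with two-sided p-value
#'
#' Pearson or Spearman correlation; the p-value uses the t approximation
#' (Spearman p is the t approximation on the rank correlation, robust to
#' ties).
#'
#' @param x,y numeric vectors, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return a list with `estimate`, `p_value`, `method`, and a
#'   `degenerate` flag when either vector is constant (estimate `NA`).
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant vector: correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_, method = method,
                degenerate = TRUE))
  }
  res <- suppressWarnings(
    stats::cor.test(x, y, method = method,
                    exact = if (method == "spearman") FALSE else NULL))
  list(estimate = unname(res$estimate), p_value = res$p.value,
       method = method, degenerate = FALSE)
}

#' Dichotomize a cohort at the Youden-optimal biomarker cutoff
#'
#' Splits patients into biomarker-high and -low groups at the Youden
#' cutoff for the chosen clinical label, then reports per-group response
#' rates with a Fisher exact test, the ROC AUC, sensitivity/specificity
#' at the cutoff, Kaplan-Meier medians with the log-rank p, and the Cox
#' hazard ratio of high vs low. Response tests use evaluable patients
#' only (label not NE/NA); survival uses all patients with follow-up
#' times.
#'
#' @param cohort a cohort table (see [simulate_cohort()] /
#'   [read_clinical_table()]) with the score column plus `orr_label` or
#'   `dcb_label` and endpoint columns `pfs_days`/`pfs_event` or
#'   `os_days`/`os_event`.
#' @param score_col name of the biomarker column (default `"iotnl"`).
#' @param label `"ORR"` or `"DCB"`.
#' @param endpoint `"PFS"` or `"OS"`.
#' @return a `dichotomy_result` list.
#' @export
dichotomize_cohort <- function(cohort, score_col = "iotnl",
                               label = c("ORR", "DCB"),
                               endpoint = c("PFS", "OS")) {
  label <- match.arg(label)
  endpoint <- match.arg(endpoint)
  lab_col <- if (label == "ORR") "orr_label" else "dcb_label"
  if (!lab_col %in% names(cohort)) stopf("cohort lacks column %s", lab_col)
  score <- cohort[[score_col]]
  lab <- cohort[[lab_col]]
  evaluable <- !is.na(lab) & lab != "NE" & !is.na(score)
  yj <- youden_cutoff(score[evaluable], lab[evaluable], positive = label)
  auc <- roc_auc(score[evaluable], lab[evaluable], positive = label)
  high <- score > yj$cutoff
  resp <- as_binary_labels(lab[evaluable], positive = label)
  hi_e <- high[evaluable]
  tab <- matrix(c(sum(resp & hi_e), sum(!resp & hi_e),
                  sum(resp & !hi_e), sum(!resp & !hi_e)),
                nrow = 2, byrow = TRUE)
  fisher_p <- fisher_exact_two_sided(tab)
  tcol <- if (endpoint == "PFS") "pfs_days" else "os_days"
  ecol <- if (endpoint == "PFS") "pfs_event" else "os_event"
  km <- hr <- NULL
  if (all(c(tcol, ecol) %in% names(cohort))) {
    surv_ok <- !is.na(cohort[[tcol]]) & !is.na(high)
    grp <- factor(ifelse(high[surv_ok], "high", "low"),
                  levels = c("low", "high"))
    if (nlevels(droplevels(grp)) == 2) {
      km <- km_logrank(cohort[[tcol]][surv_ok], cohort[[ecol]][surv_ok], grp)
      hr <- cox_hr(grp, cohort[[tcol]][surv_ok], cohort[[ecol]][surv_ok])
    }
  }
  structure(list(
    label = label, endpoint = endpoint, cutoff = yj$cutoff,
    sensitivity = yj$sensitivity, specificity = yj$specificity,
    auc = auc, n_evaluable = sum(evaluable),
    n_high = sum(hi_e), n_low = sum(!hi_e),
    rate_high = if (sum(hi_e)) sum(resp & hi_e) / sum(hi_e) else NA_real_,
    rate_low = if (sum(!hi_e)) sum(resp & !hi_e) / sum(!hi_e) else NA_real_,
    response_table = tab, fisher_p = fisher_p,
    km_medians = if (!is.null(km)) km$medians else NULL,
    logrank_p = if (!is.null(km)) km$logrank_p else NA_real_,
    hazard_ratio = if (!is.null(hr)) hr$hr else NA_real_,
    hr_ci = if (!is.null(hr)) hr$ci else c(NA_real_, NA_real_),
    hr_p = if (!is.null(hr)) hr$p_value else NA_real_),
    class = "dichotomy_result")
}

#' @export
print.dichotomy_result <- function(x, ...) {
  cat(sprintf("%s dichotomization at cutoff %.4g (AUC %.3f)\n",
              x$label, x$cutoff, x$auc))
  cat(sprintf("  high: %d/%d = %.1f%%  |  low: %d/%d = %.1f%%  (Fisher p = %.4g)\n",
              x$response_table[1, 1], x$n_high, 100 * x$rate_high,
              x$response_table[2, 1], x$n_low, 100 * x$rate_low,
              x$fisher_p))
  if (!is.na(x$logrank_p)) {
    cat(sprintf("  %s: median high %s vs low %s days, log-rank p = %.4g\n",
                x$endpoint,
                format(x$km_medians[["high"]]), format(x$km_medians[["low"]]),
                x$logrank_p))
    cat(sprintf("  HR (high vs low) = %.3f [%.3f, %.3f], p = %.4g\n",
                x$hazard_ratio, x$hr_ci[1], x$hr_ci[2], x$hr_p))
  }
  invisible(x)
}
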