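# Synthetic-data generators: read-level candidate-variant fixtures with
# planted filter violations, clonal tumors with planted immunoediting
# structure, and cohorts whose response and survival are linked to the
# ioTNL through a logistic/exponential outcome model. Every generator is
# deterministic under a fixed seed and emits the truth alongside the
# observables.

#' Simulation configuration
#'
#' Defaults describe a mid-sized checkpoint-inhibitor cohort sequenced at
#' 200x: 2-4 clones per tumor (truncal clone at CCF 1, subclones
#' separated by at least 0.15), 10-30 mutations per clone, purity
#' 0.5-0.9. Elimination clones carry a low neoantigenic fraction (0.2)
#' and escape clones a high one (0.8), so at the simulation editing
#' cutoff of 0.5 the planted stages are recoverable from the tallies.
#' Response follows a logistic model on log10(ioTNL + 0.01); survival is
#' exponential with response-specific medians and independent
#' exponential censoring.
#'
#' @param n_patients cohort size.
#' @param clones_range integer range for clones per patient.
#' @param ccf_min_sep minimum CCF separation between clones.
#' @param subclone_ccf_range CCF range subclonal clones are drawn from.
#' @param mutations_per_clone integer range of mutations per clone.
#' @param silent_frac fraction of mutations that are silent/noncoding.
#' @param neo_frac_elimination,neo_frac_escape neoantigenic fraction of a
#'   clone's non-silent mutations by planted stage.
#' @param p_escape probability a clone is planted as immune escape.
#' @param editing_cutoff editing-score cutoff used for truth labels and
#'   downstream scoring of simulated tumors.
#' @param depth mean sequencing depth.
#' @param purity_range tumor purity range.
#' @param response_intercept,response_slope logistic link for objective
#'   response on log10(ioTNL + 0.01).
#' @param dcb_intercept logistic intercept for durable clinical benefit
#'   among non-responders (responders are DCB with probability
#'   `dcb_given_orr`).
#' @param dcb_given_orr P(DCB | objective response).
#' @param surv_median_responder,surv_median_nonresponder median PFS
#'   (days) by response group.
#' @param censor_rate expected fraction of censored patients.
#' @param region_mb region size for TMB (Mb).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 100,
                       clones_range = c(2L, 4L),
                       ccf_min_sep = 0.15,
                       subclone_ccf_range = c(0.1, 0.85),
                       mutations_per_clone = c(10L, 30L),
                       silent_frac = 0.15,
                       neo_frac_elimination = 0.2,
                       neo_frac_escape = 0.8,
                       p_escape = 0.4,
                       editing_cutoff = 0.5,
                       depth = 200L,
                       purity_range = c(0.5, 0.9),
                       response_intercept = -1,
                       response_slope = 2,
                       dcb_intercept = -1.5,
                       dcb_given_orr = 0.9,
                       surv_median_responder = 300,
                       surv_median_nonresponder = 100,
                       censor_rate = 0.2,
                       region_mb = 30) {
  cfg <- as.list(environment())
  stopifnot(cfg$depth >= 1,
            all(c(cfg$silent_frac, cfg$neo_frac_elimination,
                  cfg$neo_frac_escape, cfg$p_escape,
                  cfg$censor_rate) >= 0),
            all(c(cfg$silent_frac, cfg$neo_frac_elimination,
                  cfg$neo_frac_escape, cfg$p_escape,
                  cfg$censor_rate) <= 1))
  structure(cfg, class = "sim_config")
}

# Draw descending clone CCFs: truncal clone at 1, subclones in the
# configured range with minimum separation (sequential shrink).
draw_clone_ccfs <- function(n_clones, config) {
  ccfs <- 1
  lo <- config$subclone_ccf_range[1]
  for (k in seq_len(n_clones - 1)) {
    hi <- ccfs[length(ccfs)] - config$ccf_min_sep
    if (hi <= lo) hi <- lo + 1e-3
    ccfs <- c(ccfs, stats::runif(1, lo, hi))
  }
  sort(ccfs, decreasing = TRUE)
}

#' Simulate one clonal tumor with planted immunoediting structure
#'
#' Draws clone CCFs (truncal clone at 1), per-clone mutation counts and
#' planted elimination/escape stages, then generates mutation-level read
#' counts as binomial(depth, expected VAF) with expected VAF =
#' purity * ccf * m / (purity * CN_t + (1 - purity) * 2) (diploid tumor,
#' multiplicity 1). The number of neoantigenic mutations in a clone is
#' `round(fraction * n_nonsilent)` with the fraction set by the planted
#' stage, so the truth ioTNL follows in closed form from the planted
#' labels.
#'
#' All structural arguments can be overridden to construct specific
#' tumors (e.g. a fixed three-clone example).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param patient_id identifier for the emitted table.
#' @param clone_ccfs optional fixed clone CCFs (descending).
#' @param clone_stages optional fixed stages (`"elimination"`/`"escape"`).
#' @param mutations_per_clone optional fixed per-clone mutation counts.
#' @param neo_counts optional fixed per-clone neoantigenic-mutation
#'   counts (overrides the stage fractions).
#' @param silent_frac optional override of the silent fraction.
#' @param depth optional override of sequencing depth.
#' @param purity optional fixed purity.
#' @param exact_counts if TRUE, alt counts are `round(depth * expected
#'   VAF)` instead of binomial draws (the noiseless limit, for
#'   consistency checks).
#' @return a list with `mutations` (data.frame: id, chrom, pos, ref,
#'   alt, effect, depth, alt_count, vaf, cn_major, cn_minor,
#'   is_neoantigenic, n_epitopes, true_clone) and `truth` (purity, clone
#'   CCFs, stages, per-clone tallies, labels, truth TNL and ioTNL).
#' @export
simulate_patient <- function(config = sim_config(), seed = 1L,
                             patient_id = "P1",
                             clone_ccfs = NULL, clone_stages = NULL,
                             mutations_per_clone = NULL, neo_counts = NULL,
                             silent_frac = NULL, depth = NULL,
                             purity = NULL, exact_counts = FALSE) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  silent_frac <- silent_frac %||% config$silent_frac
  depth <- depth %||% config$depth
  purity <- purity %||% stats::runif(1, config$purity_range[1],
                                     config$purity_range[2])
  if (is.null(clone_ccfs)) {
    n_clones <- sample(seq(config$clones_range[1], config$clones_range[2]), 1)
    clone_ccfs <- draw_clone_ccfs(n_clones, config)
  }
  n_clones <- length(clone_ccfs)
  if (is.null(clone_stages)) {
    clone_stages <- ifelse(stats::runif(n_clones) < config$p_escape,
                           "escape", "elimination")
  }
  if (is.null(mutations_per_clone)) {
    mutations_per_clone <- sample(
      seq(config$mutations_per_clone[1], config$mutations_per_clone[2]),
      n_clones, replace = TRUE)
  }
  mutations_per_clone <- rep_len(mutations_per_clone, n_clones)

  rows <- vector("list", n_clones)
  clone_neo <- integer(n_clones)
  clone_nonsil <- integer(n_clones)
  pos0 <- 0
  for (k in seq_len(n_clones)) {
    nmut <- mutations_per_clone[k]
    effect <- ifelse(stats::runif(nmut) < silent_frac,
                     sample(c("silent", "noncoding"), nmut, replace = TRUE),
                     sample(c("missense", "nonsense", "frameshift_indel",
                              "splice"), nmut, replace = TRUE,
                            prob = c(0.8, 0.08, 0.08, 0.04)))
    nonsil <- which(is_nonsilent(effect))
    frac <- if (clone_stages[k] == "escape") config$neo_frac_escape
            else config$neo_frac_elimination
    n_neo <- if (!is.null(neo_counts)) neo_counts[k]
             else round(frac * length(nonsil))
    n_neo <- min(n_neo, length(nonsil))
    neo_idx <- if (n_neo > 0) sample(nonsil, n_neo) else integer(0)
    is_neo <- seq_len(nmut) %in% neo_idx
    evaf <- purity * clone_ccfs[k] /
      (purity * 2 + (1 - purity) * 2)  # diploid, multiplicity 1
    d <- rep(depth, nmut)
    alt <- if (exact_counts) round(d * evaf) else stats::rbinom(nmut, d, evaf)
    rows[[k]] <- data.frame(
      id = sprintf("%s_c%d_m%03d", patient_id, k, seq_len(nmut)),
      chrom = sample(paste0("chr", 1:22), nmut, replace = TRUE),
      pos = pos0 + seq_len(nmut) * 1000L,
      ref = sample(c("A", "C", "G", "T"), nmut, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), nmut, replace = TRUE),
      effect = effect,
      depth = d, alt_count = alt, vaf = alt / d,
      cn_major = 1L, cn_minor = 1L,
      is_neoantigenic = is_neo,
      n_epitopes = ifelse(is_neo, stats::rpois(nmut, 2) + 1L, 0L),
      true_clone = k)
    pos0 <- pos0 + nmut * 1000L
    clone_neo[k] <- n_neo
    clone_nonsil[k] <- length(nonsil)
  }
  mutations <- do.call(rbind, rows)
  rownames(mutations) <- NULL
  true_scores <- immune_editing_score(clone_neo, clone_nonsil)
  elim <- clone_stages == "elimination"
  truth <- list(patient_id = patient_id,
                purity = purity,
                clone_ccfs = clone_ccfs,
                clone_stages = clone_stages,
                clone_n_nonsilent = clone_nonsil,
                clone_n_neoantigen = clone_neo,
                clone_editing_scores = true_scores,
                labels = mutations$true_clone,
                tnl = sum(clone_neo),
                iotnl = sum(clone_neo[elim] * clone_ccfs[elim]))
  list(mutations = mutations, truth = truth)
}

#' Simulate a cohort with outcomes linked to the ioTNL
#'
#' Simulates `n_patients` tumors via [simulate_patient()], then draws
#' objective response from a logistic model on log10(truth ioTNL + 0.01),
#' durable clinical benefit correlated with response, and exponential
#' progression-free/overall survival with response-specific medians and
#' independent exponential censoring.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a list with `cohort` (data.frame: patient_id, iotnl, tnl,
#'   tmb, log10_iotnl, response, orr_label, dcb_label, pfs_days,
#'   pfs_event, os_days, os_event), `patients` (per-patient
#'   [simulate_patient()] outputs) and `truth` (list of truth records).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- config$n_patients
  patient_seeds <- sample.int(2^30, n)
  outcome_seed <- sample.int(2^30, 1)
  patients <- lapply(seq_len(n), function(i) {
    simulate_patient(config, seed = patient_seeds[i],
                     patient_id = sprintf("P%03d", i))
  })
  set.seed(outcome_seed)
  iotnl <- vapply(patients, function(p) p$truth$iotnl, numeric(1))
  tnl <- vapply(patients, function(p) p$truth$tnl, numeric(1))
  tmb <- vapply(patients, function(p) {
    compute_tmb(p$mutations, config$region_mb)
  }, numeric(1))
  x <- log10(iotnl + 0.01)
  p_orr <- stats::plogis(config$response_intercept + config$response_slope * x)
  orr <- stats::runif(n) < p_orr
  response <- ifelse(orr,
                     sample(c("CR", "PR"), n, replace = TRUE,
                            prob = c(0.25, 0.75)),
                     sample(c("SD", "PD"), n, replace = TRUE))
  p_dcb <- stats::plogis(config$dcb_intercept + config$response_slope * x)
  dcb <- ifelse(orr, stats::runif(n) < config$dcb_given_orr,
                stats::runif(n) < p_dcb)
  med <- ifelse(orr, config$surv_median_responder,
                config$surv_median_nonresponder)
  haz <- log(2) / med
  t_event <- stats::rexp(n, haz)
  cens_haz <- haz * config$censor_rate / max(1 - config$censor_rate, 1e-6)
  t_cens <- if (config$censor_rate > 0) stats::rexp(n, cens_haz) else
    rep(Inf, n)
  pfs <- pmin(t_event, t_cens)
  pfs_event <- as.integer(t_event <= t_cens)
  os_event_t <- t_event * stats::runif(n, 1.5, 2.5)
  os_cens <- if (config$censor_rate > 0) stats::rexp(n, cens_haz / 2) else
    rep(Inf, n)
  os <- pmin(os_event_t, os_cens)
  os_event <- as.integer(os_event_t <= os_cens)
  cohort <- data.frame(
    patient_id = vapply(patients, function(p) p$truth$patient_id,
                        character(1)),
    iotnl = iotnl, tnl = tnl, tmb = tmb,
    log10_iotnl = x,
    response = response,
    orr_label = ifelse(orr, "ORR", "NOR"),
    dcb_label = ifelse(dcb, "DCB", "NDB"),
    pfs_days = round(pfs, 1), pfs_event = pfs_event,
    os_days = round(os, 1), os_event = os_event)
  list(cohort = cohort, patients = patients,
       truth = lapply(patients, `[[`, "truth"))
}

#' Simulate candidate-variant read fixtures with planted filter violations
#'
#' Generates SNV candidates whose read-level evidence either passes all
#' eight somatic filter criteria by construction ("clean" variants) or is
#' planted to violate one named criterion. Clean variants draw tumor
#' depth 80-150 at VAF 0.2-0.45, zero normal alt reads at depth 40-80,
#' mutant mapping qualities 50-60, base qualities 30-38, and mutant read-
#' end distances shifted above the reference distances, so each
#' criterion holds with certainty. Violators override exactly the fields
#' the criterion tests (a planted violation can incidentally trip other
#' criteria; the truth records the planted one).
#'
#' @param n_variants total number of candidates.
#' @param violation_mix named proportions over criteria
#'   `c(I=, II=, ..., VIII=)`; must sum to at most 1. Criterion IV
#'   violators are generated in adjacent pairs (both members planted).
#' @param seed integer seed.
#' @return a list with `candidates` (a [candidate_variants()] table) and
#'   `truth` (data.frame: id, planted criterion or "none").
#' @export
simulate_read_fixture <- function(n_variants,
                                  violation_mix = c(I = 0, II = 0, III = 0,
                                                    IV = 0, V = 0, VI = 0,
                                                    VII = 0, VIII = 0),
                                  seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  crits <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  mix <- stats::setNames(rep(0, 8), crits)
  mix[names(violation_mix)] <- violation_mix
  if (sum(mix) > 1 + 1e-9) stopf("violation proportions must sum to <= 1")
  counts <- round(mix * n_variants)
  counts["IV"] <- 2 * (counts["IV"] %/% 2)  # pairs
  if (sum(counts) > n_variants) stopf("violation counts exceed n_variants")
  planted <- c(rep(crits, counts), rep("none", n_variants - sum(counts)))

  clean_variant <- function(i) {
    d <- sample(80:150, 1)
    alt <- round(d * stats::runif(1, 0.2, 0.45))
    nd <- sample(40:80, 1)
    list(pos = i * 1000L, tumor_depth = d, tumor_alt_count = alt,
         normal_depth = nd, normal_alt_count = 0L,
         mapq = sample(50:60, alt, replace = TRUE),
         baseq = sample(30:38, alt, replace = TRUE),
         mend = sample(25:75, alt, replace = TRUE),
         rend = sample(10:50, d - alt, replace = TRUE))
  }
  n <- length(planted)
  vars <- lapply(seq_len(n), clean_variant)
  iv_pair_offset <- TRUE
  for (i in seq_len(n)) {
    v <- vars[[i]]
    switch(planted[i],
      I = { v$tumor_depth <- sample(5:9, 1)
            v$tumor_alt_count <- 3L
            v$mapq <- v$mapq[1:3]; v$baseq <- v$baseq[1:3]
            v$mend <- v$mend[1:3]
            v$rend <- v$rend[seq_len(v$tumor_depth - 3)] },
      II = { v$normal_alt_count <- max(2L, round(0.04 * v$normal_depth)) },
      III = { v$tumor_depth <- 40L; v$tumor_alt_count <- 2L
              v$mapq <- v$mapq[1:2]; v$baseq <- v$baseq[1:2]
              v$mend <- v$mend[1:2]; v$rend <- v$rend[1:38] },
      IV = { # second member of each pair sits 5 bp after the first
             if (!iv_pair_offset) v$pos <- vars[[i - 1L]]$pos + 5L
             iv_pair_offset <- !iv_pair_offset },
      V = { v$mapq <- sample(20:30, v$tumor_alt_count, replace = TRUE) },
      VI = { v$baseq <- sample(12:20, v$tumor_alt_count, replace = TRUE) },
      VII = { v$mend <- sample(1:5, v$tumor_alt_count, replace = TRUE) },
      VIII = { v$tumor_depth <- 100L
               v$tumor_alt_count <- sample(5:6, 1)
               v$normal_depth <- 12L; v$normal_alt_count <- 0L
               alt <- v$tumor_alt_count
               v$mapq <- sample(50:60, alt, replace = TRUE)
               v$baseq <- sample(30:38, alt, replace = TRUE)
               v$mend <- sample(25:75, alt, replace = TRUE)
               v$rend <- sample(10:50, 100 - alt, replace = TRUE) },
      none = NULL)
    vars[[i]] <- v
  }
  candidates <- data.frame(
    id = sprintf("fix%04d", seq_len(n)),
    chrom = "chr1",
    pos = vapply(vars, `[[`, numeric(1), "pos"),
    ref = "C", alt = "T",
    variant_class = "SNV", effect = "missense",
    tumor_depth = vapply(vars, `[[`, numeric(1), "tumor_depth"),
    tumor_alt_count = vapply(vars, `[[`, numeric(1), "tumor_alt_count"),
    normal_depth = vapply(vars, `[[`, numeric(1), "normal_depth"),
    normal_alt_count = vapply(vars, `[[`, numeric(1), "normal_alt_count"))
  candidates$mutant_mapqs <- I(lapply(vars, `[[`, "mapq"))
  candidates$mutant_baseqs <- I(lapply(vars, `[[`, "baseq"))
  candidates$mutant_end_distances <- I(lapply(vars, `[[`, "mend"))
  candidates$ref_end_distances <- I(lapply(vars, `[[`, "rend"))
  list(candidates = candidate_variants(candidates),
       truth = data.frame(id = candidates$id, planted = planted))
}
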