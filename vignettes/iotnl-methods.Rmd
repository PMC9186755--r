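---
title: "The immunoediting-optimized tumor neoantigen load: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The immunoediting-optimized tumor neoantigen load: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioTNL)
```

## The model

Checkpoint-inhibitor response correlates with how much tumor-specific
antigen the immune system can still act on. The total neoantigen load
(TNL) treats every predicted neoantigen equally, but a tumor is a
mixture of clones, and clones that have already been immunoedited —
that have escaped T-cell surveillance despite carrying neoantigens — no
longer contribute to immunogenicity. The ioTNL
(immunoediting-optimized tumor neoantigen load) restricts the
neoantigen count to clones that still look subject to immune
elimination, and weights each clone's contribution by its cancer cell
fraction (CCF), so truncal neoantigens count more than private ones.

Three quantities define the score. For each clone $i$:

* the **immune editing score** is the ratio of neoantigen(-bearing) to
  non-silent mutations,
  $\mathrm{score}_i = n^{neo}_i / n^{nonsilent}_i$;
* the clone is in the **immune escape** stage when its score exceeds a
  cutoff $c$, and in the **immune elimination** stage otherwise (ties
  at the cutoff count as elimination, since escape is the
  strict-inequality, "high score" class);
* the patient's score is
  $\mathrm{ioTNL} = \sum_{i \,\in\, \mathrm{elimination}}
  \mathrm{load}_i \times \mathrm{CCF}_i$,
  with $\mathrm{load}_i$ the clone's neoantigen count.

TNL is $\sum_i \mathrm{load}_i$ over all clones, so
$0 \le \mathrm{ioTNL} \le \mathrm{TNL}$ always holds under the default
counting unit. For reporting and plotting we use
$\log_{10}(\mathrm{ioTNL} + 0.01)$, the small offset keeping
zero-score patients finite; the raw score is always emitted too.

A worked example: a tumor with three clones, where clones 1 and 2
(CCFs 1.0 and 0.1) each carry one neoantigen and remain subject to
elimination, while clone 3 (CCF 0.05) carries three neoantigens but is
fully immunoedited. TNL counts all five neoantigens; ioTNL keeps only
the elimination clones, $1 \times 1.0 + 1 \times 0.1 = 1.1$.

```{r toy}
sim <- simulate_patient(
  sim_config(), seed = 1,
  clone_ccfs = c(1.0, 0.1, 0.05),
  clone_stages = c("elimination", "elimination", "escape"),
  mutations_per_clone = c(4, 3, 3), neo_counts = c(1, 1, 3),
  silent_frac = 0, depth = 10000, purity = 1, exact_counts = TRUE)
mut <- add_ccf(sim$mutations, purity = 1)
clones <- accept_precomputed_clusters(
  mut, stats::setNames(mut$true_clone, mut$id))
compute_iotnl(clones, cutoff = 0.9)
```

### The neoantigen counting unit

"Number of neoantigens" is ambiguous between neoantigenic *mutations*
(a mutation with at least one predicted HLA class I binder among its
8–11-mer peptides) and binder *peptides* (one mutation can yield
several). The default is mutation-level counting, which keeps
ioTNL ≤ TNL and the editing score in $[0, 1]$; `count_unit =
"peptide"` switches both the load and the editing score to peptide
tallies, under which scores above 1 (clones whose mutations each
generate several binders) become possible — this matches landscape
analyses where per-clone editing scores range up to ~10 with a median
near 1. The binder definition is %rank ≤ 2.0 or affinity ≤ 500 nM
(NetMHCpan conventions), both configurable in
`annotate_neoantigens()`; an optional `expressed` column in the
epitope table masks unexpressed peptides, but no expression model is
built into the package.

### The editing-score cutoff

When response labels are available, the cutoff is chosen by grid
search over 0.5–1.5 in steps of 0.1 (`optimize_editing_cutoff()`),
recomputing every patient's ioTNL at each candidate and keeping the
cutoff whose ioTNL maximizes the ROC AUC against the chosen label
(ties go to the smaller cutoff). Without labels the default is 1.0,
consistent with a landscape median editing score of about 1 under
peptide counting. Note that under mutation-level counting scores never
exceed 1, so only the 0.5–1.0 half of the grid is active; simulated
studies in this package therefore plant their structure around a
cutoff of 0.5.

## From reads to clones

### Somatic variant filtering

`filter_snvs()` applies eight read-evidence criteria (coverage ≥ 10×
in tumor and normal; tumor VAF ≥ 5% with normal VAF < 2%; ≥ 3 mutant
reads; > 10 bp spacing between candidate SNVs; mutant mapping
qualities significantly above 30 and base qualities above 20;
no enrichment of mutant reads near read ends; a significant
tumor-vs-normal Fisher contrast). Two constructions deserve comment,
because a "rank sum test against a constant" is not a defined
two-sample procedure:

* Criteria V/VI are implemented as one-sided Wilcoxon *signed-rank*
  tests of (quality − threshold), zeros dropped (Pratt handling
  available via `zero_method = "pratt"`), exact null for n ≤ 25
  without ties and the corrected normal approximation otherwise. This
  is the closest well-defined test to the stated intent; it is a
  documented choice, not a claim about any external tool's internals.
* Criterion VII compares mutant-read against reference-read distances
  to the nearer read end with a one-sided rank-sum test for "mutant
  closer"; the variant fails at p < 0.1. The 5 bp figure is kept as a
  reported diagnostic (`end_prox_frac`, the fraction of mutant reads
  within 5 bp of an end), not as a hard cutoff.

Variants missing evidence vectors fail with a distinct
`insufficient_evidence` tally rather than aborting the batch, and both
members of a too-close pair fail the spacing criterion. InDels pass at
tumor VAF ≥ 10% without a germline flag. Filtering is
order-independent and equals the intersection of the criteria applied
in isolation, which the test suite checks against stand-alone
per-criterion oracles.

### CCF estimation

For a mutation with VAF $f$, purity $\rho$, tumor allele-specific copy
numbers $(CN_M, CN_m)$ and normal copy number $CN_n$, the CCF at
multiplicity $m$ is
$f \cdot (\rho\,CN_t + (1-\rho)\,CN_n) / (\rho\, m)$ with
$CN_t = CN_M + CN_m$. Candidate multiplicities $1..CN_M$ are scanned;
the one whose implied CCF lies closest to $[0,1]$ wins (preferring
CCF ≤ 1, the largest $m$ on ties), and the result is clipped to
$[0,1]$. When copy number is missing the tumor is assumed diploid
(1+1); when purity is missing it is estimated as twice the 95th VAF
percentile capped at 1, and flagged.

### Clone clustering

External Dirichlet-process reconstruction (PyClone-style MCMC) is
deliberately not reproduced: the downstream score depends only on the
partition and the clone CCFs, so the package uses a deterministic 1-D
mixture with BIC model selection. When read counts are available the
component likelihood is binomial — mutation $j$'s expected VAF at
clone CCF $\varphi$ is $s_j \varphi$, with $s_j = f_j/\mathrm{ccf}_j$
the mutation's own purity/copy-number scaling — and Gaussian on the
CCFs otherwise. Components are initialized at CCF quantiles (no random
restarts, hence deterministic), the mixture is fit by EM for
$k = 1..K_{max}$ (default 6), and BIC picks $k$ with ties to the
smaller model. The clone CCF is the *median* member CCF (robust to
occasional multiplicity mis-calls), clusters are ordered by decreasing
CCF with cluster 1 the truncal clone. Silent and non-coding mutations
participate in clustering — they inform the clone structure — but only
non-silent ones enter the editing-score denominators.
`accept_precomputed_clusters()` is the import path for assignments
made by external tools.

BIC at modest depth is conservative: closely spaced clones (CCF
separation near the simulation minimum of 0.15 at depth 200) are
sometimes merged. This biases the recovered clone count down but
perturbs ioTNL only when a merge mixes stages; end-to-end recovery is
quantified below.

## Cohort statistics

Group comparisons use the two-sided Fisher exact test
(minimum-likelihood definition — the sum of all hypergeometric
probabilities no larger than the observed table's; this is what
`stats::fisher.test` computes and what reproduces the reported
cohort p-values) and the Mann–Whitney U test (exact for combined
n ≤ 20 without ties). ROC AUC is the tie-adjusted concordance
probability; the Youden cutoff scans midpoints of adjacent sorted
unique scores plus infinite sentinels, maximizing
sensitivity + specificity − 1 with ties to the smallest cutoff.
Survival uses Kaplan–Meier product-limit curves (median = first time
the curve reaches 0.5; "not reached" is reported as `NA`), the
unweighted log-rank test, and univariable Cox regression with Efron
tie handling; monotone-likelihood separation is flagged with an
unbounded CI instead of a spurious estimate. All tests are two-tailed
at $\alpha = 0.05$ with no multiple-testing correction. Response
analyses drop non-evaluable (NE) patients; survival keeps every
patient with a follow-up time — which is why dichotomization group
sizes can be smaller than the enrolled cohort. Both Pearson and
Spearman correlations are provided; the caller chooses.

## The synthetic-data generators

`simulate_patient()` emulates a sequenced tumor: a truncal clone at
CCF 1 plus subclones separated by ≥ 0.15, 10–30 mutations per clone,
purity 0.5–0.9, and read counts drawn binomially at the expected VAF
$\rho\,\mathrm{ccf}\,m/(\rho\,CN_t + (1-\rho)2)$ — the same
observation model the CCF estimator inverts, on a diploid genome
where the multiplicity is identifiable. Escape clones are planted with
a high neoantigenic fraction (0.8) and elimination clones low (0.2),
mirroring the model's direction (high editing score = escape); the
counts are `round(fraction × n_nonsilent)`, so truth TNL/ioTNL follow
in closed form from the planted labels. With fractions 0.2/0.8 the
planted stages are recoverable at the simulation cutoff of 0.5 under
mutation-level counting. `simulate_cohort()` links outcomes to the
truth score: objective response is Bernoulli with success probability
$\mathrm{logit}^{-1}(\beta_0 + \beta_1 \log_{10}(\mathrm{ioTNL} +
0.01))$ (defaults −1 and 2, a strong but realistic biomarker), durable
clinical benefit is correlated with response (P(DCB | ORR) = 0.9),
and survival is exponential with response-specific medians (300 vs
100 days) under independent exponential censoring (20%).
`simulate_read_fixture()` plants named filter violations by
construction — e.g. depth ≤ 9 for coverage violators — while clean
variants are built to pass every criterion with certainty (mutant
end-distances are drawn stochastically above the reference
distribution, so the rank-sum criterion cannot fire against them).

What the generators do *not* emulate: mutational signatures and
genome-wide positional structure, subclonal copy number, sample
contamination, caller-specific artifact modes, multi-region or
longitudinal sampling, and any real linkage between mutation identity
and HLA binding (neoantigenic flags are planted, not predicted).
Passing recovery tests therefore demonstrates internal consistency of
the estimator chain on its own observation model, not performance on
real cohorts.

## Numerical choices and problem sizes

* Editing score of a clone with no non-silent mutations is defined as
  0 (it can hold no neoantigens, and is marked degenerate).
* ioTNL invariants — monotonicity in the cutoff, additivity of one
  extra neoantigen (+CCF), ioTNL ≤ TNL — are enforced by tests against
  per-mutation brute-force summation.
* EM convergence: relative log-likelihood change < 1e-8, ≤ 300
  iterations; component CCFs optimized on [1e-4, 1]; Gaussian
  component standard deviations floored at 0.01.
* Validation problem sizes were chosen to characterize the estimators
  at desk scale: 50 seeded three-clone tumors at depth 200 for
  CCF/partition recovery (mean absolute CCF error ≤ 0.05, mean
  adjusted Rand index ≥ 0.9), a 200-patient cohort for planted-cutoff
  recovery, 500 patients for Cox hazard-ratio recovery at a true HR of
  2, and 1000 replicates for type-I calibration. Calibration uses two
  binomial(150, 0.4) arms for the Fisher test — the exact test is
  conservative on small tables, and at this size its rejection rate
  sits at the nominal level — and two normal samples of 30 for the
  Mann–Whitney test.

## Known limitations

* The clustering stand-in has no notion of the copy-number priors an
  MCMC reconstruction would use; in copy-number-poor samples the
  diploid fallback is a convention, not an inference.
* Mutation-level and peptide-level counting can disagree on stage
  assignments for the same tumor; comparisons across cohorts must fix
  the unit.
* The editing-score direction (high = escape) follows the model's
  definition; depletion-based immunoediting metrics in other work
  orient the opposite way, so scores are not transferable between
  conventions.
* A reference-set ("expected vs observed") editing-score variant is
  intentionally not implemented; the refless ratio is the model.
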