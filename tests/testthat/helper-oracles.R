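# Independent brute-force oracles used to check the package's
# implementations. These deliberately use the most direct computation
# available (full enumeration, double loops), not the algorithms under
# test.

# Exact one-sided signed-rank tail by enumerating all 2^n sign
# assignments of the absolute differences (zeros dropped).
signed_rank_enum <- function(values, threshold) {
  d <- values - threshold
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  mean(w_all >= w_obs)
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins (minimum-likelihood definition).
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by counting concordant positive-negative pairs (ties 1/2).
auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# Exhaustive Youden scan over a dense threshold set.
youden_scan <- function(scores, pos) {
  cand <- sort(unique(c(-Inf, scores, scores - 1e-9, Inf)))
  j <- vapply(cand, function(ct) {
    mean(scores[pos] > ct) + mean(scores[!pos] <= ct) - 1
  }, numeric(1))
  list(max_j = max(j))
}

# ioTNL by iterating over individual neoantigenic mutations: each adds
# its clone's CCF when the clone is in the elimination stage.
iotnl_brute <- function(mutations, clone_ccf, clone_stage) {
  tot <- 0
  for (i in seq_len(nrow(mutations))) {
    k <- mutations$true_clone[i]
    if (mutations$is_neoantigenic[i] &&
        is_nonsilent(mutations$effect[i]) &&
        clone_stage[k] == "elimination") {
      tot <- tot + clone_ccf[k]
    }
  }
  tot
}

# Unweighted two-group log-rank by an explicit risk-table walk.
logrank_oracle <- function(time, event, group) {
  group <- as.integer(factor(group))
  ev_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (o1 - e1)^2 / v
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

# Per-criterion somatic SNV checkers applied in isolation (direct
# restatement of the filtering rules; IV via an all-pairs double loop).
snv_criterion_pass <- function(cands, crit) {
  n <- nrow(cands)
  tvaf <- cands$tumor_alt_count / cands$tumor_depth
  nvaf <- cands$normal_alt_count / cands$normal_depth
  switch(crit,
    I = cands$tumor_depth >= 10 & cands$normal_depth >= 10,
    II = tvaf >= 0.05 & nvaf < 0.02,
    III = cands$tumor_alt_count >= 3,
    IV = {
      ok <- rep(TRUE, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j && cands$chrom[i] == cands$chrom[j] &&
            abs(cands$pos[i] - cands$pos[j]) <= 10) ok[i] <- FALSE
      }
      ok
    },
    V = vapply(seq_len(n), function(i) {
      rank_test_vs_threshold(cands$mutant_mapqs[[i]], 30) < 0.2
    }, logical(1)),
    VI = vapply(seq_len(n), function(i) {
      rank_test_vs_threshold(cands$mutant_baseqs[[i]], 20) < 0.05
    }, logical(1)),
    VII = vapply(seq_len(n), function(i) {
      suppressWarnings(stats::wilcox.test(
        cands$mutant_end_distances[[i]], cands$ref_end_distances[[i]],
        alternative = "less")$p.value) >= 0.1
    }, logical(1)),
    VIII = vapply(seq_len(n), function(i) {
      tab <- matrix(c(cands$tumor_alt_count[i],
                      cands$tumor_depth[i] - cands$tumor_alt_count[i],
                      cands$normal_alt_count[i],
                      cands$normal_depth[i] - cands$normal_alt_count[i]),
                    2, byrow = TRUE)
      stats::fisher.test(tab)$p.value < 0.05
    }, logical(1)))
}

# A hand-built clone_clusters table (bypasses clustering).
make_clones <- function(ccf, n_nonsilent, n_neoantigen,
                        n_epitopes = n_neoantigen) {
  k <- length(ccf)
  cl <- data.frame(cluster_id = seq_len(k), ccf = ccf,
                   n_mutations = n_nonsilent, n_nonsilent = n_nonsilent,
                   n_neoantigen = n_neoantigen, n_epitopes = n_epitopes,
                   editing_score = NA_real_, stage = NA_character_)
  cl$member_ids <- I(as.list(paste0("m", seq_len(k))))
  class(cl) <- c("clone_clusters", "data.frame")
  cl
}
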