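# Cancer cell fraction estimation and clone clustering.
#
# The CCF of a mutation is its VAF corrected for tumor purity and local
# copy number; mutations sharing a CCF are interpreted as one clone.
# Clustering is a deterministic 1-D mixture model selected by BIC; an
# import path accepts cluster assignments from external subclonal
# reconstruction tools.

#' Estimate mutation multiplicity and cancer cell fraction
#'
#' For candidate multiplicities m = 1..cn_major, the CCF implied by the
#' observed VAF is
#' \deqn{ccf_m = vaf (purity \cdot CN_t + (1-purity) \cdot CN_n) /
#'   (purity \cdot m)}
#' with CN_t = cn_major + cn_minor the tumor total copy number and CN_n
#' the normal copy number. The multiplicity whose implied CCF is closest
#' to the unit interval is chosen (preferring ccf <= 1; the largest m
#' breaks ties) and the CCF is clipped to [0, 1].
#'
#' @param vaf tumor variant allele fraction(s) in [0, 1].
#' @param purity tumor purity in (0, 1].
#' @param cn_major,cn_minor allele-specific tumor copy numbers
#'   (cn_major >= 1); recycled against `vaf`.
#' @param normal_cn copy number in the normal (2 autosomal, 1 for male
#'   sex chromosomes).
#' @return a data.frame with columns `multiplicity` and `ccf`.
#' @export
estimate_ccf <- function(vaf, purity, cn_major = 1L, cn_minor = 1L,
                         normal_cn = 2L) {
  if (any(purity <= 0) || any(purity > 1)) {
    stopf("purity must be in (0, 1]; CCF is undefined at purity 0")
  }
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) stopf("vaf must be in [0, 1]")
  if (any(cn_major < 1)) stopf("cn_major must be >= 1")
  if (!all(normal_cn %in% c(1L, 2L))) stopf("normal_cn must be 1 or 2")
  n <- length(vaf)
  cn_major <- rep_len(cn_major, n)
  cn_minor <- rep_len(cn_minor, n)
  normal_cn <- rep_len(normal_cn, n)
  purity <- rep_len(purity, n)
  mult <- integer(n)
  ccf <- numeric(n)
  for (i in seq_len(n)) {
    m_cand <- seq_len(cn_major[i])
    cn_t <- cn_major[i] + cn_minor[i]
    ccf_m <- vaf[i] * (purity[i] * cn_t + (1 - purity[i]) * normal_cn[i]) /
      (purity[i] * m_cand)
    dist <- pmax(0, ccf_m - 1)  # distance to [0,1]; ccf_m >= 0 always
    best <- which(dist == min(dist))
    pick <- max(best)  # largest m among ties (all implied ccf <= 1 ties at 0)
    mult[i] <- m_cand[pick]
    ccf[i] <- min(max(ccf_m[pick], 0), 1)
  }
  data.frame(multiplicity = mult, ccf = ccf)
}

#' Add multiplicity and CCF columns to a mutation table
#'
#' Applies [estimate_ccf()] row-wise. When `cn_major`/`cn_minor` columns
#' are absent the tumor is assumed diploid (1+1); when `purity` is `NULL`
#' it is estimated as twice the 95th percentile of the VAF, capped at 1,
#' and the result is flagged via the `purity_estimated` attribute.
#'
#' @param mutations data.frame with at least `vaf`; optionally
#'   `cn_major`, `cn_minor`, `normal_cn`.
#' @param purity scalar tumor purity, or `NULL` to estimate.
#' @return `mutations` with `multiplicity` and `ccf` columns and
#'   attributes `purity` and `purity_estimated`.
#' @export
add_ccf <- function(mutations, purity = NULL) {
  estimated <- is.null(purity)
  if (estimated) {
    purity <- min(1, 2 * stats::quantile(mutations$vaf, 0.95, names = FALSE))
    if (purity <= 0) stopf("cannot estimate purity: all VAFs are zero")
  }
  if (!"cn_major" %in% names(mutations)) mutations$cn_major <- 1L
  if (!"cn_minor" %in% names(mutations)) mutations$cn_minor <- 1L
  cn_major <- ifelse(is.na(mutations$cn_major), 1L, mutations$cn_major)
  cn_minor <- ifelse(is.na(mutations$cn_minor), 1L, mutations$cn_minor)
  normal_cn <- if ("normal_cn" %in% names(mutations)) {
    ifelse(is.na(mutations$normal_cn), 2L, mutations$normal_cn)
  } else 2L
  est <- estimate_ccf(mutations$vaf, purity, cn_major, cn_minor, normal_cn)
  mutations$multiplicity <- est$multiplicity
  mutations$ccf <- est$ccf
  attr(mutations, "purity") <- purity
  attr(mutations, "purity_estimated") <- estimated
  mutations
}

#' Cluster mutations into clones by cancer cell fraction
#'
#' Fits 1-D mixture models with 1..`max_clusters` components to the
#' per-mutation CCFs and selects the component count by BIC (ties go to
#' the smaller model). When `alt_count` and `depth` columns are present
#' the component likelihood is binomial on the read counts, with each
#' mutation's expected VAF scaling linearly in the clone CCF; otherwise
#' a Gaussian mixture on the CCF values is used. Initialization is by
#' CCF quantiles, so the fit is deterministic.
#'
#' @param mutations data.frame of somatic mutations with a `ccf` column
#'   (see [add_ccf()]); `effect` and `is_neoantigenic` columns feed the
#'   per-clone tallies.
#' @param max_clusters maximum number of clones to consider.
#' @param seed integer seed (the fit itself is deterministic; the seed is
#'   recorded and fixed for reproducibility of any downstream draws).
#' @param method `"auto"` (default), `"binomial"` or `"gaussian"`.
#' @return a `clone_clusters` data.frame: one row per clone, ordered by
#'   decreasing CCF (`cluster_id` 1 = highest), with columns `cluster_id`,
#'   `ccf` (median member CCF), `n_mutations`, `n_nonsilent`,
#'   `n_neoantigen`, `n_epitopes` (peptide-level tally), `editing_score`
#'   and `stage` (filled by the scoring step), and a `member_ids`
#'   list-column. The assigned labels are attached to the input order as
#'   attribute `assignments`.
#' @export
cluster_mutations <- function(mutations, max_clusters = 6L, seed = 1L,
                              method = c("auto", "binomial", "gaussian")) {
  method <- match.arg(method)
  if (max_clusters < 1) stopf("max_clusters must be >= 1")
  n <- nrow(mutations)
  if (n < 1) stopf("need at least one mutation to cluster")
  if (!"ccf" %in% names(mutations) || any(is.na(mutations$ccf))) {
    stopf("every mutation needs a ccf; run add_ccf() first")
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  ccf <- mutations$ccf
  have_counts <- all(c("alt_count", "depth") %in% names(mutations)) &&
    !anyNA(mutations$alt_count) && !anyNA(mutations$depth)
  if (method == "auto") method <- if (have_counts) "binomial" else "gaussian"
  if (method == "binomial" && !have_counts) {
    stopf("binomial clustering needs alt_count and depth columns")
  }

  kmax <- min(max_clusters, length(unique(round(ccf, 6))))
  if (kmax == 1 || n == 1) {
    labels <- rep(1L, n)
  } else {
    fits <- lapply(seq_len(kmax), function(k) {
      if (method == "binomial") {
        fit_binom_mixture(mutations$alt_count, mutations$depth,
                          mutations$vaf, ccf, k)
      } else {
        fit_gauss_mixture(ccf, k)
      }
    })
    bic <- vapply(fits, function(f) f$bic, numeric(1))
    best <- which(bic <= min(bic) + 1e-9)[1]  # tie -> smaller k
    labels <- fits[[best]]$labels
  }
  build_clone_clusters(mutations, labels)
}

# Binomial mixture over alt/depth. Each mutation's expected VAF at clone
# CCF phi is s_j * phi where s_j = vaf_j / ccf_j is the purity/copy-number
# scaling recovered from its own point estimate.
fit_binom_mixture <- function(alt, depth, vaf, ccf, k,
                              max_iter = 300, tol = 1e-8) {
  n <- length(alt)
  s <- ifelse(ccf > 1e-6, vaf / ccf, 0.5)
  s <- pmin(pmax(s, 0.01), 1)
  phi <- stats::quantile(ccf, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  phi <- pmin(pmax(phi + (seq_len(k) - 1) * 1e-6, 1e-4), 1)  # distinct starts
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  comp_ll <- function(phi_k) {
    p <- pmin(pmax(s * phi_k, 1e-9), 1 - 1e-9)
    stats::dbinom(alt, depth, p, log = TRUE)
  }
  for (iter in seq_len(max_iter)) {
    lmat <- vapply(seq_len(k), function(j) comp_ll(phi[j]) + log(pi_k[j]),
                   numeric(n))
    lmat <- matrix(lmat, nrow = n)
    mx <- apply(lmat, 1, max)
    lse <- mx + log(rowSums(exp(lmat - mx)))
    ll <- sum(lse)
    resp <- exp(lmat - lse)
    pi_k <- pmax(colMeans(resp), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    for (j in seq_len(k)) {
      w <- resp[, j]
      if (sum(w) < 1e-10) next
      phi[j] <- stats::optimize(function(f) -sum(w * comp_ll(f)),
                                interval = c(1e-4, 1))$minimum
    }
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  labels <- max.col(lmat, ties.method = "first")
  list(bic = -2 * ll + (2 * k - 1) * log(n), labels = labels)
}

fit_gauss_mixture <- function(x, k, max_iter = 300, tol = 1e-8) {
  n <- length(x)
  mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  mu <- mu + (seq_len(k) - 1) * 1e-6
  sd_k <- rep(max(stats::sd(x) / k, 0.01), k)
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lmat <- vapply(seq_len(k), function(j) {
      stats::dnorm(x, mu[j], sd_k[j], log = TRUE) + log(pi_k[j])
    }, numeric(n))
    lmat <- matrix(lmat, nrow = n)
    mx <- apply(lmat, 1, max)
    lse <- mx + log(rowSums(exp(lmat - mx)))
    ll <- sum(lse)
    resp <- exp(lmat - lse)
    nk <- pmax(colSums(resp), 1e-12)
    pi_k <- nk / n
    for (j in seq_len(k)) {
      mu[j] <- sum(resp[, j] * x) / nk[j]
      sd_k[j] <- max(sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j]), 0.01)
    }
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  labels <- max.col(lmat, ties.method = "first")
  # parameters: k means + k sds + (k-1) weights
  list(bic = -2 * ll + (3 * k - 1) * log(n), labels = labels)
}

#' Build clone clusters from externally computed assignments
#'
#' Interoperability path for subclonal-reconstruction output produced
#' elsewhere: given per-mutation cluster labels, builds the same
#' `clone_clusters` table as [cluster_mutations()] (median member CCF,
#' decreasing-CCF ordering, per-clone tallies).
#'
#' @param mutations data.frame with `id` and `ccf` columns.
#' @param assignments a named vector (names = mutation ids, values =
#'   cluster labels) or a data.frame with columns `id` and `cluster`.
#' @return a `clone_clusters` data.frame.
#' @export
accept_precomputed_clusters <- function(mutations, assignments) {
  if (is.data.frame(assignments)) {
    assignments <- stats::setNames(assignments$cluster, assignments$id)
  }
  missing_ids <- setdiff(mutations$id, names(assignments))
  if (length(missing_ids) > 0) {
    stopf("no cluster assignment for mutation id(s): %s",
          paste(missing_ids, collapse = ", "))
  }
  labels <- as.character(assignments[as.character(mutations$id)])
  build_clone_clusters(mutations, labels)
}

build_clone_clusters <- function(mutations, labels) {
  stopifnot(length(labels) == nrow(mutations))
  uniq <- unique(labels)
  eff <- if ("effect" %in% names(mutations)) mutations$effect else
    rep("missense", nrow(mutations))
  neo <- if ("is_neoantigenic" %in% names(mutations)) {
    as.logical(mutations$is_neoantigenic)
  } else rep(FALSE, nrow(mutations))
  nep <- if ("n_epitopes" %in% names(mutations)) mutations$n_epitopes else
    as.integer(neo)
  rows <- lapply(uniq, function(lab) {
    idx <- which(labels == lab)
    data.frame(
      ccf = stats::median(mutations$ccf[idx]),
      n_mutations = length(idx),
      n_nonsilent = sum(is_nonsilent(eff[idx])),
      n_neoantigen = sum(neo[idx] & is_nonsilent(eff[idx])),
      n_epitopes = sum(nep[idx][neo[idx] & is_nonsilent(eff[idx])])
    )
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$ccf)
  out <- out[ord, , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  out$editing_score <- NA_real_
  out$stage <- NA_character_
  ids <- if ("id" %in% names(mutations)) mutations$id else
    as.character(seq_len(nrow(mutations)))
  out$member_ids <- I(lapply(uniq[ord], function(lab) ids[labels == lab]))
  out <- out[, c("cluster_id", "ccf", "n_mutations", "n_nonsilent",
                 "n_neoantigen", "n_epitopes", "editing_score", "stage",
                 "member_ids")]
  rownames(out) <- NULL
  # re-expressed in output order
  relabel <- match(labels, uniq[ord])
  attr(out, "assignments") <- relabel
  class(out) <- c("clone_clusters", "data.frame")
  out
}
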