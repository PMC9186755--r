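# Per-clone immune editing score and per-patient ioTNL.
#
# The immune editing score of a clone is the ratio of neoantigen-bearing
# to non-silent mutations; clones scoring above the cutoff are in the
# immune escape stage, the rest in the immune elimination stage. The
# ioTNL score sums the CCF-weighted neoantigen loads of the elimination
# clones only.

#' Immune editing score of a clone
#'
#' Ratio of the clone's neoantigen count to its non-silent mutation
#' count. A clone with no non-silent mutations can hold no neoantigens;
#' its score is defined as 0 so it contributes nothing downstream.
#'
#' @param n_neoantigen,n_nonsilent non-negative counts (vectorized).
#' @return numeric score(s).
#' @export
immune_editing_score <- function(n_neoantigen, n_nonsilent) {
  if (any(n_neoantigen < 0) || any(n_nonsilent < 0)) {
    stopf("counts must be non-negative")
  }
  ifelse(n_nonsilent == 0, 0, n_neoantigen / n_nonsilent)
}

#' Classify a clone's immunoediting stage
#'
#' A clone with editing score strictly above the cutoff is in the immune
#' escape stage; at or below the cutoff it is in the immune elimination
#' stage (the boundary counts as elimination).
#'
#' @param score editing score(s).
#' @param cutoff non-negative editing-score cutoff.
#' @return character vector of `"escape"` / `"elimination"`.
#' @export
classify_clone <- function(score, cutoff) {
  if (any(cutoff < 0)) stopf("cutoff must be >= 0")
  ifelse(score > cutoff, "escape", "elimination")
}

#' Score clones: editing score and stage
#'
#' Fills the `editing_score` and `stage` columns of a `clone_clusters`
#' table at a given cutoff. The `count_unit` controls whether the
#' neoantigen count entering the score (and downstream loads) is the
#' number of neoantigenic mutations (default) or the number of predicted
#' binder peptides.
#'
#' @param clones a `clone_clusters` data.frame.
#' @param cutoff editing-score cutoff.
#' @param count_unit `"mutation"` or `"peptide"`.
#' @return the clones table with `editing_score` and `stage` filled.
#' @export
score_clones <- function(clones, cutoff = 1,
                         count_unit = c("mutation", "peptide")) {
  count_unit <- match.arg(count_unit)
  load <- clone_load(clones, count_unit)
  clones$editing_score <- immune_editing_score(load, clones$n_nonsilent)
  clones$stage <- classify_clone(clones$editing_score, cutoff)
  clones
}

clone_load <- function(clones, count_unit) {
  if (count_unit == "peptide" && "n_epitopes" %in% names(clones)) {
    clones$n_epitopes
  } else {
    clones$n_neoantigen
  }
}

#' Compute per-patient ioTNL, TNL and clone breakdown
#'
#' The ioTNL score is
#' \deqn{ioTNL = \sum_{i=1}^{n} load_i \times CCF_i}
#' summed over the n clones classified as immune elimination at the given
#' editing-score cutoff, where load_i is clone i's neoantigen count and
#' CCF_i its cancer cell fraction. TNL (total neoantigen load) sums the
#' loads of all clones regardless of stage.
#'
#' @param clones a `clone_clusters` data.frame (tallies and CCFs filled).
#' @param cutoff editing-score cutoff separating elimination from escape.
#' @param patient_id identifier carried into the result.
#' @param tmb optional precomputed tumor mutation burden (see
#'   [compute_tmb()]); reported alongside.
#' @param count_unit neoantigen counting unit, as in [score_clones()].
#' @return a `patient_scores` list: `patient_id`, `tnl`, `tmb`, `iotnl`,
#'   `log10_iotnl` (= log10(ioTNL + 0.01)), `n_elimination`, `n_escape`,
#'   and `per_clone` (a data.frame with cluster_id, n_nonsilent,
#'   n_neoantigen, load, ccf, editing_score, stage).
#' @export
compute_iotnl <- function(clones, cutoff = 1, patient_id = "patient",
                          tmb = NA_real_,
                          count_unit = c("mutation", "peptide")) {
  count_unit <- match.arg(count_unit)
  if (is.null(clones) || nrow(clones) == 0) {
    warnf("patient %s has no clones; scores set to 0", patient_id)
    return(structure(list(patient_id = patient_id, tnl = 0, tmb = tmb,
                          iotnl = 0, log10_iotnl = log10(0.01),
                          n_elimination = 0L, n_escape = 0L,
                          per_clone = NULL, empty = TRUE),
                     class = "patient_scores"))
  }
  clones <- score_clones(clones, cutoff, count_unit)
  load <- clone_load(clones, count_unit)
  elim <- clones$stage == "elimination"
  iotnl <- sum(load[elim] * clones$ccf[elim])
  per_clone <- data.frame(cluster_id = clones$cluster_id,
                          n_nonsilent = clones$n_nonsilent,
                          n_neoantigen = clones$n_neoantigen,
                          load = load,
                          ccf = clones$ccf,
                          editing_score = clones$editing_score,
                          stage = clones$stage)
  structure(list(patient_id = patient_id,
                 tnl = sum(load),
                 tmb = tmb,
                 iotnl = iotnl,
                 log10_iotnl = log10(iotnl + 0.01),
                 n_elimination = sum(elim),
                 n_escape = sum(!elim),
                 per_clone = per_clone,
                 empty = FALSE),
            class = "patient_scores")
}

#' @export
print.patient_scores <- function(x, ...) {
  cat(sprintf("Patient %s: TNL = %g, ioTNL = %g (log10 = %.3f)\n",
              x$patient_id, x$tnl, x$iotnl, x$log10_iotnl))
  cat(sprintf("  %d elimination clone(s), %d escape clone(s)\n",
              x$n_elimination, x$n_escape))
  if (!is.null(x$per_clone)) {
    print(x$per_clone, row.names = FALSE)
  }
  invisible(x)
}

#' Tumor mutation burden
#'
#' Count of non-silent mutations per megabase of the sequenced region.
#'
#' @param mutations data.frame with an `effect` column.
#' @param region_mb size of the captured coding region in Mb (> 0);
#'   around 30-40 Mb for whole exome, 1-2 Mb for targeted panels.
#' @return mutations per Mb.
#' @export
compute_tmb <- function(mutations, region_mb) {
  if (length(region_mb) != 1 || is.na(region_mb) || region_mb <= 0) {
    stopf("region_mb must be a single positive number")
  }
  sum(is_nonsilent(mutations$effect)) / region_mb
}
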