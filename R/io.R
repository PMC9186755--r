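# Readers and writers for the package's table dialects, and the
# top-level pipeline composing filter -> CCF -> cluster -> score ->
# cohort statistics.
#
# TSV with MAF-like column names is the canonical interchange format;
# read-level evidence vectors travel as semicolon-separated lists. All
# genomic coordinates are 1-based inclusive.

MAF_COLUMN_MAP <- c(
  chrom = "Chromosome", pos = "Start_Position", ref = "Reference_Allele",
  alt = "Tumor_Seq_Allele2", variant_class = "Variant_Type",
  effect = "Variant_Classification",
  tumor_depth = "t_depth", tumor_alt_count = "t_alt_count",
  normal_depth = "n_depth", normal_alt_count = "n_alt_count")

EVIDENCE_COLS <- c("mutant_mapqs", "mutant_baseqs", "mutant_end_distances",
                   "ref_end_distances")

split_semicolon <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    if (length(v) == 0) numeric(0) else as.numeric(v)
  })
}

join_semicolon <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1))
}

#' Read a mutation or candidate-variant table
#'
#' Reads a MAF-like TSV (canonical dialect) or a VCF (convenience path,
#' requires the vcfR package). The MAF dialect uses standard column names
#' (Chromosome, Start_Position, Reference_Allele, Tumor_Seq_Allele2,
#' Variant_Classification, t_depth, t_alt_count, n_depth, n_alt_count)
#' plus optional semicolon-separated read-evidence columns and optional
#' score columns (vaf, cn_major, cn_minor, ccf, ...). Schema violations
#' are reported with the offending column and row.
#'
#' @param path file path.
#' @param dialect `"maf_tsv"` or `"vcf"`.
#' @return a data.frame in the package's internal column naming; VAF is
#'   computed from counts when absent.
#' @export
read_mutation_table <- function(path, dialect = c("maf_tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "vcf") return(read_vcf_candidates(path))
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  miss <- setdiff(unname(MAF_COLUMN_MAP), names(raw))
  if (length(miss) > 0) {
    stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  }
  df <- data.frame(row.names = NULL)
  for (internal in names(MAF_COLUMN_MAP)) {
    df[seq_len(nrow(raw)), internal] <- raw[[MAF_COLUMN_MAP[[internal]]]]
  }
  for (col in c("pos", "tumor_depth", "tumor_alt_count", "normal_depth",
                "normal_alt_count")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stopf("malformed value '%s' in column %s at row %d",
            df[[col]][bad[1]], MAF_COLUMN_MAP[[col]], bad[1])
    }
    df[[col]] <- v
  }
  opt <- intersect(c("id", "patient_id", "vaf", "cn_major", "cn_minor",
                     "multiplicity", "ccf", "is_neoantigenic", "n_epitopes",
                     "cluster_id", "germline_flag"), names(raw))
  for (col in opt) df[[col]] <- raw[[col]]
  if (!"vaf" %in% names(df)) {
    df$vaf <- ifelse(df$tumor_depth > 0,
                     df$tumor_alt_count / df$tumor_depth, NA_real_)
  }
  for (col in intersect(EVIDENCE_COLS, names(raw))) {
    df[[col]] <- I(split_semicolon(raw[[col]]))
  }
  if (!"id" %in% names(df)) df$id <- sprintf("var%04d", seq_len(nrow(df)))
  df
}

read_vcf_candidates <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-variant files
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  as_mat <- function(x) if (is.null(dim(x))) t(x) else x
  ad <- as_mat(vcfR::extract.gt(v, element = "AD"))
  dp <- as_mat(vcfR::extract.gt(v, element = "DP"))
  samples <- colnames(ad)
  if (length(samples) < 2) stopf("VCF must contain tumor and normal samples")
  # tumor = sample named TUMOR/PRIMARY if present, else the last column
  tum <- samples[grepl("tumor|primary", samples, ignore.case = TRUE)][1]
  if (is.na(tum)) tum <- samples[length(samples)]
  nor <- setdiff(samples, tum)[1]
  alt_of <- function(col) {
    vapply(strsplit(ad[, col], ","), function(p) {
      if (length(p) >= 2) as.numeric(p[2]) else NA_real_
    }, numeric(1))
  }
  df <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    variant_class = ifelse(nchar(fix$REF) == nchar(fix$ALT), "SNV",
                           ifelse(nchar(fix$REF) < nchar(fix$ALT),
                                  "insertion", "deletion")),
    effect = "missense",
    tumor_depth = as.numeric(dp[, tum]),
    tumor_alt_count = alt_of(tum),
    normal_depth = as.numeric(dp[, nor]),
    normal_alt_count = alt_of(nor))
  df$vaf <- ifelse(df$tumor_depth > 0,
                   df$tumor_alt_count / df$tumor_depth, NA_real_)
  df$id <- sprintf("var%04d", seq_len(nrow(df)))
  df
}

#' Write a mutation table as MAF-like TSV
#'
#' Inverse of [read_mutation_table()]; evidence list-columns are written
#' semicolon-separated.
#'
#' @param mutations data.frame in internal naming.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  out <- data.frame(row.names = NULL)
  n <- nrow(mutations)
  for (internal in names(MAF_COLUMN_MAP)) {
    if (internal %in% names(mutations)) {
      out[seq_len(n), MAF_COLUMN_MAP[[internal]]] <- mutations[[internal]]
    }
  }
  extra <- setdiff(names(mutations), c(names(MAF_COLUMN_MAP), EVIDENCE_COLS))
  for (col in extra) out[[col]] <- mutations[[col]]
  for (col in intersect(EVIDENCE_COLS, names(mutations))) {
    out[[col]] <- join_semicolon(mutations[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' TSV with columns chrom, start, end, major, minor (1-based inclusive
#' coordinates).
#'
#' @param path file path.
#' @return a data.frame of segments.
#' @export
read_cnv_segments <- function(path) {
  seg <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "start", "end", "major", "minor"), names(seg))
  if (length(miss)) {
    stopf("segment file missing column(s): %s", paste(miss, collapse = ", "))
  }
  seg
}

#' Assign allele-specific copy number to mutations by position
#'
#' Intersects mutation positions with copy-number segments; positions not
#' covered by any segment fall back to the diploid default (1+1).
#'
#' @param mutations data.frame with `chrom` and `pos`.
#' @param segments segment data.frame from [read_cnv_segments()].
#' @return `mutations` with `cn_major` and `cn_minor` filled.
#' @export
assign_copy_number <- function(mutations, segments) {
  mutations$cn_major <- 1L
  mutations$cn_minor <- 1L
  for (i in seq_len(nrow(segments))) {
    hit <- mutations$chrom == segments$chrom[i] &
      mutations$pos >= segments$start[i] & mutations$pos <= segments$end[i]
    mutations$cn_major[hit] <- segments$major[i]
    mutations$cn_minor[hit] <- segments$minor[i]
  }
  mutations
}

#' Read a predicted-neoepitope table
#'
#' TSV in NetMHCpan-style long format: one row per (mutation, HLA allele,
#' peptide) with columns mutation_id, hla_allele, peptide, affinity_nM,
#' rank_pct and an optional logical `expressed` column.
#'
#' @param path file path.
#' @return a data.frame of epitope predictions.
#' @export
read_epitope_table <- function(path) {
  ep <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("mutation_id", "hla_allele", "peptide", "affinity_nM",
                    "rank_pct"), names(ep))
  if (length(miss)) {
    stopf("epitope table missing column(s): %s", paste(miss, collapse = ", "))
  }
  ep
}

#' Flag neoantigenic mutations from an epitope table
#'
#' A peptide counts as an HLA class I binder when its percentile rank is
#' at most `rank_cutoff` or its affinity at most `affinity_cutoff` nM
#' (NetMHCpan conventions). A mutation is neoantigenic when it is
#' non-silent and has at least one binder; `n_epitopes` counts its
#' binders. If the epitope table has an `expressed` column and
#' `use_expressed` is TRUE, unexpressed peptides are masked first.
#'
#' @param mutations mutation data.frame with `id` and `effect`.
#' @param epitopes epitope data.frame (see [read_epitope_table()]).
#' @param rank_cutoff maximum \%rank (default 2.0).
#' @param affinity_cutoff maximum affinity in nM (default 500).
#' @param use_expressed honor the optional `expressed` column.
#' @return `mutations` with `is_neoantigenic` and `n_epitopes` columns.
#' @export
annotate_neoantigens <- function(mutations, epitopes, rank_cutoff = 2.0,
                                 affinity_cutoff = 500,
                                 use_expressed = TRUE) {
  binder <- epitopes$rank_pct <= rank_cutoff |
    epitopes$affinity_nM <= affinity_cutoff
  if (use_expressed && "expressed" %in% names(epitopes)) {
    binder <- binder & as.logical(epitopes$expressed)
  }
  counts <- table(epitopes$mutation_id[binder])
  n_ep <- as.integer(counts[as.character(mutations$id)])
  n_ep[is.na(n_ep)] <- 0L
  mutations$n_epitopes <- ifelse(is_nonsilent(mutations$effect), n_ep, 0L)
  mutations$is_neoantigenic <- mutations$n_epitopes >= 1
  mutations
}

#' Read a cohort clinical table
#'
#' TSV with columns patient_id, response (CR/PR/SD/PD/NE), dcb
#' (DCB/NDB/NE), pfs_days, pfs_event, os_days, os_event. Derives
#' `orr_label` (ORR = CR/PR, NOR = SD/PD, NA for NE) and normalizes
#' `dcb_label`.
#'
#' @param path file path.
#' @return a cohort clinical data.frame.
#' @export
read_clinical_table <- function(path) {
  cl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("patient_id", "response"), names(cl))
  if (length(miss)) {
    stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  }
  bad <- which(!cl$response %in% c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad)) {
    stopf("unknown response '%s' at row %d", cl$response[bad[1]], bad[1])
  }
  cl$orr_label <- ifelse(cl$response %in% c("CR", "PR"), "ORR",
                         ifelse(cl$response %in% c("SD", "PD"), "NOR",
                                NA_character_))
  if ("dcb" %in% names(cl)) {
    cl$dcb_label <- ifelse(cl$dcb %in% c("DCB", "NDB"), cl$dcb, NA_character_)
  }
  cl
}

#' Write per-patient scores as TSV
#'
#' @param scores_list a list of `patient_scores` objects.
#' @param path output path (or NULL to just return the data.frame).
#' @return the flat scores data.frame, invisibly when written.
#' @export
write_scores_table <- function(scores_list, path = NULL) {
  df <- do.call(rbind, lapply(scores_list, function(s) {
    data.frame(patient_id = s$patient_id, tnl = s$tnl, tmb = s$tmb,
               iotnl = s$iotnl, log10_iotnl = s$log10_iotnl,
               n_elimination = s$n_elimination, n_escape = s$n_escape)
  }))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Write clone clusters as JSON
#'
#' @param clones a `clone_clusters` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(clones, path) {
  obj <- lapply(seq_len(nrow(clones)), function(i) {
    list(cluster_id = clones$cluster_id[i], ccf = clones$ccf[i],
         n_mutations = clones$n_mutations[i],
         n_nonsilent = clones$n_nonsilent[i],
         n_neoantigen = clones$n_neoantigen[i],
         n_epitopes = clones$n_epitopes[i],
         editing_score = clones$editing_score[i],
         stage = clones$stage[i],
         member_ids = clones$member_ids[[i]])
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full ioTNL pipeline on a multi-patient mutation table
#'
#' Composes the stages: copy-number assignment, neoantigen annotation,
#' CCF estimation, clone clustering, per-patient editing-score/ioTNL
#' computation and, when a clinical table is supplied, cohort-level
#' dichotomization (optionally after an editing-score cutoff grid
#' search). Deterministic for a fixed seed; the returned manifest records
#' the package version, configuration hash and seed.
#'
#' @param mutations mutation data.frame with a `patient_id` column (and
#'   `vaf` or `alt_count`/`depth`); pre-filtered somatic calls.
#' @param purity named vector of per-patient purities, a scalar, or NULL
#'   to estimate per patient from the VAF spectrum.
#' @param segments optional copy-number segments (see
#'   [assign_copy_number()]).
#' @param epitopes optional epitope table (see [annotate_neoantigens()]);
#'   if absent, mutations must already carry `is_neoantigenic`.
#' @param clinical optional clinical table (see [read_clinical_table()]).
#' @param cutoff editing-score cutoff (used when `optimize_grid` FALSE).
#' @param optimize_grid if TRUE and clinical data are present, grid
#'   search the editing cutoff (0.5-1.5 by 0.1) maximizing the AUC for
#'   `label` before final scoring.
#' @param label,endpoint clinical label and survival endpoint for the
#'   cohort stage.
#' @param region_mb region size for TMB.
#' @param count_unit neoantigen counting unit.
#' @param max_clusters maximum clones per patient.
#' @param seed integer seed.
#' @param outdir optional output directory for TSV/JSON artifacts.
#' @return a list with `scores` (per-patient data.frame), `clusters`
#'   (per-patient clone tables), `cohort` (scores joined to clinical),
#'   `dichotomy` (a `dichotomy_result` or NULL), `best_cutoff` and
#'   `manifest`.
#' @export
run_pipeline <- function(mutations, purity = NULL, segments = NULL,
                         epitopes = NULL, clinical = NULL,
                         cutoff = 1, optimize_grid = FALSE,
                         label = "ORR", endpoint = "PFS",
                         region_mb = 30, count_unit = "mutation",
                         max_clusters = 6L, seed = 1L, outdir = NULL) {
  if (!"patient_id" %in% names(mutations)) {
    stopf("mutation table needs a patient_id column")
  }
  if (!is.null(segments)) mutations <- assign_copy_number(mutations, segments)
  if (!is.null(epitopes)) mutations <- annotate_neoantigens(mutations, epitopes)
  if (!"is_neoantigenic" %in% names(mutations)) {
    stopf("mutations lack is_neoantigenic; supply an epitope table")
  }
  patients <- unique(mutations$patient_id)
  clusters <- vector("list", length(patients))
  names(clusters) <- patients
  per_patient_tmb <- numeric(length(patients))
  for (i in seq_along(patients)) {
    pid <- patients[i]
    mut_p <- mutations[mutations$patient_id == pid, , drop = FALSE]
    pur_p <- if (is.null(purity)) NULL
             else if (length(purity) == 1 && is.null(names(purity))) purity
             else unname(purity[[pid]])
    mut_p <- tryCatch(add_ccf(mut_p, purity = pur_p), error = function(e) {
      stopf("CCF stage failed for patient %s: %s", pid, conditionMessage(e))
    })
    clusters[[i]] <- tryCatch(
      cluster_mutations(mut_p, max_clusters = max_clusters, seed = seed),
      error = function(e) {
        stopf("clustering stage failed for patient %s: %s", pid,
              conditionMessage(e))
      })
    per_patient_tmb[i] <- compute_tmb(mut_p, region_mb)
  }
  score_at <- function(ct) {
    lapply(seq_along(patients), function(i) {
      compute_iotnl(clusters[[i]], cutoff = ct,
                    patient_id = patients[i], tmb = per_patient_tmb[i],
                    count_unit = count_unit)
    })
  }
  best_cutoff <- cutoff
  grid_result <- NULL
  cohort <- NULL
  if (!is.null(clinical) && optimize_grid) {
    builder <- function(ct) {
      merge(write_scores_table(score_at(ct)), clinical, by = "patient_id")
    }
    grid_result <- optimize_editing_cutoff(builder, label = label)
    best_cutoff <- grid_result$best_cutoff
  }
  scores_list <- score_at(best_cutoff)
  scores <- write_scores_table(scores_list)
  dichotomy <- NULL
  if (!is.null(clinical)) {
    cohort <- merge(scores, clinical, by = "patient_id")
    dichotomy <- dichotomize_cohort(cohort, label = label,
                                    endpoint = endpoint)
  }
  cfg <- list(cutoff = cutoff, optimize_grid = optimize_grid, label = label,
              endpoint = endpoint, region_mb = region_mb,
              count_unit = count_unit, max_clusters = max_clusters,
              seed = seed)
  manifest <- list(
    package = "ioTNL",
    version = as.character(utils::packageVersion("ioTNL")),
    config = cfg,
    config_hash = config_hash(cfg),
    best_cutoff = best_cutoff,
    n_patients = length(patients),
    seed = seed)
  result <- list(scores = scores, clusters = clusters, cohort = cohort,
                 dichotomy = dichotomy, best_cutoff = best_cutoff,
                 grid = grid_result, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(scores, file.path(outdir, "patient_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_along(patients)) {
      write_clusters_json(clusters[[i]],
                          file.path(outdir,
                                    sprintf("clusters_%s.json", patients[i])))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(dichotomy)) {
      d <- dichotomy; d$response_table <- as.vector(d$response_table)
      jsonlite::write_json(unclass(d), file.path(outdir, "dichotomy.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
    }
  }
  result
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
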