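# Somatic SNV / InDel filtering on read-level evidence.

make_candidate <- function(pos = 1000, tumor_depth = 100, tumor_alt = 30,
                           normal_depth = 50, normal_alt = 0,
                           mapq = rep(60, tumor_alt),
                           baseq = rep(35, tumor_alt),
                           mend = rep(40, tumor_alt),
                           rend = rep(30, tumor_depth - tumor_alt),
                           variant_class = "SNV", effect = "missense",
                           germline_flag = FALSE, chrom = "chr1") {
  df <- data.frame(chrom = chrom, pos = pos, ref = "C", alt = "T",
                   variant_class = variant_class, effect = effect,
                   tumor_depth = tumor_depth, tumor_alt_count = tumor_alt,
                   normal_depth = normal_depth, normal_alt_count = normal_alt,
                   germline_flag = germline_flag)
  df$mutant_mapqs <- I(list(mapq))
  df$mutant_baseqs <- I(list(baseq))
  df$mutant_end_distances <- I(list(mend))
  df$ref_end_distances <- I(list(rend))
  df
}

test_that("rank test against a threshold matches exact enumeration", {
  expect_lt(rank_test_vs_threshold(c(60, 60, 60, 60, 60), 30), 0.2)
  expect_gte(rank_test_vs_threshold(c(30, 30, 30), 30), 0.2)
  vals <- c(35, 28, 40, 33, 31, 45, 38)
  expect_equal(rank_test_vs_threshold(vals, 30),
               signed_rank_enum(vals, 30), tolerance = 1e-12)
  # a second mixed case against the 2^n enumeration
  vals2 <- c(32, 25, 41, 36, 29, 52)
  expect_equal(rank_test_vs_threshold(vals2, 30),
               signed_rank_enum(vals2, 30), tolerance = 1e-12)
  expect_error(rank_test_vs_threshold(numeric(0), 30), "insufficient")
})

test_that("pratt zero handling keeps zeros in the ranking", {
  # all zeros: no evidence either way
  expect_equal(rank_test_vs_threshold(c(30, 30, 30), 30,
                                      zero_method = "pratt"), 1,
               tolerance = 0.5)
  # clear exceedance stays significant under both zero methods
  expect_lt(rank_test_vs_threshold(c(60, 60, 60, 60, 60, 30), 30,
                                   zero_method = "pratt"), 0.2)
})

test_that("individual SNV criteria reject as specified", {
  res <- filter_snvs(make_candidate(tumor_depth = 8, tumor_alt = 3,
                                    mapq = rep(60, 3), baseq = rep(35, 3),
                                    mend = rep(40, 3), rend = rep(30, 5)))
  expect_equal(res$report$n_passed, 0L)
  expect_equal(unname(res$report$rejections[["I"]]), 1L)

  res <- filter_snvs(make_candidate(tumor_depth = 100, tumor_alt = 4,
                                    mapq = rep(60, 4), baseq = rep(35, 4),
                                    mend = rep(40, 4), rend = rep(30, 96)))
  expect_equal(unname(res$report$rejections[["II"]]), 1L)

  # missing evidence lists: rejected under a distinct tally
  cand <- make_candidate()
  cand$mutant_mapqs <- I(list(numeric(0)))
  res <- filter_snvs(cand)
  expect_equal(res$report$n_passed, 0L)
  expect_equal(unname(res$report$rejections[["insufficient_evidence"]]), 1L)

  empty <- filter_snvs(make_candidate()[0, ])
  expect_equal(empty$report$n_input, 0L)
  expect_equal(empty$report$n_passed, 0L)
})

test_that("passed set equals the intersection of independent criteria", {
  fx <- simulate_read_fixture(
    200, c(I = 0.08, II = 0.08, III = 0.05, IV = 0.06, V = 0.08,
           VI = 0.08, VII = 0.05, VIII = 0.05), seed = 11)
  res <- filter_snvs(fx$candidates)
  crits <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  pass_each <- sapply(crits, function(cr) snv_criterion_pass(fx$candidates, cr))
  expect_setequal(res$passed$id, fx$candidates$id[rowSums(!pass_each) == 0])
  # per-criterion tallies count every failing variant
  for (cr in crits) {
    expect_equal(unname(res$report$rejections[[cr]]), sum(!pass_each[, cr]))
  }
})

test_that("filtering is order-independent", {
  fx <- simulate_read_fixture(80, c(II = 0.1, IV = 0.1, V = 0.1), seed = 5)
  res1 <- filter_snvs(fx$candidates)
  perm <- withr::with_seed(9, sample(nrow(fx$candidates)))
  res2 <- filter_snvs(fx$candidates[perm, ])
  expect_setequal(res1$passed$id, res2$passed$id)
  expect_equal(res1$report$rejections, res2$report$rejections)
})

test_that("raising alt support or qualities never flips pass to fail", {
  base <- make_candidate(tumor_depth = 100, tumor_alt = 10,
                         mapq = rep(55, 10), baseq = rep(33, 10),
                         mend = rep(40, 10), rend = rep(30, 90))
  expect_equal(filter_snvs(base)$report$n_passed, 1L)
  for (alt in c(20, 40, 60)) {
    more <- make_candidate(tumor_depth = 100, tumor_alt = alt,
                           mapq = rep(55, alt), baseq = rep(33, alt),
                           mend = rep(40, alt), rend = rep(30, 100 - alt))
    expect_equal(filter_snvs(more)$report$n_passed, 1L)
  }
  higher_mapq <- make_candidate(tumor_depth = 100, tumor_alt = 10,
                                mapq = rep(70, 10), baseq = rep(33, 10),
                                mend = rep(40, 10), rend = rep(30, 90))
  expect_equal(filter_snvs(higher_mapq)$report$n_passed, 1L)
})

test_that("indel filter applies the VAF floor and germline exclusion", {
  lo <- make_candidate(tumor_depth = 100, tumor_alt = 9,
                       variant_class = "deletion",
                       effect = "frameshift_indel")
  expect_equal(filter_indels(lo)$report$n_passed, 0L)
  at <- make_candidate(tumor_depth = 100, tumor_alt = 10,
                       variant_class = "insertion",
                       effect = "inframe_indel")
  expect_equal(filter_indels(at)$report$n_passed, 1L)  # 10% is kept

  # 50 indels: 12 below-VAF, 5 germline, 1 overlapping -> 34 pass
  rows <- lapply(1:50, function(i) {
    below <- i <= 12
    germ <- i >= 12 & i < 17
    make_candidate(pos = i * 100, tumor_depth = 100,
                   tumor_alt = if (below) 5 else 30,
                   variant_class = "deletion", effect = "frameshift_indel",
                   germline_flag = germ)
  })
  cands <- do.call(rbind, rows)
  res <- filter_indels(cands)
  vaf <- cands$tumor_alt_count / cands$tumor_depth
  expect_equal(res$report$n_passed,
               sum(vaf >= 0.10 & !cands$germline_flag))
  expect_equal(res$report$n_passed, 34L)
})
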