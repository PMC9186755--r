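# Immune editing score, stage classification and ioTNL.

test_that("editing score is the neoantigen to non-silent ratio", {
  expect_equal(immune_editing_score(5, 10), 0.5)
  expect_equal(immune_editing_score(0, 7), 0)
  expect_equal(immune_editing_score(3, 0), 0)  # degenerate clone
  expect_error(immune_editing_score(-1, 5), "non-negative")
  # tally-from-members oracle on random clones
  set.seed(12)
  for (i in 1:20) {
    n_ns <- sample(0:30, 1)
    n_neo <- if (n_ns == 0) 0 else sample(0:n_ns, 1)
    expected <- if (n_ns == 0) 0 else n_neo / n_ns
    expect_equal(immune_editing_score(n_neo, n_ns), expected)
  }
})

test_that("stage classification: strictly above the cutoff is escape", {
  expect_equal(classify_clone(1.2, 1.0), "escape")
  expect_equal(classify_clone(1.0, 1.0), "elimination")
  scores <- seq(0, 2, by = 0.05)
  for (ct in c(0.5, 0.8, 1, 1.5)) {
    expect_equal(classify_clone(scores, ct),
                 ifelse(scores > ct, "escape", "elimination"))
  }
  expect_error(classify_clone(1, -0.1), "cutoff")
})

test_that("ioTNL sums CCF-weighted loads of elimination clones only", {
  # three-clone tumor: loads {1,1,3}, clone 3 escapes at cutoff 0.9
  clones <- make_clones(ccf = c(1.0, 0.1, 0.05),
                        n_nonsilent = c(4, 3, 3),
                        n_neoantigen = c(1, 1, 3))
  s <- compute_iotnl(clones, cutoff = 0.9)
  expect_equal(s$tnl, 5)
  expect_equal(s$iotnl, 1 * 1.0 + 1 * 0.1, tolerance = 1e-9)
  expect_equal(s$n_elimination, 2L)
  expect_equal(s$n_escape, 1L)
  expect_equal(s$log10_iotnl, log10(1.1 + 0.01))

  # all clones escape -> ioTNL 0
  esc <- make_clones(ccf = c(1, 0.5), n_nonsilent = c(4, 4),
                     n_neoantigen = c(4, 4))
  expect_equal(compute_iotnl(esc, cutoff = 0.5)$iotnl, 0)

  # single elimination clone with 7 neoantigens at CCF 1
  one <- make_clones(ccf = 1, n_nonsilent = 20, n_neoantigen = 7)
  expect_equal(compute_iotnl(one, cutoff = 1)$iotnl, 7)

  expect_warning(s0 <- compute_iotnl(make_clones(1, 1, 1)[0, ]), "no clones")
  expect_equal(s0$iotnl, 0)
})

test_that("ioTNL is monotone in the editing cutoff and bounded by TNL", {
  set.seed(77)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    n_ns <- sample(5:20, k, replace = TRUE)
    clones <- make_clones(ccf = runif(k),
                          n_nonsilent = n_ns,
                          n_neoantigen = vapply(n_ns, function(n)
                            sample(0:n, 1), integer(1)))
    cuts <- seq(0, 1.2, by = 0.1)
    vals <- vapply(cuts, function(ct) compute_iotnl(clones, ct)$iotnl,
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
    s <- compute_iotnl(clones, cutoff = Inf)
    expect_equal(s$iotnl, sum(clones$n_neoantigen * clones$ccf))
    expect_lte(s$iotnl, s$tnl + 1e-12)
  }
})

test_that("ioTNL equals the per-mutation brute-force sum on simulated tumors", {
  cfg <- sim_config(silent_frac = 0.2)
  for (seed in 1:25) {
    sim <- simulate_patient(cfg, seed = seed)
    truth <- sim$truth
    clones <- accept_precomputed_clusters(
      transform(sim$mutations, ccf = truth$clone_ccfs[true_clone]),
      stats::setNames(sim$mutations$true_clone, sim$mutations$id))
    # stage each clone exactly as planted by matching its CCF
    stage_of <- truth$clone_stages[match(round(clones$ccf, 9),
                                         round(truth$clone_ccfs, 9))]
    manual <- sum(ifelse(stage_of == "elimination",
                         clones$n_neoantigen * clones$ccf, 0))
    brute <- iotnl_brute(sim$mutations, truth$clone_ccfs, truth$clone_stages)
    expect_equal(manual, brute, tolerance = 1e-9)
    expect_equal(truth$iotnl, brute, tolerance = 1e-9)
  }
})

test_that("adding a neoantigen to an elimination clone adds its CCF", {
  clones <- make_clones(ccf = c(0.9, 0.3), n_nonsilent = c(10, 10),
                        n_neoantigen = c(2, 3))
  before <- compute_iotnl(clones, cutoff = 0.6)$iotnl
  clones$n_neoantigen[2] <- 4L  # score 0.4 stays below the cutoff
  after <- compute_iotnl(clones, cutoff = 0.6)$iotnl
  expect_equal(after - before, clones$ccf[2], tolerance = 1e-12)
})

test_that("TMB is the non-silent count per megabase", {
  m <- data.frame(effect = c(rep("missense", 250), rep("nonsense", 50),
                             rep("silent", 40)))
  expect_equal(compute_tmb(m, 30), 10)
  expect_equal(compute_tmb(m[0, , drop = FALSE], 30), 0)
  set.seed(5)
  eff <- sample(c("missense", "silent", "noncoding", "splice"), 100,
                replace = TRUE)
  expect_equal(compute_tmb(data.frame(effect = eff), 1.4),
               sum(eff %in% c("missense", "splice")) / 1.4)
  expect_error(compute_tmb(m, 0), "positive")
})

test_that("peptide counting unit uses epitope tallies for load and score", {
  clones <- make_clones(ccf = c(1, 0.2), n_nonsilent = c(4, 4),
                        n_neoantigen = c(2, 2), n_epitopes = c(8, 2))
  s_mut <- compute_iotnl(clones, cutoff = 1, count_unit = "mutation")
  expect_equal(s_mut$iotnl, 2 * 1 + 2 * 0.2)
  # peptide unit: clone 1 scores 8/4 = 2 > 1 -> escape
  s_pep <- compute_iotnl(clones, cutoff = 1, count_unit = "peptide")
  expect_equal(s_pep$tnl, 10)
  expect_equal(s_pep$iotnl, 2 * 0.2)
})
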