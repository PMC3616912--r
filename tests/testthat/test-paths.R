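test_that("path enumeration yields L! lexicographic orderings with valid chains", {
  p5 <- enumerate_paths(loci5)
  expect_length(p5, 120L)
  expect_length(enumerate_paths(locus_set("a")), 1L)
  p3 <- enumerate_paths(loci3)
  expect_length(p3, 6L)
  for (p in p3) expect_length(p$chain, 4L)
  # orderings come out in lexicographic order
  ords <- vapply(p3, function(p) paste(p$ordering, collapse = ""), character(1))
  expect_identical(ords, sort(ords))
  # chain element k has exactly k mutations and consecutive elements differ
  # by one locus
  for (p in p5[c(1, 37, 120)]) {
    expect_equal(genotype_size(p$chain, loci5), 0:5)
    for (k in 1:5) {
      d <- genotype_mask(p$chain[k + 1], loci5) - genotype_mask(p$chain[k], loci5)
      expect_equal(sum(d == 1), 1)
      expect_equal(sum(d == -1), 0)
    }
  }
})

test_that("accessibility verdicts match direct per-step comparison", {
  loci <- loci5
  gts <- all_genotypes(loci)
  # strictly additive landscape: every path monotone
  w_up <- setNames(1 + 0.1 * genotype_size(gts, loci), gts)
  ls_up <- make_landscape(w_up, loci)
  expect_equal(count_accessible(ls_up, "E1"), 120L)
  # sink the full mutant below every quadruple: nothing reaches it
  w_down <- w_up; w_down["rtsgp"] <- 1.05
  expect_equal(count_accessible(make_landscape(w_down, loci), "E1"), 0L)
  # ties break to inaccessible
  w_tie <- w_up; w_tie["r"] <- w_tie["anc"]
  ls_tie <- make_landscape(w_tie, loci)
  paths <- enumerate_paths(loci)
  starts_r <- paths[vapply(paths, function(p) p$ordering[1] == "r", logical(1))]
  expect_false(any(vapply(starts_r, is_accessible, logical(1),
                          landscape = ls_tie, env = "E1")))
})

test_that("accessible-path counts agree with the subset-DP oracle", {
  set.seed(31)
  for (i in 1:30) {
    ls <- random_landscape(loci5)
    w <- setNames(ls$w_mean, ls$genotype)
    expect_equal(count_accessible(ls, "E1"),
                 dp_accessible_count(as.list(w), loci5))
  }
  # and on a 3-locus landscape with many ties
  for (i in 1:10) {
    gts <- all_genotypes(loci3)
    w <- setNames(sample(c(1, 1.1, 1.2), length(gts), replace = TRUE), gts)
    ls <- make_landscape(w, loci3)
    expect_equal(count_accessible(ls, "E1"),
                 dp_accessible_count(as.list(w), loci3))
  }
})

test_that("significance-gated accessibility is a subset of mean accessibility", {
  set.seed(17)
  spec <- default_landscape_spec(seed = 99)
  ls <- summarize_landscape(simulate_fitness_table(spec))
  for (e in landscape_environments(ls)) {
    n_sig <- count_accessible(ls, e, mode = "significant")
    n_mean <- count_accessible(ls, e, mode = "mean")
    expect_lte(n_sig, n_mean)
    pr <- path_report(ls, e)
    expect_equal(sum(pr$accessible_mean), n_mean)
    expect_equal(sum(pr$accessible_significant), n_sig)
    # a mean-accessible path has no blocking step; a blocked one names its
    # first non-increasing step
    expect_true(all(is.na(pr$first_blocking_step[pr$accessible_mean])))
    expect_true(all(pr$first_blocking_step[!pr$accessible_mean] %in% 1:5))
  }
})

test_that("step effects cover the hypercube's edges with a per-step t-test", {
  loci <- loci5
  gts <- all_genotypes(loci)
  # flat landscape: all edges neutral
  flat <- make_landscape(setNames(rep(1, 32), gts), loci, sd = 0.02, n = 5L)
  ef <- step_effects(flat, "E1")
  expect_equal(nrow(ef), 80L)  # L * 2^(L-1)
  expect_true(all(ef$classification == "neutral"))
  expect_equal(ef$sd_delta, rep(sqrt(2 * 0.02^2), 80))
  # every edge adds exactly the locus it names
  expect_equal(genotype_size(ef$to, loci), genotype_size(ef$from, loci) + 1L)
  # a strongly deleterious step at high replication is flagged even after
  # Bonferroni
  spec <- landscape_spec(loci3, "E1",
                         list(E1 = c(a = 1.3, b = 1.2, c = 1.1)),
                         list(E1 = c(ab = -0.5)),
                         n_reps = 30L, noise_sd = 0.02, seed = 12)
  ls <- summarize_landscape(simulate_fitness_table(spec))
  ef3 <- step_effects(ls, "E1")
  expect_identical(ef3$classification[ef3$from == "a" & ef3$to == "ab"],
                   "deleterious")
})

test_that("peak finding matches an exhaustive neighbour check", {
  set.seed(23)
  for (i in 1:20) {
    ls <- random_landscape(loci5)
    w <- setNames(ls$w_mean, ls$genotype)
    pk <- peaks(ls, "E1")
    expect_identical(pk$global_maximum, names(w)[w == max(w)])
    # oracle: enumerate Hamming-1 neighbours by label surgery
    oracle_local <- names(w)[vapply(names(w), function(g) {
      m <- genotype_mask(g, loci5)
      nb <- vapply(seq_along(m), function(i) {
        m2 <- m; m2[i] <- !m2[i]; format_genotype(m2, loci5)
      }, character(1))
      all(w[g] >= w[nb])
    }, logical(1))]
    expect_identical(pk$local_maxima, oracle_local)
  }
  # monotone landscape peaks only at the full mutant
  gts <- all_genotypes(loci5)
  mono <- make_landscape(setNames(1 + 0.05 * genotype_size(gts, loci5), gts),
                         loci5)
  expect_identical(peaks(mono, "E1")$local_maxima, "rtsgp")
})
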