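test_that("the spec's true landscape inverts the epistasis decomposition", {
  loci <- loci3
  spec <- landscape_spec(loci, c("E1", "E2"),
                         list(E1 = c(a = 1.1, b = 1.2, c = 1.05),
                              E2 = c(a = 1.0, b = 1.1, c = 0.95)),
                         list(E1 = c(ab = -0.1, abc = 0.07),
                              E2 = c(bc = 0.12)))
  tl <- true_landscape(spec)
  # recompute the four affected genotypes by hand in E1
  w <- setNames(tl$w_mean[tl$environment == "E1"],
                tl$genotype[tl$environment == "E1"])
  expect_equal(w[["anc"]], 1)
  expect_equal(w[["ab"]], 1.1 * 1.2 - 0.1)
  expect_equal(w[["ac"]], 1.1 * 1.05)
  expect_equal(w[["abc"]], 1.1 * 1.2 * 1.05 - 0.1 + 0.07)
  # interaction planted only in E2 is absent from E1: GxGxE by construction
  w2 <- setNames(tl$w_mean[tl$environment == "E2"],
                 tl$genotype[tl$environment == "E2"])
  expect_equal(w2[["bc"]], 1.1 * 0.95 + 0.12)
  expect_equal(w[["bc"]], 1.2 * 1.05)
  # a spec implying non-positive fitness is rejected
  expect_error(landscape_spec(loci, "E1",
                              list(E1 = c(a = 1.1, b = 1.2, c = 1.05)),
                              list(E1 = c(ab = -2))),
               "non-positive")
})

test_that("the default spec reflects the study's per-environment topology", {
  tl <- true_landscape(default_landscape_spec())
  # selection: smooth landscape, single peak at the full mutant
  expect_identical(peaks(tl, "selection")$local_maxima, "rtsgp")
  expect_gt(count_accessible(tl, "selection"), 60)
  # env_down: the three-mutation genotype rts outcompetes the full mutant
  expect_identical(peaks(tl, "env_down")$global_maximum, "rts")
  expect_lt(count_accessible(tl, "env_down"), 10)
  # opposite-signed mean epistasis in the two novel environments
  up <- mean(epistasis_table(tl, "env_up")$eps)
  down <- mean(epistasis_table(tl, "env_down")$eps)
  expect_lt(up, 0)
  expect_gt(down, 0)
})

test_that("simulation is a pure function of spec and seed", {
  spec <- default_landscape_spec(seed = 42)
  t1 <- simulate_fitness_table(spec)
  t2 <- simulate_fitness_table(spec)
  expect_identical(t1, t2)
  t3 <- simulate_fitness_table(default_landscape_spec(seed = 43))
  expect_false(identical(t1$w, t3$w))
  # noise-free replicates equal the truth exactly
  spec0 <- default_landscape_spec(noise_sd = 0, n_reps = 3L)
  tab0 <- simulate_fitness_table(spec0)
  ls0 <- summarize_landscape(tab0)
  tl <- true_landscape(spec0)
  key <- paste(tl$environment, tl$genotype)
  expect_equal(ls0$w_mean[match(key, paste(ls0$environment, ls0$genotype))],
               tl$w_mean)
  expect_equal(max(ls0$w_sd), 0)
})

test_that("replicate means converge to the truth (law of large numbers)", {
  loci <- locus_set("a")
  spec <- landscape_spec(loci, "E1", list(E1 = c(a = 1.2)),
                         n_reps = 10000L, noise_sd = 0.05, seed = 6)
  tab <- simulate_fitness_table(spec)
  m <- mean(tab$w[tab$genotype == "a"])
  se <- 0.05 / sqrt(10000)
  expect_lt(abs(m - 1.2), 3 * se)
})

test_that("competition records round-trip the target fitness exactly", {
  targets <- data.frame(environment = "E1", genotype = c("r", "rt", "rtsgp"),
                        replicate = 1L, w = c(1.0, 1.3, 0.85))
  rec <- simulate_competitions(targets)
  back <- competition_fitness(rec)
  expect_equal(back$w, targets$w, tolerance = 1e-9)
  # symmetric counts at neutrality
  expect_equal(rec$Af[1], rec$Bf[1])
})

test_that("growth curves encode AUC ratios and biolog curves planted calls", {
  tab <- simulate_growth_curves(c(x = 1.25), n_reps = 1, seed = 2)
  gt <- growth_table(tab, reference = "anc")
  expect_equal(gt$rel_growth[gt$strain == "x"], 1.25, tolerance = 1e-9)
  # a tenfold planted gain with tiny noise must be called
  tab_b <- simulate_biolog(n_env = 4, gains = 2, gain_factor = 10,
                           noise_sd = 0.005, seed = 8)
  calls <- biolog_screen(tab_b, "evolved", "ancestor")
  expect_identical(calls$verdict[calls$environment == "env002"], "gain")
  expect_identical(unique(calls$verdict[calls$environment != "env002"]), "none")
})

test_that("planted interaction coefficients are recovered from the landscape", {
  spec <- default_landscape_spec()
  tl <- true_landscape(spec)
  for (e in spec$environments) {
    en <- spec$eps_net[[e]]
    et <- epistasis_table(tl, e)
    for (B in names(en)) {
      # net term comes back exactly
      expect_equal(net_higher_order(tl, e, B), unname(en[B]),
                   tolerance = 1e-12)
      # absolute epistasis is the sum of planted terms over subsets
      planted <- sum(en[names(en) %in% c(subsets(B, spec$loci, 2L), B)])
      expect_equal(et$eps[et$genotype == B], planted, tolerance = 1e-12)
    }
  }
})

test_that("GxGxE calibration hits the requested noise-free share", {
  spec <- landscape_spec(loci5, c("up", "down"),
                         list(up = c(r = 1.000, t = 1.220, s = 1.060,
                                     g = 1.04, p = 1.12),
                              down = c(r = 1.005, t = 1.130, s = 0.920,
                                       g = 1.01, p = 0.99)),
                         list(up = c(tg = -0.25, ts = -0.03, rts = 0.08),
                              down = c(ts = 0.14, rs = 0.08, rts = -0.02)))
  cal <- calibrate_gxgxe(spec, target = 0.08)
  truth <- true_landscape(cal)
  tab <- data.frame(environment = truth$environment, genotype = truth$genotype,
                    replicate = 1L, w = truth$w_mean)
  attr(tab, "loci") <- cal$loci
  # saturated noise-free fit: only the SS decomposition is of interest
  vp <- variance_partition(suppressWarnings(gxe_anova(tab)))
  expect_equal(vp$fraction[vp$class == "GxGxE"], 0.08, tolerance = 1e-6)
})
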