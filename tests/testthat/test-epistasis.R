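test_that("multiplicative expectation and error propagation match closed forms", {
  expect_equal(expected_fitness(c(1, 1, 1))$w_exp, 1)
  expect_equal(expected_fitness(c(1, 1, 1))$sd_exp, 0)
  # reported single-mutant fitnesses for the five loci in the two novel
  # environments; expectation is their product
  egta <- c(1.00, 1.22, 1.06, 1.04, 1.12)
  guan <- c(1.005, 1.13, 0.92, 1.01, 0.99)
  expect_equal(expected_fitness(egta)$w_exp, prod(egta))
  expect_equal(expected_fitness(guan)$w_exp, prod(guan))
  # quadrature: two unit-mean singles with sd 0.03 and 0.04 give sd 0.05
  expect_equal(expected_fitness(c(1, 1), c(0.03, 0.04))$sd_exp, 0.05)
  # linear option sums relative errors instead
  expect_equal(expected_fitness(c(1, 1), c(0.03, 0.04),
                                error_propagation = "linear")$sd_exp, 0.07)
  expect_error(expected_fitness(numeric(0)), "at least one")
})

test_that("absolute epistasis keeps its sign against the product null", {
  egta <- c(1.00, 1.22, 1.06, 1.04, 1.12)
  guan <- c(1.005, 1.13, 0.92, 1.01, 0.99)
  expect_equal(absolute_epistasis(prod(egta), egta), 0)
  # full-mutant fitness observed in each novel environment: epistasis is
  # slightly negative where expectation overshoots, positive where it
  # undershoots
  expect_equal(absolute_epistasis(1.497, egta), 1.497 - prod(egta))
  expect_lt(absolute_epistasis(1.497, egta), 0)
  expect_equal(absolute_epistasis(1.116, guan), 1.116 - prod(guan))
  expect_gt(absolute_epistasis(1.116, guan), 0)
})

test_that("epistasis SD combines observation and expectation uncertainty", {
  expect_equal(epistasis_sd(0, 0), 0)
  expect_equal(epistasis_sd(0.12, 0.05), 0.13)  # 5-12-13 triangle
  expect_equal(epistasis_sd(0.3, 0), 0.3)
  expect_equal(epistasis_sd(0.12, 0.05, "linear"), 0.17)
})

test_that("the epistasis t-test uses replicate df and is symmetric in sign", {
  expect_equal(epistasis_test(0, 0.05, 5)$t, 0)
  expect_equal(epistasis_test(0, 0.05, 5)$p, 1)
  ts <- epistasis_test(0.10, 0.05, 5)
  expect_equal(ts$t, 2)
  expect_equal(ts$df, 4)
  expect_equal(ts$p, 2 * pt(-2, 4))
  expect_equal(ts$p, 0.1161165, tolerance = 1e-6)
  neg <- epistasis_test(-0.10, 0.05, 5)
  expect_equal(neg$t, -2)
  expect_equal(neg$p, ts$p)
  dg <- epistasis_test(0.1, 0, 5)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p))
})

test_that("net higher-order epistasis follows the hand recursion on 3 loci", {
  loci <- loci3
  s <- c(a = 1.1, b = 1.2, c = 1.3)
  pair_eps <- c(ab = 0.05, ac = -0.08, bc = 0.02)
  w <- c(anc = 1, s,
         ab = s["a"] * s["b"] + pair_eps["ab"],
         ac = s["a"] * s["c"] + pair_eps["ac"],
         bc = s["b"] * s["c"] + pair_eps["bc"],
         abc = prod(s))  # triple sits exactly on the product null
  names(w) <- c("anc", "a", "b", "c", "ab", "ac", "bc", "abc")
  ls <- make_landscape(w, loci)
  # pairs: net term is the absolute epistasis itself
  expect_equal(net_higher_order(ls, "E1", "ab"), unname(pair_eps["ab"]))
  # triple with zero absolute epistasis: net higher order cancels the pairs
  expect_equal(net_higher_order(ls, "E1", "abc"), -sum(pair_eps))
  # fully multiplicative landscape: all net terms vanish
  w_mult <- w
  for (g in c("ab", "ac", "bc"))
    w_mult[g] <- prod(s[strsplit(g, "")[[1]]])
  ls_mult <- make_landscape(w_mult, loci)
  for (g in c("ab", "ac", "bc", "abc"))
    expect_equal(net_higher_order(ls_mult, "E1", g), 0, tolerance = 1e-12)
})

test_that("the per-environment epistasis table is internally consistent", {
  set.seed(21)
  ls <- random_landscape(loci5, sd = 0.05, n = 5L)
  et <- epistasis_table(ls, "E1")
  expect_equal(nrow(et), 26L)  # 32 - 5 singles - ancestor
  expect_equal(et$eps, et$w_obs - et$w_exp)
  expect_equal(et$sd_eps, sqrt(et$sd_obs^2 + et$sd_exp^2))
  expect_equal(et$t, et$eps / et$sd_eps)
  expect_equal(et$df, rep(4L, 26L))
  # pairs carry their own eps as the higher-order column (recursion base)
  pairs <- et$n_mut == 2L
  expect_equal(et$eps_higher[pairs], et$eps[pairs])
  # Bonferroni can only lose significance relative to uncorrected calls
  et_bf <- epistasis_table(ls, "E1", correction = "bonferroni")
  expect_true(all(et_bf$significant <= et$significant))
})

test_that("expectation SD is permutation-invariant and scales linearly", {
  set.seed(3)
  w <- runif(5, 0.9, 1.4); s <- runif(5, 0.01, 0.1)
  base <- expected_fitness(w, s)
  for (i in 1:5) {
    p <- sample(5)
    expect_equal(expected_fitness(w[p], s[p])$sd_exp, base$sd_exp)
  }
  k <- 2.5  # scaling all fitnesses and SDs together scales the product SD
  scaled <- expected_fitness(k * w, k * s)
  expect_equal(scaled$w_exp, k^5 * base$w_exp)
  expect_equal(scaled$sd_exp, k^5 * base$sd_exp)
})

test_that("mean epistasis recovers a planted mean at the study's n", {
  # all-zero epistasis: flat test
  flat <- data.frame(eps = rep(0, 26))
  expect_error(mean_epistasis(flat[0, , drop = FALSE]), ">= 2")
  # jittered zero mean: exercise the t machinery
  set.seed(8)
  x <- data.frame(eps = 0.057 + rnorm(26, 0, 0.055))
  me <- mean_epistasis(x)
  expect_equal(me$n, 26L)
  expect_equal(me$df, 25)
  expect_lt(abs(me$mean - 0.057), me$ci95)  # truth inside the 95% CI
  zero <- mean_epistasis(data.frame(eps = c(-0.01, 0.01, -0.02, 0.02)))
  expect_equal(zero$mean, 0)
  expect_equal(zero$p, 1)
})

test_that("diminishing-returns fit reports Pearson r and the SMA line", {
  x <- seq(1, 2, length.out = 10)
  rec <- function(y) data.frame(environment = "E1", w_exp = x, eps = y)
  up <- diminishing_returns_fit(rec(2 * x))
  expect_equal(up$pearson_r, 1)
  expect_equal(up$sma_slope, 2)
  expect_equal(up$sma_intercept, 0)
  down <- diminishing_returns_fit(rec(-x + 3))
  expect_equal(down$pearson_r, -1)
  expect_equal(down$sma_slope, -1)
  # random data: slope is sign(r) * sd_y / sd_x by closed form
  set.seed(13)
  y <- rnorm(10)
  fit <- diminishing_returns_fit(rec(y))
  expect_equal(fit$sma_slope, sign(cor(x, y)) * sd(y) / sd(x))
  expect_equal(fit$sma_intercept, mean(y) - fit$sma_slope * mean(x))
  # relative scale divides epsilon by the expectation
  relf <- diminishing_returns_fit(rec(y), scale = "relative")
  expect_equal(relf$pearson_r, cor(x, y / x))
  expect_error(diminishing_returns_fit(rec(rep(1, 10))), "zero variance")
})

test_that("focal-mutation ANCOVA detects planted interaction and main effects", {
  loci <- loci5
  build_records <- function(eps) {
    gts <- all_genotypes(loci)
    gts <- gts[genotype_size(gts, loci) >= 2]
    structure(data.frame(environment = "E1", genotype = gts,
                         w_exp = seq(1, 1.5, length.out = length(gts)),
                         eps = eps, stringsAsFactors = FALSE),
              loci = loci)
  }
  gts <- all_genotypes(loci)
  gts <- gts[genotype_size(gts, loci) >= 2]
  has_t <- grepl("t", gts)
  x <- seq(1, 1.5, length.out = length(gts))

  # identical strata: nothing significant
  set.seed(2)
  noise <- rnorm(length(gts), 0, 0.01)
  same <- focal_mutation_analysis(build_records(noise), "t")
  expect_gt(same$group_p, 0.05)
  expect_gt(same$interaction_p, 0.05)

  # slopes -1 with the locus vs 0 without: interaction term significant
  slope <- focal_mutation_analysis(
    build_records(ifelse(has_t, -1 * (x - 1), 0) + noise), "t")
  expect_lt(slope$interaction_p, 0.01)
  expect_lt(slope$r_with, -0.9)

  # intercept shift only: main effect significant, interaction not
  shift <- focal_mutation_analysis(
    build_records(ifelse(has_t, 0.2, 0) + noise), "t")
  expect_lt(shift$main_effect_p, 0.01)
  expect_gt(shift$interaction_p, 0.05)
  expect_equal(shift$group_df, 24)  # pooled t over 26 genotypes
  expect_error(focal_mutation_analysis(build_records(noise), "z"),
               "unknown locus")
})
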