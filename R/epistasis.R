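## Propagated SD of a product of independent measurements.
## quadrature: sd = |prod| * sqrt(sum((sd_i/x_i)^2))   (root-sum-of-squares)
## linear:     sd = |prod| * sum(sd_i/x_i)             (plain sum of relative errors)
propagate_product_sd <- function(prod_value, values, sds,
                                 mode = c("quadrature", "linear")) {
  mode <- match.arg(mode)
  rel <- sds / values
  if (mode == "quadrature") abs(prod_value) * sqrt(sum(rel^2))
  else abs(prod_value) * sum(rel)
}

#' Expected fitness of a mutation combination under the multiplicative null
#'
#' The no-epistasis null model holds that the relative fitness of a
#' combination of mutations equals the product of the single-mutant relative
#' fitnesses: `w_exp = prod(w_i)`. Measurement error propagates through the
#' product from the relative errors of the singles; by default in quadrature,
#' `sd_exp = w_exp * sqrt(sum((sd_i / w_i)^2))`, with a linear-sum option.
#'
#' @param w numeric vector of single-mutant mean fitnesses, one per mutation
#'   in the target combination (all > 0).
#' @param sd their standard deviations (same length, >= 0); default 0.
#' @param error_propagation `"quadrature"` (default) or `"linear"`.
#' @return list with `w_exp` and `sd_exp`.
#' @examples
#' expected_fitness(c(1.00, 1.22, 1.06, 1.04, 1.12))  # w_exp ~ 1.506
#' @export
expected_fitness <- function(w, sd = rep(0, length(w)),
                             error_propagation = c("quadrature", "linear")) {
  if (length(w) < 1L) stop("need at least one single-mutant fitness")
  stopifnot(length(sd) == length(w), all(w > 0), all(sd >= 0))
  w_exp <- prod(w)
  list(w_exp = w_exp,
       sd_exp = propagate_product_sd(w_exp, w, sd, match.arg(error_propagation)))
}

#' Absolute epistasis of a genotype
#'
#' The deviation of observed fitness from the multiplicative null,
#' `eps = w_obs - prod(w_i)`. The sign matters: positive values indicate
#' synergistic (fitness above expectation) and negative values antagonistic
#' interactions.
#'
#' @param w_obs observed mean relative fitness of the combination genotype.
#' @param singles vector of single-mutant mean fitnesses for its mutations.
#' @return epsilon (dimensionless).
#' @export
absolute_epistasis <- function(w_obs, singles) {
  w_obs - expected_fitness(singles)$w_exp
}

#' Propagated standard deviation of an epistasis estimate
#'
#' Epsilon depends on both the observed fitness and the multiplicative
#' expectation, so its uncertainty combines both: by default in quadrature,
#' `sd_eps = sqrt(sd_obs^2 + sd_exp^2)`; linearly as `sd_obs + sd_exp` under
#' the linear option.
#'
#' @param sd_obs SD of the observed fitness (replicate sample SD).
#' @param sd_exp propagated SD of the expectation (see [expected_fitness()]).
#' @param error_propagation `"quadrature"` (default) or `"linear"`.
#' @return sd of epsilon.
#' @export
epistasis_sd <- function(sd_obs, sd_exp,
                         error_propagation = c("quadrature", "linear")) {
  stopifnot(sd_obs >= 0, sd_exp >= 0)
  if (match.arg(error_propagation) == "quadrature") sqrt(sd_obs^2 + sd_exp^2)
  else sd_obs + sd_exp
}

#' t-test for one epistasis estimate
#'
#' The t-statistic is the ratio of epsilon to its propagated standard
#' deviation, with degrees of freedom from the replication of the observed
#' genotype (df = n_reps - 1) and a two-sided p from the t distribution.
#' A zero `sd_eps` is degenerate (no error estimate): the test is flagged
#' rather than reported as p = 0.
#'
#' @param eps epistasis estimate.
#' @param sd_eps its propagated SD.
#' @param n_reps replicate count behind the observed fitness (>= 2 for a
#'   reportable test).
#' @return list with `t`, `df`, `p`, `sd_eps` and logical `degenerate`.
#' @export
epistasis_test <- function(eps, sd_eps, n_reps) {
  stopifnot(sd_eps >= 0, n_reps >= 2)
  df <- n_reps - 1L
  if (sd_eps == 0)
    return(list(t = NA_real_, df = df, p = NA_real_, sd_eps = 0,
                degenerate = TRUE))
  t <- eps / sd_eps
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), sd_eps = sd_eps,
       degenerate = FALSE)
}

#' Single-mutant fitness statistics for one environment
#'
#' @param landscape a `landscape_summary`.
#' @param env environment label.
#' @return data.frame with one row per locus: locus, w_mean, w_sd, n.
#' @export
single_mutant_stats <- function(landscape, env) {
  loci <- attr(landscape, "loci")
  rows <- lapply(unclass(loci), function(l) {
    cell <- landscape_cell(landscape, env, l)
    data.frame(locus = l, w_mean = cell$w_mean, w_sd = cell$w_sd, n = cell$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Absolute epistasis of one genotype straight from a landscape summary.
eps_abs_cell <- function(landscape, env, genotype, sgl) {
  loci <- attr(landscape, "loci")
  present <- unclass(loci)[genotype_mask(genotype, loci)]
  landscape_cell(landscape, env, genotype)$w_mean -
    prod(sgl$w_mean[match(present, sgl$locus)])
}

#' Net higher-order epistasis of a genotype
#'
#' Interactions among three or more mutations that cannot be explained by the
#' constituent lower-order interactions. The decomposition is recursive
#' (inclusion-exclusion): for a pair, the net interaction is its absolute
#' epistasis; for `|g| >= 3`,
#' `eps_HO(g) = eps_abs(g) - sum over proper subsets B of g with |B| >= 2 of
#' eps_net(B)`, and `eps_net(g) = eps_HO(g)`. This makes the decomposition
#' exact: observed fitness always reconstructs as the product of singles plus
#' the sum of net terms over all subsets of size >= 2.
#'
#' @param landscape a `landscape_summary`.
#' @param env environment label.
#' @param genotype canonical genotype label with >= 2 mutations; all of its
#'   subset genotypes must be present in `landscape`.
#' @return net higher-order epistasis (equals absolute epistasis for pairs).
#' @export
net_higher_order <- function(landscape, env, genotype) {
  loci <- attr(landscape, "loci")
  if (genotype_size(genotype, loci) < 2L)
    stop("net higher-order epistasis is defined for >= 2 mutations")
  sgl <- single_mutant_stats(landscape, env)
  memo <- new.env(parent = emptyenv())
  eps_net_memo(landscape, env, genotype, sgl, memo)
}

eps_net_memo <- function(landscape, env, g, sgl, memo) {
  if (!is.null(memo[[g]])) return(memo[[g]])
  loci <- attr(landscape, "loci")
  total <- eps_abs_cell(landscape, env, g, sgl)
  val <- if (genotype_size(g, loci) == 2L) total else {
    lower <- subsets(g, loci, min_size = 2L)
    total - sum(vapply(lower, eps_net_memo, numeric(1L),
                       landscape = landscape, env = env, sgl = sgl,
                       memo = memo))
  }
  memo[[g]] <- val
  val
}

#' Per-genotype epistasis report for one environment
#'
#' Builds the full epistasis decomposition for every genotype with at least
#' `min_mut` mutations: observed fitness, multiplicative expectation with
#' propagated SD, absolute epistasis with propagated SD, t-test (df from the
#' observed genotype's replication), optional multiple-testing correction,
#' and the net higher-order term.
#'
#' @param landscape a `landscape_summary`.
#' @param env environment label.
#' @param min_mut smallest mutation count to report (default 2; 26 of the 32
#'   genotypes on a five-locus landscape).
#' @param alpha two-sided significance level (default 0.05).
#' @param error_propagation `"quadrature"` (default) or `"linear"`.
#' @param correction multiple-testing correction across the reported
#'   genotypes: `"none"` (default), `"bonferroni"` or `"bh"`.
#' @return an `epistasis_table` data.frame with columns environment, genotype,
#'   n_mut, w_obs, sd_obs, w_exp, sd_exp, eps, sd_eps, t, df, p, p_adj,
#'   significant, eps_higher.
#' @export
epistasis_table <- function(landscape, env, min_mut = 2L, alpha = 0.05,
                            error_propagation = c("quadrature", "linear"),
                            correction = c("none", "bonferroni", "bh")) {
  error_propagation <- match.arg(error_propagation)
  correction <- match.arg(correction)
  loci <- attr(landscape, "loci")
  sgl <- single_mutant_stats(landscape, env)
  gts <- landscape$genotype[landscape$environment == env]
  gts <- gts[genotype_size(gts, loci) >= min_mut]
  gts <- gts[order(genotype_size(gts, loci), gts)]
  memo <- new.env(parent = emptyenv())
  rows <- lapply(gts, function(g) {
    cell <- landscape_cell(landscape, env, g)
    present <- unclass(loci)[genotype_mask(g, loci)]
    idx <- match(present, sgl$locus)
    ex <- expected_fitness(sgl$w_mean[idx], sgl$w_sd[idx], error_propagation)
    eps <- cell$w_mean - ex$w_exp
    sde <- epistasis_sd(cell$w_sd, ex$sd_exp, error_propagation)
    tst <- if (cell$n >= 2L) epistasis_test(eps, sde, cell$n)
           else list(t = NA_real_, df = cell$n - 1L, p = NA_real_, sd_eps = sde)
    ho <- if (length(present) >= 2L)
      eps_net_memo(landscape, env, g, sgl, memo) else NA_real_
    data.frame(environment = env, genotype = g, n_mut = length(present),
               w_obs = cell$w_mean, sd_obs = cell$w_sd,
               w_exp = ex$w_exp, sd_exp = ex$sd_exp,
               eps = eps, sd_eps = sde,
               t = tst$t, df = tst$df, p = tst$p, eps_higher = ho,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- switch(correction,
                      none = out$p,
                      bonferroni = stats::p.adjust(out$p, "bonferroni"),
                      bh = stats::p.adjust(out$p, "BH"))
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out <- out[c("environment", "genotype", "n_mut", "w_obs", "sd_obs",
               "w_exp", "sd_exp", "eps", "sd_eps", "t", "df", "p", "p_adj",
               "significant", "eps_higher")]
  rownames(out) <- NULL
  structure(out, loci = loci, alpha = alpha,
            class = c("epistasis_table", "data.frame"))
}

#' Mean epistasis across genotypes in one environment
#'
#' One-sample t-test of the per-genotype epistasis values against zero,
#' with a t-based 95% confidence interval. Restrict `records` to the
#' genotype class of interest first (e.g. `n_mut >= 2` for overall mean
#' epistasis; `n_mut >= 3` with `value = "eps_higher"` for the mean net
#' higher-order deviation).
#'
#' @param records an `epistasis_table` (or subset thereof).
#' @param value which column to average: `"eps"` (default) or `"eps_higher"`.
#' @return list with `mean`, `ci95` (half-width), `t`, `df`, `p`, `n`.
#' @export
mean_epistasis <- function(records, value = c("eps", "eps_higher")) {
  value <- match.arg(value)
  x <- records[[value]]
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need >= 2 epistasis records")
  tt <- stats::t.test(x, mu = 0)
  list(mean = unname(tt$estimate), ci95 = unname(diff(tt$conf.int)) / 2,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = length(x))
}

#' Diminishing-returns fit: epistasis versus expected fitness
#'
#' Diminishing-returns epistasis appears as a negative association between a
#' genotype's expected fitness and its epistasis. The fit reports the Pearson
#' correlation with a two-sided p, and a standard major axis (model II)
#' regression, appropriate because both axes are measured with error:
#' `slope = sign(r) * sd_y / sd_x`, `intercept = mean_y - slope * mean_x`.
#'
#' @param records an `epistasis_table` (one environment).
#' @param scale `"absolute"` (y = eps, default) or `"relative"`
#'   (y = eps / w_exp).
#' @return list with environment, scale, pearson_r, p_value, sma_slope,
#'   sma_intercept, n_genotypes.
#' @export
diminishing_returns_fit <- function(records, scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  x <- records$w_exp
  y <- if (scale == "absolute") records$eps else records$eps / records$w_exp
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 records for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in expected fitness or epistasis")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  list(environment = records$environment[1L], scale = scale,
       pearson_r = r, p_value = ct$p.value,
       sma_slope = slope, sma_intercept = mean(y) - slope * mean(x),
       n_genotypes = length(x))
}

#' Focal-mutation stratified analysis of the epistasis pattern
#'
#' Tests whether one locus drives the relationship between epistasis and
#' expected fitness, by stratifying the genotypes on presence/absence of the
#' locus: (a) a pooled-variance two-sample t-test of mean epistasis between
#' strata (df = n1 + n2 - 2); (b) an ANCOVA `eps ~ w_exp * has_locus` fit by
#' least squares, with F-tests for the change in fit when the
#' locus-by-fitness interaction term, or the locus main-effect term, is
#' dropped from the full model; (c) the per-stratum Pearson correlation.
#'
#' @param records an `epistasis_table` (one environment).
#' @param locus single locus character to stratify on.
#' @return list with group means/test, ANCOVA drop-term F-tests, and
#'   per-stratum correlations.
#' @export
focal_mutation_analysis <- function(records, locus) {
  loci <- attr(records, "loci")
  if (is.null(loci)) loci <- locus_set()
  if (!locus %in% unclass(loci)) stop("unknown locus '", locus, "'")
  has <- vapply(records$genotype, function(g) genotype_mask(g, loci)[
    match(locus, unclass(loci))], logical(1L), USE.NAMES = FALSE)
  d <- data.frame(eps = records$eps, w_exp = records$w_exp, has = has)
  d <- d[stats::complete.cases(d), ]
  if (min(table(d$has)) < 2L)
    stop("each stratum needs >= 2 records for locus '", locus, "'")
  tt <- stats::t.test(eps ~ has, data = d, var.equal = TRUE)
  full <- stats::lm(eps ~ w_exp * has, data = d)
  no_int <- stats::lm(eps ~ w_exp + has, data = d)
  no_main <- stats::lm(eps ~ w_exp + w_exp:has, data = d)
  a_int <- stats::anova(no_int, full)
  a_main <- stats::anova(no_main, full)
  strat_r <- function(sub) {
    if (nrow(sub) < 3L || stats::sd(sub$w_exp) == 0 || stats::sd(sub$eps) == 0)
      return(NA_real_)
    stats::cor(sub$w_exp, sub$eps)
  }
  list(locus = locus,
       mean_with = mean(d$eps[d$has]), mean_without = mean(d$eps[!d$has]),
       n_with = sum(d$has), n_without = sum(!d$has),
       group_t = unname(tt$statistic), group_df = unname(tt$parameter),
       group_p = tt$p.value,
       interaction_F = a_int$F[2L], interaction_p = a_int$`Pr(>F)`[2L],
       main_effect_F = a_main$F[2L], main_effect_p = a_main$`Pr(>F)`[2L],
       r_with = strat_r(d[d$has, ]), r_without = strat_r(d[!d$has, ]))
}
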