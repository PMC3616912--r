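#' Relative fitness from a serial-transfer competition
#'
#' Two strains are mixed, grown, and diluted `dilution`-fold into fresh medium
#' every 24 h for `days` days; densities (CFU/mL) are plated at the start and
#' end. The realized growth of a competitor is its net fold-expansion over the
#' whole competition, `final * dilution^(days-1) / initial` (the final plating
#' happens after growth on the last day, so only days - 1 transfers dilute the
#' culture between the two platings). Relative fitness is the ratio of natural
#' logs of realized growth (the Lenski convention):
#' `w = ln(RG_A) / ln(RG_B)`. `w = 1` is neutrality.
#'
#' @param A0,Af initial and final density of competitor A (the focal strain).
#' @param B0,Bf initial and final density of competitor B (the reference).
#' @param days length of the competition in days (>= 1).
#' @param dilution fold-dilution at each daily transfer (default 100).
#' @return relative fitness w of A versus B (dimensionless).
#' @examples
#' relative_fitness(1e5, exp(2) * 1e5, 1e5, exp(1) * 1e5, days = 1)  # 2
#' @export
relative_fitness <- function(A0, Af, B0, Bf, days = 3L, dilution = 100) {
  stopifnot(A0 > 0, Af > 0, B0 > 0, Bf > 0, days >= 1, dilution > 1 || days == 1)
  rg_a <- realized_growth(A0, Af, days, dilution)
  rg_b <- realized_growth(B0, Bf, days, dilution)
  if (rg_b <= 1)
    stop("reference competitor shows no net growth (realized growth <= 1); ",
         "log-ratio fitness is undefined")
  log(rg_a) / log(rg_b)
}

#' Net fold-expansion of one competitor over a serial-transfer assay
#' @inheritParams relative_fitness
#' @param initial,final densities at the first and last plating.
#' @return realized growth (dimensionless fold-expansion).
#' @export
realized_growth <- function(initial, final, days = 3L, dilution = 100) {
  stopifnot(initial > 0, final > 0)
  final * dilution^(days - 1) / initial
}

#' Relative fitness for a table of competition records
#'
#' @param df data.frame with columns `strain_A,strain_B,environment,replicate,
#'   A0,Af,B0,Bf,days,dilution` (the competitions CSV dialect).
#' @return the table with an added `w` column.
#' @export
competition_fitness <- function(df) {
  need <- c("strain_A", "strain_B", "environment", "replicate",
            "A0", "Af", "B0", "Bf", "days", "dilution")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("competition table is missing column(s): ", paste(miss, collapse = ", "))
  df$w <- mapply(relative_fitness, df$A0, df$Af, df$B0, df$Bf,
                 df$days, df$dilution)
  df
}

#' Area under a growth curve
#'
#' Trapezoidal integral of optical density over the recorded window, in
#' OD x hours. Raw OD is used as read (no blank subtraction or log
#' transform).
#'
#' @param times timepoints in hours, strictly increasing, length >= 2.
#' @param od OD600 readings, same length as `times`, all >= 0.
#' @return area under the curve (OD.h).
#' @export
auc <- function(times, od) {
  if (length(times) < 2L) stop("a growth curve needs at least 2 timepoints")
  stopifnot(length(times) == length(od))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od < 0)) stop("OD values must be >= 0")
  pracma::trapz(times, od)
}

#' Relative growth of a strain versus a reference
#' @param auc_strain,auc_reference areas under the two growth curves.
#' @return ratio of areas (dimensionless).
#' @export
relative_growth <- function(auc_strain, auc_reference) {
  if (auc_reference <= 0) stop("reference AUC must be > 0")
  auc_strain / auc_reference
}

#' Expected relative growth of a combination genotype under no epistasis
#'
#' The multiplicative null: the expected relative growth of a genotype is the
#' product of the relative growths of the constituent single mutants.
#' Propagated uncertainty uses the same machinery as [expected_fitness()].
#'
#' @param singles numeric vector of single-mutant relative growths (one per
#'   constituent mutation).
#' @param sds optional vector of their standard deviations (same length); if
#'   supplied, the propagated SD of the product is returned as an attribute.
#' @param error_propagation `"quadrature"` (root-sum-of-squares of relative
#'   errors, default) or `"linear"` (plain sum).
#' @return expected relative growth; with `sds`, attribute `"sd"` holds the
#'   propagated SD.
#' @export
expected_growth <- function(singles, sds = NULL,
                            error_propagation = c("quadrature", "linear")) {
  if (length(singles) < 1L) stop("need at least one single-mutant value")
  expc <- prod(singles)
  if (is.null(sds)) return(expc)
  stopifnot(length(sds) == length(singles), all(sds >= 0), all(singles > 0))
  structure(expc, sd = propagate_product_sd(expc, singles, sds,
                                            match.arg(error_propagation)))
}

#' Compare observed replicate relative growth to a no-epistasis expectation
#'
#' t-statistic is the deviation of the mean observed relative growth from the
#' expectation over the combined (propagated) standard deviation, with
#' df = n - 1 from the observed replicates — the same construction used for
#' fitness epistasis in [epistasis_test()].
#'
#' @param obs_reps replicate observed relative growths of the combination
#'   genotype.
#' @param expected expected relative growth (product of singles).
#' @param sd_expected propagated SD of the expectation.
#' @return data.frame with observed mean/sd, expectation, deviation, sd of the
#'   deviation, t, df and two-sided p.
#' @export
growth_epistasis_test <- function(obs_reps, expected, sd_expected = 0) {
  if (length(obs_reps) < 2L) stop("need >= 2 observed replicates")
  m <- mean(obs_reps); s <- stats::sd(obs_reps)
  eps <- m - expected
  tst <- epistasis_test(eps, epistasis_sd(s, sd_expected), length(obs_reps))
  data.frame(obs_mean = m, obs_sd = s, expected = expected,
             sd_expected = sd_expected, eps = eps, sd_eps = tst$sd_eps,
             t = tst$t, df = tst$df, p = tst$p)
}

#' Per-strain AUC and relative growth from a long plate-reader table
#'
#' @param df long data.frame with columns `strain,replicate,time_h,od`.
#' @param reference strain label of the reference (ancestor) whose mean AUC
#'   scales the others.
#' @return data.frame with one row per (strain, replicate): auc and
#'   rel_growth (AUC over the reference mean AUC).
#' @export
growth_table <- function(df, reference = "anc") {
  need <- c("strain", "replicate", "time_h", "od")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("growth table is missing column(s): ", paste(miss, collapse = ", "))
  sp <- split(df, list(df$strain, df$replicate), drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$time_h), ]
    data.frame(strain = d$strain[1L], replicate = d$replicate[1L],
               auc = auc(d$time_h, d$od), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  ref <- out$auc[out$strain == reference]
  if (!length(ref)) stop("reference strain '", reference, "' not in table")
  out$rel_growth <- out$auc / mean(ref)
  out[order(out$strain, out$replicate), ]
}
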