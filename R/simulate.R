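## Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic fitness landscape with known ground truth
#'
#' The generative model mirrors the epistasis decomposition it is meant to
#' exercise: true fitness of a genotype is the product of its per-locus
#' multiplicative effects plus the sum of planted net interaction terms over
#' its mutation subsets,
#' `w_true(g) = prod(singles) + sum over B subset of g, |B| >= 2 of
#' eps_net(B)`. Interaction coefficients differ between environments, which
#' plants GxE (through the singles) and GxGxE (through the interactions)
#' structure by construction.
#'
#' @param loci a [locus_set()].
#' @param environments character vector of environment labels.
#' @param singles named list: per environment, a named numeric vector of
#'   single-mutant fitnesses (one per locus, all > 0).
#' @param eps_net named list: per environment, a named numeric vector of net
#'   interaction coefficients keyed by canonical genotype label (size >= 2);
#'   loci combinations not listed default to 0.
#' @param n_reps replicate measurements per (environment, genotype).
#' @param noise_sd SD of additive Gaussian measurement noise on w.
#' @param seed integer seed; the spec plus seed fully determine every output.
#' @return a `landscape_spec` object.
#' @export
landscape_spec <- function(loci, environments, singles, eps_net = NULL,
                           n_reps = 5L, noise_sd = 0.03, seed = 1L) {
  stopifnot(inherits(loci, "locus_set"), length(environments) >= 1L,
            n_reps >= 1L, noise_sd >= 0)
  environments <- as.character(environments)
  if (is.null(eps_net)) eps_net <- stats::setNames(
    rep(list(numeric(0L)), length(environments)), environments)
  for (e in environments) {
    s <- singles[[e]]
    if (is.null(s) || !all(unclass(loci) %in% names(s)))
      stop("singles for environment '", e, "' must name every locus")
    if (any(s <= 0)) stop("single-mutant fitnesses must be > 0")
    en <- eps_net[[e]]
    if (length(en)) {
      canon <- parse_genotype(names(en), loci)
      if (any(genotype_size(canon, loci) < 2L))
        stop("eps_net coefficients need >= 2 mutations")
      if (anyDuplicated(canon)) stop("duplicated eps_net coefficient")
      names(eps_net[[e]]) <- canon
    }
  }
  spec <- structure(list(loci = loci, environments = environments,
                         singles = singles, eps_net = eps_net,
                         n_reps = as.integer(n_reps), noise_sd = noise_sd,
                         seed = as.integer(seed)),
                    class = "landscape_spec")
  tl <- true_landscape(spec)  # validates all implied w_true > 0
  if (any(tl$w_mean <= 0))
    stop("spec implies non-positive true fitness for: ",
         paste(tl$genotype[tl$w_mean <= 0], collapse = ", "))
  spec
}

#' Default synthetic landscape mirroring the study conditions
#'
#' Five loci in fixation order (r, t, s, g, p); three environments — the
#' original selection environment plus one raising and one lowering the fitness
#' of the full mutant; single-mutant effects taken from the study's reported
#' per-environment fitness gains; five replicates per cell with Gaussian
#' measurement noise of SD 0.03. Interaction coefficients were chosen once to
#' reproduce the qualitative topology reported for each environment: a smooth
#' selection landscape with a single peak at the full mutant and most paths
#' accessible under mild diminishing returns; an `env_up` landscape with a
#' strongly antagonistic t-g pair partly rescued by positive higher-order
#' terms, slightly negative mean epistasis and roughly a third of paths
#' accessible; and an `env_down` landscape with positive mean pairwise but
#' negative higher-order epistasis, a strongly negative diminishing-returns
#' correlation, only a handful of accessible paths, and a global peak at the
#' three-mutation genotype rts rather than the full mutant.
#'
#' @inheritParams landscape_spec
#' @return a `landscape_spec`.
#' @export
default_landscape_spec <- function(n_reps = 5L, noise_sd = 0.03, seed = 1L) {
  loci <- locus_set()
  singles <- list(
    selection = c(r = 1.015, t = 1.133, s = 1.094, g = 1.05, p = 1.00),
    env_up    = c(r = 1.000, t = 1.220, s = 1.060, g = 1.04, p = 1.12),
    env_down  = c(r = 1.005, t = 1.130, s = 0.920, g = 1.01, p = 0.99))
  eps_net <- list(
    selection = c(rt = -0.01, rs = -0.01, rg = -0.01, ts = -0.02, tg = -0.02,
                  sg = -0.02, rp = 0.02, tp = 0.03, sp = 0.03, gp = 0.03),
    env_up    = c(tg = -0.25, ts = -0.03, tp = -0.03, sp = -0.03, sg = -0.03,
                  gp = -0.03, rt = 0.02, rs = 0.02, rp = 0.02,
                  rtg = 0.08, tsg = 0.10, tgp = 0.10,
                  rtsg = 0.02, rtgp = 0.02, tsgp = 0.02, rtsgp = -0.02),
    env_down  = c(rs = 0.08, ts = 0.14, sg = 0.07, sp = 0.08,
                  rt = -0.04, rg = -0.03, rp = -0.03, tg = -0.05, tp = -0.05,
                  gp = 0.02,
                  rts = -0.02, tsp = -0.04, rsp = -0.01, sgp = -0.04,
                  tsg = -0.03, rtsgp = 0.05))
  landscape_spec(loci, names(singles), singles, eps_net,
                 n_reps = n_reps, noise_sd = noise_sd, seed = seed)
}

## True fitness of one genotype in one environment under a spec.
spec_w_true <- function(spec, env, genotype) {
  loci <- spec$loci
  mask <- genotype_mask(genotype, loci)
  base <- prod(spec$singles[[env]][unclass(loci)[mask]])
  en <- spec$eps_net[[env]]
  if (!length(en)) return(base)
  subs <- c(subsets(genotype, loci, min_size = 2L),
            if (sum(mask) >= 2L) genotype)
  base + sum(en[names(en) %in% subs])
}

#' Noise-free landscape implied by a spec
#'
#' @param spec a [landscape_spec()].
#' @return a `landscape_summary` with the exact true means (w_sd = 0, n = 1).
#' @export
true_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  gts <- all_genotypes(spec$loci)
  rows <- lapply(spec$environments, function(e)
    data.frame(environment = e, genotype = gts,
               n_mut = genotype_size(gts, spec$loci),
               w_mean = vapply(gts, spec_w_true, numeric(1L), spec = spec,
                               env = e),
               w_sd = 0, n = 1L, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, loci = spec$loci,
            class = c("landscape_summary", "data.frame"))
}

#' Simulate a replicate-level fitness table from a spec
#'
#' Each replicate draws `w = w_true + Normal(0, noise_sd)`, resampling any
#' non-positive draw (fitness is a ratio of log growth and must be positive).
#' Output is fully determined by the spec and its seed.
#'
#' @param spec a [landscape_spec()].
#' @return replicate-level fitness table (environment, genotype, replicate, w)
#'   with the spec's `loci` attached.
#' @export
simulate_fitness_table <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  truth <- true_landscape(spec)
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      w <- truth$w_mean[i] + stats::rnorm(spec$n_reps, 0, spec$noise_sd)
      bad <- which(w <= 0)
      while (length(bad)) {
        w[bad] <- truth$w_mean[i] + stats::rnorm(length(bad), 0, spec$noise_sd)
        bad <- which(w <= 0)
      }
      data.frame(environment = truth$environment[i],
                 genotype = truth$genotype[i],
                 replicate = seq_len(spec$n_reps), w = w,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "loci") <- spec$loci
    out
  })
}

#' Competition plate-count records encoding target fitness values
#'
#' Inverts the serial-transfer fitness formula: the reference competitor is
#' given a fixed realized growth (`dilution^days`, i.e. it exactly balances
#' the daily transfers with a hundredfold net expansion per day), and the
#' focal competitor's final density is chosen so that [relative_fitness()]
#' returns the target w exactly.
#'
#' @param targets data.frame with columns environment, genotype (or strain_A),
#'   replicate, w — e.g. the output of [simulate_fitness_table()].
#' @param days,dilution competition length and daily transfer dilution.
#' @param A0,B0 initial densities (CFU/mL).
#' @param reference label for competitor B.
#' @return competitions table in the package CSV dialect (strain_A, strain_B,
#'   environment, replicate, A0, Af, B0, Bf, days, dilution).
#' @export
simulate_competitions <- function(targets, days = 3L, dilution = 100,
                                  A0 = 1e5, B0 = 1e5, reference = "anc") {
  strain <- if ("genotype" %in% names(targets)) targets$genotype
            else targets$strain_A
  rg_b <- dilution^days
  Bf <- B0 * rg_b / dilution^(days - 1)
  rg_a <- rg_b^targets$w
  data.frame(strain_A = strain, strain_B = reference,
             environment = targets$environment,
             replicate = targets$replicate,
             A0 = A0, Af = A0 * rg_a / dilution^(days - 1),
             B0 = B0, Bf = Bf, days = days, dilution = dilution,
             stringsAsFactors = FALSE)
}

#' Logistic growth curves whose AUC ratios encode target relative growth
#'
#' The reference strain follows a logistic OD trajectory
#' `K / (1 + ((K - od0)/od0) exp(-r t))`; each other strain's curve is the
#' reference trajectory scaled by its target relative growth, so the ratio of
#' areas under the curves equals the target exactly in the noise-free case.
#' Optional Gaussian read noise (truncated at 0) is added per well read.
#'
#' @param targets named numeric vector of relative growth per strain (the
#'   reference gets 1 implicitly if absent).
#' @param n_reps replicate wells per strain.
#' @param times read times in hours (default every 15 min for 24 h).
#' @param od0,K,r logistic initial OD, capacity, and rate (per hour).
#' @param noise_sd SD of additive OD read noise.
#' @param seed integer seed.
#' @param reference reference strain label.
#' @return long plate-reader table (strain, replicate, time_h, od).
#' @export
simulate_growth_curves <- function(targets, n_reps = 12L,
                                   times = seq(0, 24, by = 0.25),
                                   od0 = 0.02, K = 0.5, r = 0.8,
                                   noise_sd = 0, seed = 1L,
                                   reference = "anc") {
  if (!reference %in% names(targets))
    targets <- c(stats::setNames(1, reference), targets)
  base <- K / (1 + ((K - od0) / od0) * exp(-r * times))
  with_seed(seed, {
    rows <- lapply(names(targets), function(s) {
      do.call(rbind, lapply(seq_len(n_reps), function(rep) {
        od <- targets[[s]] * base
        if (noise_sd > 0) od <- pmax(0, od + stats::rnorm(length(od), 0, noise_sd))
        data.frame(strain = s, replicate = rep, time_h = times, od = od,
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Synthetic phenotype-microarray kinetic curves with planted calls
#'
#' Every environment gets a saturating respiration curve scaled so the
#' average curve height equals the strain's target h. The ancestor's target
#' height is `h_base` everywhere; the evolved strain's height is multiplied
#' by `gain_factor` in planted gain environments and by `loss_factor` in
#' planted loss environments. Replicate-to-replicate variability is modelled
#' as a plate effect shared by both strains on the same replicate plate (the
#' dominant source of variation in duplicate phenotype-microarray runs), so
#' unplanted wells have identical strain means and are never called, while
#' planted wells exceed the 3-SD differential rule by construction.
#'
#' @param n_env number of environments (wells).
#' @param gains,losses integer indices of environments planted as gains /
#'   losses of function for the evolved strain.
#' @param h_base ancestor mean curve height (arbitrary units).
#' @param gain_factor,loss_factor multiplicative height change in planted
#'   wells.
#' @param n_reps replicate plates (duplicate by default).
#' @param noise_sd SD of the multiplicative plate effect shared by both
#'   strains on a replicate plate (relative units).
#' @param times read times in hours.
#' @param tau saturation time constant (hours).
#' @param seed integer seed.
#' @return long kinetic-curve table (strain, environment, replicate, time_h,
#'   signal) with strains `"evolved"` and `"ancestor"`.
#' @export
simulate_biolog <- function(n_env = 96L, gains = integer(0L),
                            losses = integer(0L), h_base = 70,
                            gain_factor = 1.5, loss_factor = 0.6,
                            n_reps = 2L, noise_sd = 0.01,
                            times = seq(0, 48, by = 0.25), tau = 8,
                            seed = 1L) {
  stopifnot(!length(intersect(gains, losses)))
  envs <- sprintf("env%03d", seq_len(n_env))
  shape <- 1 - exp(-times / tau)
  shape <- shape / (pracma::trapz(times, shape) / diff(range(times)))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_env)) {
      plate <- 1 + stats::rnorm(n_reps, 0, noise_sd)
      h_anc <- h_base
      h_evo <- h_base *
        if (i %in% gains) gain_factor else if (i %in% losses) loss_factor else 1
      for (strain in c("evolved", "ancestor")) {
        h <- if (strain == "evolved") h_evo else h_anc
        for (rep in seq_len(n_reps)) {
          rows[[length(rows) + 1L]] <-
            data.frame(strain = strain, environment = envs[i],
                       replicate = rep, time_h = times,
                       signal = pmax(0, h * plate[rep] * shape),
                       stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate every assay input the pipeline consumes
#'
#' @param spec a [landscape_spec()].
#' @return list with `fitness` (replicate table), `competitions` (plate
#'   counts encoding the same replicate fitness values), `growth` (logistic
#'   OD curves for the single mutants, one double mutant and the full mutant
#'   in the first environment), and `biolog` (kinetic screen with three
#'   planted gains and one planted loss).
#' @export
simulate_assays <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  fitness <- simulate_fitness_table(spec)
  truth <- true_landscape(spec)
  env1 <- spec$environments[1L]
  tr <- truth[truth$environment == env1, ]
  strains <- c(unclass(spec$loci),
               format_genotype(c(rep(FALSE, length(spec$loci) - 2L), TRUE, TRUE),
                               spec$loci),
               format_genotype(rep(TRUE, length(spec$loci)), spec$loci))
  growth_targets <- stats::setNames(tr$w_mean[match(strains, tr$genotype)],
                                    strains)
  list(fitness = fitness,
       competitions = simulate_competitions(fitness),
       growth = simulate_growth_curves(growth_targets, seed = spec$seed),
       biolog = simulate_biolog(gains = c(3L, 17L, 41L), losses = 60L,
                                seed = spec$seed))
}

#' Calibrate the planted GxGxE variance share of a spec
#'
#' Rescales the between-environment deviation of every planted interaction
#' coefficient around its cross-environment mean by a common factor `s`
#' (`eps_net(B, e) -> mean_e eps_net(B, e) + s * deviation`), solving for the
#' `s` at which the noise-free GxGxE share of the total ANOVA sum of squares
#' equals `target`. The noise-free share is computed by running the
#' full-factorial ANOVA on the exact true cell means.
#'
#' @param spec a [landscape_spec()] with >= 2 environments.
#' @param target desired GxGxE SS fraction (default 0.08).
#' @param interval search interval for the scale factor.
#' @return the calibrated `landscape_spec`.
#' @export
calibrate_gxgxe <- function(spec, target = 0.08, interval = c(0, 20)) {
  stopifnot(inherits(spec, "landscape_spec"), length(spec$environments) >= 2L)
  all_B <- unique(unlist(lapply(spec$eps_net, names)))
  base <- vapply(all_B, function(B) mean(vapply(
    spec$environments, function(e) {
      v <- spec$eps_net[[e]][B]; if (is.na(v)) 0 else unname(v)
    }, numeric(1L))), numeric(1L))
  scaled_spec <- function(s) {
    en <- lapply(spec$environments, function(e) {
      v <- vapply(all_B, function(B) {
        x <- spec$eps_net[[e]][B]; if (is.na(x)) 0 else unname(x)
      }, numeric(1L))
      stats::setNames(base + s * (v - base), all_B)
    })
    names(en) <- spec$environments
    landscape_spec(spec$loci, spec$environments, spec$singles, en,
                   n_reps = spec$n_reps, noise_sd = spec$noise_sd,
                   seed = spec$seed)
  }
  share <- function(s) {
    truth <- true_landscape(scaled_spec(s))
    tab <- data.frame(environment = truth$environment,
                      genotype = truth$genotype, replicate = 1L,
                      w = truth$w_mean, stringsAsFactors = FALSE)
    attr(tab, "loci") <- spec$loci
    # saturated noise-free fit: F-tests are meaningless here, only SS are used
    vp <- variance_partition(suppressWarnings(gxe_anova(tab)))
    vp$fraction[vp$class == "GxGxE"]
  }
  # stay inside the feasible region (all implied true fitnesses positive)
  upper <- interval[2L]
  while (upper > interval[1L] &&
         inherits(try(scaled_spec(upper), silent = TRUE), "try-error"))
    upper <- upper / 2
  s_star <- stats::uniroot(function(s) share(s) - target,
                           c(interval[1L], upper), tol = 1e-8)$root
  scaled_spec(s_star)
}
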