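---
title: "Environment-dependent epistasis on a combinatorially complete fitness landscape"
author: "epiland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment-dependent epistasis on a combinatorially complete fitness landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiland)
```

## The problem

A combinatorially complete fitness landscape assigns a relative fitness to
every subset of L focal mutations — 2^L genotypes in all — in one or more
external environments. The motivating system is a set of five beneficial
mutations (in *rbs*, *topA*, *spoT*, *glmUS* and *pykF*, abbreviated r, t, s,
g, p in their order of fixation) from a laboratory-evolved *Escherichia coli*
population, whose 32 combination genotypes were assayed by head-to-head
competition against the ancestor. Measuring the same genotypes in several
environments separates three kinds of effects on fitness:

* **G x G (epistasis)** — a combination's fitness deviates from what its
  constituent mutations predict;
* **G x E (plasticity)** — a single mutation's effect depends on the
  environment;
* **G x G x E** — the *interactions between mutations* depend on the
  environment, which reshapes the topology of the landscape itself.

`epiland` implements the full analysis chain: assay-level fitness
computations, the epistasis decomposition with propagated measurement error,
landscape topology (accessible mutational paths and peaks), and a
full-factorial ANOVA that partitions fitness variance across the classes
above.

## The multiplicative null and the epistasis decomposition

Relative fitness from a serial-transfer competition is the ratio of natural
logs of each competitor's realized growth (its net fold-expansion over the
assay, `final x dilution^(days-1) / initial`); `w = 1` is neutrality. On this
scale, the conventional null model for combining beneficial mutations is
multiplicative: for a genotype `g` carrying mutations with single-mutant
fitnesses `w_i`,

    w_exp(g) = prod_i w_i .

**Absolute epistasis** is the signed deviation of the observed mean fitness
from this expectation:

    eps(g) = w_obs(g) - prod_i w_i .

Measurement error propagates through the product from the relative errors of
the singles, and into epsilon from both components. The default is standard
root-sum-of-squares propagation,

    sd_exp = w_exp * sqrt( sum_i (sd_i / w_i)^2 ),
    sd_eps = sqrt( sd_obs^2 + sd_exp^2 ),

with a linear-sum option (`error_propagation = "linear"`) because the
summation convention differs between texts; both are exposed so results can
be compared under either. Significance uses `t = eps / sd_eps` with
`df = n_reps - 1` taken from the observed genotype's replication and a
two-sided p. Note that `sd_obs` and `sd_i` are replicate *sample* standard
deviations, not standard errors of means — this follows the source assays'
convention and makes the test conservative.

**Net higher-order epistasis** asks whether interactions among three or more
mutations add anything beyond their constituent lower-order interactions.
The decomposition is recursive: for a pair the net term is its absolute
epistasis, and for larger genotypes

    eps_HO(g) = eps_abs(g) - sum over proper subsets B of g, |B| >= 2, of eps_net(B),

with `eps_net(g) = eps_HO(g)`. Because this is exactly inclusion–exclusion,
the decomposition is order-independent and reconstructs observed fitness
identically: `w_obs(g) = prod singles + sum over subsets B (|B| >= 2) of
eps_net(B)`. The test suite verifies this identity to floating-point
precision on random landscapes. This is narrower than a Walsh/Fourier
spectral decomposition: it is anchored to the multiplicative null on the
fitness scale and uses only the measured cell means.

```{r decomposition}
tl <- true_landscape(default_landscape_spec())
et <- epistasis_table(tl, "env_up")
head(et[, c("genotype", "n_mut", "w_obs", "w_exp", "eps", "eps_higher")])
```

## Diminishing returns and focal-mutation analyses

Diminishing-returns epistasis appears as a negative association between a
genotype's expected fitness and its epistasis. `diminishing_returns_fit()`
reports the Pearson correlation (two-sided p) together with a standard major
axis (model II) regression, `slope = sign(r) * sd_y / sd_x` — appropriate
because expected fitness is itself measured with error, so ordinary least
squares on either axis would be biased. Both the absolute (`eps`) and
relative (`eps / w_exp`) scales are implemented since either can reasonably
be plotted against expectation; results are reported for whichever is
requested rather than guessing a single convention.

`focal_mutation_analysis()` checks whether one locus drives the overall
pattern: a pooled-variance two-sample t-test of mean epsilon between
genotypes with and without the locus (df = n1 + n2 - 2, which is 24 for the
26 multi-mutation genotypes of a five-locus landscape), an ANCOVA
`eps ~ w_exp * has_locus` with F-tests for dropping the interaction term or
the locus main-effect term from the full model, and per-stratum
correlations.

## Landscape topology: accessible paths, steps, peaks

An ordering of the L mutations is **selectively accessible** if fitness
increases at every one of its L steps; there are `L! = 120` orderings for
five loci. Two accessibility modes are provided:

* `"mean"` (default): strict increase of cell means; ties count as
  inaccessible, matching the "monotonically increasing fitness" criterion.
* `"significant"`: every step must be significantly beneficial, using the
  per-edge t-test (`delta_w / sqrt(sd_from^2 + sd_to^2)`, df from the
  less-replicated cell) with Bonferroni correction over all `L * 2^(L-1)`
  directed edges by default. This mode is strictly more stringent, and with
  replicate-SD-based errors it is *very* conservative — a deliberate
  property inherited from the underlying assay convention.

Only edges toward more-mutated genotypes are considered; reversions are out
of scope. `peaks()` reports local maxima (no better Hamming-1 neighbour,
ties included) and the global maximum.

## The genotype-by-environment ANOVA

`gxe_anova()` fits the full factorial of L two-level locus factors and the
environment factor with effect (sum-to-zero) coding, so that on a balanced
design the per-term sums of squares are orthogonal and the class-level
shares are well defined. For L = 5 and two environments the model has
`2^6 - 1 = 63` non-intercept degrees of freedom — the "six-way ANOVA".
`variance_partition()` sums term SS within the classes G, GxG, E, GxE and
GxGxE and reports raw SS fractions of the total (not variance-component
estimates); fractions sum to one by construction. Unbalanced tables are
fitted with sequential SS in a documented order (main effects, then
ascending interaction order) and flagged with a warning. In the one-factor
case the ANOVA F reduces exactly to the square of the pooled two-sample t.

## Assay-level computations

* **Competition fitness**: `relative_fitness()` implements the log-ratio
  fitness with serial-transfer bookkeeping `final * dilution^(days-1) /
  initial`. The final plating happens after the last day's growth, so only
  `days - 1` transfers separate the two platings; this matches the classic
  serial-transfer convention. Plating-dilution factors shared by both
  competitors cancel from the ratio and are not modelled. A reference
  competitor with realized growth at or below 1 has no defined log-ratio and
  is an error.
* **Growth curves**: relative growth is the ratio of trapezoidal AUCs of raw
  OD600 over the recorded window (no blank subtraction or log transform), and
  the multiplicative expectation for a combination genotype is the product of
  single-mutant relative growths, compared to observation with the same
  t machinery as fitness epistasis.
* **Phenotype microarrays**: a well's activity is the average height h of its
  kinetic respiration curve (trapezoidal integral over window length). Two
  strains differ in an environment when their mean h differ by more than
  3 SD of h *for both strains* — the conjunctive reading, which is the most
  conservative consistent interpretation of the criterion; the multiplier
  and a disjunctive variant are configuration. With duplicate plates the SD
  of two values has little power, which is flagged rather than hidden: zero
  SDs degenerate the rule to "any nonzero difference" and set a `degenerate`
  flag on the call.

## The synthetic-data generator

Because the study's raw replicate measurements are not deposited, every
input the pipeline consumes can be generated with known ground truth. The
generative model inverts the decomposition above:

    w_true(g) = prod_i singles_i + sum over B subset of g, |B| >= 2 of eps_net(B),

with per-environment singles and interaction coefficients, additive Gaussian
measurement noise on w (the scale the t-tests operate on), truncated at zero
by resampling. `default_landscape_spec()` fixes the study conditions: five
loci, three environments (`selection`, `env_up`, `env_down`), five
replicates per cell and noise SD 0.03 — within the "no less than three-fold,
typically five-fold" replication the assays used. Single-mutant effects are
the study's reported per-environment fitness gains. Interaction coefficients
were chosen once to reproduce each environment's reported qualitative
topology: a smooth selection landscape (single peak at the full mutant, most
orderings accessible, mild diminishing returns), an `env_up` landscape with
one strongly antagonistic pair partly rescued by positive higher-order terms
(slightly negative mean epistasis, about a third of paths accessible), and an
`env_down` landscape with positive pairwise but negative higher-order terms,
a strong negative diminishing-returns correlation, very few accessible paths
and a global peak at the three-mutation genotype rts.

The generator emulates the statistical structure the analysis assumes —
independent Gaussian replicate noise, exact multiplicative composition plus
planted interaction terms, plate effects shared between strains on a
phenotype-microarray plate. It does not emulate day effects, marker costs,
counting (plating) error, or any mechanistic population dynamics, so passing
recovery tests demonstrates correctness of the statistical machinery, not
that real assay data satisfy these assumptions.

Assay generators are exact inversions where possible: competition counts
reproduce a target w to floating-point precision via the fitness formula;
growth curves are logistic trajectories scaled so AUC ratios equal target
relative growth; microarray curves are saturating curves with planted
gain/loss factors that exceed the 3-SD rule by construction.

`calibrate_gxgxe()` supports parameter-recovery experiments that require a
known environment-interaction share: it rescales the between-environment
deviation of every interaction coefficient around its cross-environment mean
and solves (by `uniroot` on the noise-free SS decomposition) for the scale at
which the GxGxE share of total SS equals a requested value, staying inside
the region where all implied fitnesses are positive.

```{r recovery}
spec <- default_landscape_spec(seed = 7)
tab <- simulate_fitness_table(spec)
res <- run_pipeline(tab)
writeLines(res$summary)
```

## Numerical and design choices

* **Replicate SD** uses the n - 1 denominator, feeding t-tests with
  df = n - 1; single-replicate cells get SD 0 with a warning.
* **Degenerate tests** (sd_eps = 0) are flagged, never reported as p = 0.
* **Ties** in accessibility and peaks: steps with exactly equal means are
  inaccessible; peak ties are reported as sets.
* **Multiple testing**: per-genotype epistasis calls are uncorrected by
  default (matching how per-genotype counts are usually quoted), with
  Bonferroni and Benjamini–Hochberg options; per-step calls over the 80
  hypercube edges are Bonferroni-corrected by default.
* **Genotype labels**: presence letters in fixation order (`"rts"`, never
  `"srt"`), with bitstrings accepted on input and `"anc"` as the ancestor
  token; locus order is configuration, so landscapes with L other than 5
  work throughout.
* **ANOVA replicate layout**: synthetic runs use 5 replicates per cell (320
  observations for two environments). The source analysis reports residual
  df 261, implying 325 observations in a layout that was never published;
  the balanced 5-replicate layout is the closest reconstruction and is used
  consistently.
* **Reproducibility**: generators are pure functions of (spec, seed); the
  pipeline is deterministic given its inputs, and report CSVs use fixed
  column order with 6 significant digits.

## Known limitations

* The epistasis error model treats single-mutant estimates as independent
  between genotypes; shared-ancestor correlations are not modelled.
* Accessibility is a purely rank-based notion on mean fitness — no
  population-genetic dynamics (fixation probabilities, clonal interference)
  are implied.
* The microarray screen consumes kinetic curves; reproducing a commercial
  instrument's internal preprocessing is out of scope, and the published
  screen-wide counts cannot be reproduced without the unpublished raw
  curves.
* Tests exercise landscapes up to L = 8; path enumeration is factorial in L
  and is not intended for large L.
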