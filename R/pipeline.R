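#' Run the full landscape analysis end to end
#'
#' Orchestrates the whole analysis in the order of the underlying study:
#' summarise replicate fitness into a landscape; per environment, build the
#' epistasis decomposition (multiplicative null, propagated errors, t-tests,
#' net higher-order terms), the mean-epistasis and mean higher-order tests,
#' the diminishing-returns fit, and the path/edge/peak topology reports; then
#' the full-factorial GxE ANOVA with variance partitioning. Deterministic
#' given its inputs; all outputs are plain CSV/text with fixed column order
#' and 6 significant digits.
#'
#' @param fitness replicate-level fitness table (data.frame) or path to its
#'   CSV (columns environment, genotype, replicate, w).
#' @param loci a [locus_set()].
#' @param alpha two-sided significance level.
#' @param error_propagation `"quadrature"` or `"linear"` (see
#'   [expected_fitness()]).
#' @param epistasis_scale `"absolute"` or `"relative"` scale for the
#'   diminishing-returns fit.
#' @param correction multiple-testing correction for per-genotype epistasis
#'   calls (`"none"`, `"bonferroni"`, `"bh"`).
#' @param edge_correction correction for per-step significance over the
#'   hypercube edges (default `"bonferroni"`).
#' @param outdir if non-NULL, directory into which all report CSVs, the
#'   plain-text summary and the configuration echo are written.
#' @return (invisibly if writing) a list with elements `landscape`,
#'   `epistasis` (per environment), `mean_eps`, `mean_higher`, `dr_fit`,
#'   `paths`, `edges`, `peaks` (per environment), `anova`, `partition` and
#'   `summary` (character lines echoing the headline statistics).
#' @export
run_pipeline <- function(fitness, loci = locus_set(), alpha = 0.05,
                         error_propagation = c("quadrature", "linear"),
                         epistasis_scale = c("absolute", "relative"),
                         correction = c("none", "bonferroni", "bh"),
                         edge_correction = "bonferroni", outdir = NULL) {
  error_propagation <- match.arg(error_propagation)
  epistasis_scale <- match.arg(epistasis_scale)
  correction <- match.arg(correction)
  obs <- if (is.character(fitness)) load_fitness_table(fitness, loci)
         else validate_fitness_table(fitness, loci)
  landscape <- summarize_landscape(obs, loci)
  envs <- landscape_environments(landscape)
  per_env <- function(f) stats::setNames(lapply(envs, f), envs)

  eps_tabs <- per_env(function(e)
    epistasis_table(landscape, e, alpha = alpha,
                    error_propagation = error_propagation,
                    correction = correction))
  mean_eps <- per_env(function(e) mean_epistasis(eps_tabs[[e]], "eps"))
  mean_higher <- per_env(function(e)
    mean_epistasis(eps_tabs[[e]][eps_tabs[[e]]$n_mut >= 3L, ], "eps_higher"))
  dr_fit <- per_env(function(e)
    diminishing_returns_fit(eps_tabs[[e]], scale = epistasis_scale))
  edges <- per_env(function(e)
    step_effects(landscape, e, alpha = alpha, correction = edge_correction))
  path_tabs <- per_env(function(e)
    path_report(landscape, e, alpha = alpha, correction = edge_correction))
  peak_sets <- per_env(function(e) peaks(landscape, e))
  aov_fit <- gxe_anova(obs, loci)
  part <- variance_partition(aov_fit)

  summary_lines <- c(
    sprintf("landscape: %d loci, %d genotypes, %d environment(s)",
            length(loci), length(all_genotypes(loci)), length(envs)),
    unlist(lapply(envs, function(e) {
      me <- mean_eps[[e]]; mh <- mean_higher[[e]]; dr <- dr_fit[[e]]
      pr <- path_tabs[[e]]
      c(sprintf("[%s] mean epistasis = %.4f +/- %.4f (95%% CI), t_%d = %.3f, p = %.3g",
                e, me$mean, me$ci95, me$df, me$t, me$p),
        sprintf("[%s] mean higher-order deviation = %.4f +/- %.4f, t_%d = %.3f, p = %.3g",
                e, mh$mean, mh$ci95, mh$df, mh$t, mh$p),
        sprintf("[%s] diminishing returns: r = %.3f (p = %.3g), SMA slope = %.3f",
                e, dr$pearson_r, dr$p_value, dr$sma_slope),
        sprintf("[%s] accessible paths: %d of %d (mean), %d (significant steps)",
                e, sum(pr$accessible_mean), nrow(pr),
                sum(pr$accessible_significant)),
        sprintf("[%s] significant epistasis in %d of %d genotypes; global peak: %s",
                e, sum(eps_tabs[[e]]$significant, na.rm = TRUE),
                nrow(eps_tabs[[e]]),
                paste(peak_sets[[e]]$global_maximum, collapse = ",")))
    })),
    sprintf("GxE ANOVA: F_%d,%d = %.3f, p = %.3g", aov_fit$model_df,
            aov_fit$residual_df, aov_fit$model_F, aov_fit$model_p),
    sprintf("variance fractions: %s",
            paste(sprintf("%s = %.3f", part$class, part$fraction),
                  collapse = ", ")))

  res <- list(landscape = landscape, epistasis = eps_tabs,
              mean_eps = mean_eps, mean_higher = mean_higher,
              dr_fit = dr_fit, paths = path_tabs, edges = edges,
              peaks = peak_sets, anova = aov_fit, partition = part,
              summary = summary_lines)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name)
      utils::write.csv(format_numeric(as.data.frame(df)),
                       file.path(outdir, name), row.names = FALSE,
                       quote = FALSE)
    write_landscape(landscape, file.path(outdir, "landscape_summary.csv"))
    for (e in envs) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", e)
      wcsv(eps_tabs[[e]], sprintf("epistasis_%s.csv", safe))
      wcsv(path_tabs[[e]], sprintf("paths_%s.csv", safe))
      wcsv(edges[[e]], sprintf("edges_%s.csv", safe))
    }
    wcsv(aov_fit$table, "anova.csv")
    wcsv(part, "variance_partition.csv")
    writeLines(summary_lines, file.path(outdir, "summary.txt"))
    cfg <- c(sprintf("loci=%s", paste(unclass(loci), collapse = "")),
             sprintf("alpha=%g", alpha),
             sprintf("error_propagation=%s", error_propagation),
             sprintf("epistasis_scale=%s", epistasis_scale),
             sprintf("correction=%s", correction),
             sprintf("edge_correction=%s", edge_correction))
    writeLines(cfg, file.path(outdir, "config.txt"))
    return(invisible(res))
  }
  res
}
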