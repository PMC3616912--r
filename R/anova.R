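## Classify a model term into G / GxG / E / GxE / GxGxE by the number of
## locus factors it involves and whether it includes the environment factor.
classify_term <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  n_loci <- sum(startsWith(parts, "m_"))
  has_env <- "env" %in% parts
  if (!has_env) {
    if (n_loci == 1L) "G" else "GxG"
  } else {
    if (n_loci == 0L) "E" else if (n_loci == 1L) "GxE" else "GxGxE"
  }
}

#' Describe the full-factorial genotype-by-environment design
#'
#' Enumerates every non-intercept term of the full factorial over L two-level
#' locus factors and one E-level environment factor: all non-empty subsets of
#' the L + 1 factors, `2^(L+1) - 1` terms (63 for L = 5, E = 2), each with
#' `(E - 1)^(env in term)` degrees of freedom. Terms are effect-coded
#' (sum-to-zero contrasts) so that on balanced data their sums of squares are
#' orthogonal and class-level variance fractions are well defined.
#'
#' @param loci a [locus_set()].
#' @param environments character vector of environment labels (>= 1).
#' @return data.frame with columns term, class, df, ordered by interaction
#'   order then term label.
#' @export
gxe_design <- function(loci, environments) {
  L <- length(loci)
  E <- length(unique(environments))
  facs <- c(paste0("m_", unclass(loci)), if (E > 1L) "env")
  terms <- unlist(lapply(seq_along(facs), function(k)
    apply(utils::combn(facs, k), 2L, paste, collapse = ":")), use.names = FALSE)
  out <- data.frame(term = terms,
                    class = vapply(terms, classify_term, character(1L)),
                    df = ifelse(grepl("(^|:)env($|:)", terms), E - 1L, 1L),
                    stringsAsFactors = FALSE)
  ord <- lengths(strsplit(out$term, ":", fixed = TRUE))
  out <- out[order(ord, out$term), ]
  rownames(out) <- NULL
  out
}

#' Full-factorial ANOVA of fitness over loci and environment
#'
#' Fits the six-way (for L = 5 plus environment) fixed-effects linear model of
#' replicate relative fitness on effect-coded (sum-to-zero) locus-presence
#' factors and the environment factor, with all interaction orders. On a
#' balanced design the sequential sums of squares are orthogonal, so each
#' term's SS is well defined regardless of order; unbalanced data are fitted
#' with sequential SS in a documented order (main effects, then ascending
#' interaction order) and flagged with a warning.
#'
#' @param df replicate-level fitness table (columns environment, genotype,
#'   replicate, w).
#' @param loci a [locus_set()]; defaults to the table's attribute.
#' @return a `gxe_anova` object: list with `table` (term, class, df, SS, MS,
#'   F, p), `residual_df`, `residual_ss`, `total_ss`, `model_df`, `model_F`,
#'   `model_p`, and the fitted `lm` in `fit`.
#' @export
gxe_anova <- function(df, loci = attr(df, "loci")) {
  if (is.null(loci)) loci <- locus_set()
  df <- validate_fitness_table(df, loci)
  dat <- data.frame(w = df$w)
  for (l in unclass(loci)) {
    pres <- vapply(df$genotype, function(g) genotype_mask(g, loci)[
      match(l, unclass(loci))], logical(1L), USE.NAMES = FALSE)
    dat[[paste0("m_", l)]] <- factor(pres, levels = c(FALSE, TRUE),
                                     labels = c("0", "1"))
  }
  envs <- unique(df$environment)
  has_env <- length(envs) > 1L
  if (has_env) dat$env <- factor(df$environment)
  facs <- c(paste0("m_", unclass(loci)), if (has_env) "env")
  fmla <- stats::as.formula(paste("w ~", paste(facs, collapse = " * ")))
  counts <- table(df$environment, df$genotype)
  if (length(unique(as.vector(counts))) > 1L)
    warning("unbalanced design: sequential sums of squares, terms ordered ",
            "by ascending interaction order")
  contr <- stats::setNames(rep(list("contr.sum"), length(facs)), facs)
  fit <- stats::lm(fmla, data = dat, contrasts = contr)
  at <- stats::anova(fit)
  terms <- rownames(at)
  resid_i <- which(terms == "Residuals")
  tab <- data.frame(term = terms[-resid_i],
                    class = vapply(terms[-resid_i], classify_term,
                                   character(1L)),
                    df = at$Df[-resid_i], SS = at$`Sum Sq`[-resid_i],
                    MS = at$`Mean Sq`[-resid_i], F = at$`F value`[-resid_i],
                    p = at$`Pr(>F)`[-resid_i], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  residual_df <- at$Df[resid_i]
  residual_ss <- at$`Sum Sq`[resid_i]
  model_df <- sum(tab$df)
  model_F <- if (residual_df > 0)
    (sum(tab$SS) / model_df) / (residual_ss / residual_df) else NA_real_
  structure(list(table = tab, residual_df = residual_df,
                 residual_ss = residual_ss,
                 total_ss = sum(tab$SS) + residual_ss,
                 model_df = model_df, model_F = model_F,
                 model_p = if (!is.na(model_F))
                   stats::pf(model_F, model_df, residual_df,
                             lower.tail = FALSE) else NA_real_,
                 fit = fit),
            class = "gxe_anova")
}

#' @export
print.gxe_anova <- function(x, ...) {
  cat("Full-factorial GxE ANOVA:", x$model_df, "model df,",
      x$residual_df, "residual df\n")
  cat(sprintf("  overall F_%d,%d = %.3f, p = %.3g\n", x$model_df,
              x$residual_df, x$model_F, x$model_p))
  print(utils::head(x$table[order(x$table$p), ], 10L))
  invisible(x)
}

#' Partition fitness variance into G, GxG, E, GxE, GxGxE and residual
#'
#' Sums the ANOVA sums of squares within each interaction class and reports
#' them as fractions of the total SS (raw SS shares, not variance-component
#' estimates). Fractions sum to 1 by construction.
#'
#' @param x a [gxe_anova()] result.
#' @return data.frame with columns class, df, SS, fraction; classes in the
#'   order G, GxG, E, GxE, GxGxE, residual (absent classes dropped).
#' @export
variance_partition <- function(x) {
  stopifnot(inherits(x, "gxe_anova"))
  cls_order <- c("G", "GxG", "E", "GxE", "GxGxE")
  rows <- lapply(cls_order, function(cl) {
    sub <- x$table[x$table$class == cl, ]
    if (!nrow(sub)) return(NULL)
    data.frame(class = cl, df = sum(sub$df), SS = sum(sub$SS),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(class = "residual", df = x$residual_df, SS = x$residual_ss,
               stringsAsFactors = FALSE))))
  out$fraction <- out$SS / x$total_ss
  rownames(out) <- NULL
  out
}
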