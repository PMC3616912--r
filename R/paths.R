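## All permutations of a character vector, in lexicographic order of the
## resulting orderings. L <= 8 keeps this comfortably small (8! = 40320).
permutations <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- vector("list", factorial(n))
  k <- 1L
  for (i in seq_len(n)) {
    rest <- permutations(x[-i])
    for (p in rest) { out[[k]] <- c(x[i], p); k <- k + 1L }
  }
  out
}

#' Enumerate every mutational path from the ancestor to the full mutant
#'
#' A mutational path is an ordering of the L loci: starting from the ancestor,
#' mutations are added one at a time, visiting a chain of L + 1 genotypes that
#' ends at the all-mutant genotype. There are exactly L! such orderings; for
#' the five focal mutations, 120.
#'
#' @param loci a [locus_set()].
#' @return list of paths in lexicographic order of the ordering; each path is
#'   a list with `ordering` (locus permutation) and `chain` (L + 1 canonical
#'   genotype labels from `"anc"` to the full mutant).
#' @export
enumerate_paths <- function(loci) {
  stopifnot(inherits(loci, "locus_set"))
  lapply(permutations(unclass(loci)), function(ord) {
    mask <- rep(FALSE, length(loci))
    chain <- character(length(loci) + 1L)
    chain[1L] <- ANCESTOR
    for (k in seq_along(ord)) {
      mask[match(ord[k], unclass(loci))] <- TRUE
      chain[k + 1L] <- format_genotype(mask, loci)
    }
    list(ordering = ord, chain = chain)
  })
}

#' Is a mutational path selectively accessible?
#'
#' Under `mode = "mean"` a path is accessible iff mean fitness strictly
#' increases at every step (ties break to inaccessible, matching
#' "monotonically increasing fitness"). Under `mode = "significant"` every
#' step must be significantly beneficial: a positive fitness change with
#' adjusted p below `alpha` in the per-step t-test of [step_effects()].
#'
#' @param path one element of [enumerate_paths()].
#' @param landscape a `landscape_summary`.
#' @param env environment label.
#' @param mode `"mean"` (default) or `"significant"`.
#' @param alpha significance level for `mode = "significant"`.
#' @param correction p-adjustment over all directed edges of the hypercube
#'   (see [step_effects()]); default `"bonferroni"`.
#' @param edges optional precomputed [step_effects()] table (saves recomputing
#'   it for every path).
#' @return TRUE/FALSE.
#' @export
is_accessible <- function(path, landscape, env, mode = c("mean", "significant"),
                          alpha = 0.05, correction = "bonferroni",
                          edges = NULL) {
  mode <- match.arg(mode)
  chain <- path$chain
  if (mode == "mean") {
    w <- vapply(chain, function(g) landscape_cell(landscape, env, g)$w_mean,
                numeric(1L))
    return(all(diff(w) > 0))
  }
  if (is.null(edges))
    edges <- step_effects(landscape, env, alpha = alpha, correction = correction)
  key <- paste(chain[-length(chain)], chain[-1L], sep = ">")
  cls <- edges$classification[match(key, paste(edges$from, edges$to, sep = ">"))]
  if (anyNA(cls)) stop("path step(s) missing from the edge table")
  all(cls == "beneficial")
}

#' Count selectively accessible paths in an environment
#'
#' @inheritParams is_accessible
#' @param loci defaults to the landscape's locus set.
#' @return integer between 0 and L!.
#' @export
count_accessible <- function(landscape, env, mode = c("mean", "significant"),
                             alpha = 0.05, correction = "bonferroni",
                             loci = attr(landscape, "loci")) {
  mode <- match.arg(mode)
  assert_complete_landscape(landscape, env)
  edges <- if (mode == "significant")
    step_effects(landscape, env, alpha = alpha, correction = correction)
  else NULL
  sum(vapply(enumerate_paths(loci), is_accessible, logical(1L),
             landscape = landscape, env = env, mode = mode, alpha = alpha,
             correction = correction, edges = edges))
}

#' Per-path accessibility report
#'
#' @inheritParams count_accessible
#' @return data.frame with one row per ordering: environment, ordering,
#'   accessible_mean, accessible_significant, first_blocking_step (the first
#'   step, counting from 1, whose mean fitness change is not an increase;
#'   NA for mean-accessible paths).
#' @export
path_report <- function(landscape, env, alpha = 0.05,
                        correction = "bonferroni",
                        loci = attr(landscape, "loci")) {
  assert_complete_landscape(landscape, env)
  edges <- step_effects(landscape, env, alpha = alpha, correction = correction)
  paths <- enumerate_paths(loci)
  rows <- lapply(paths, function(p) {
    w <- vapply(p$chain, function(g) landscape_cell(landscape, env, g)$w_mean,
                numeric(1L))
    inc <- diff(w) > 0
    key <- paste(p$chain[-length(p$chain)], p$chain[-1L], sep = ">")
    cls <- edges$classification[match(key, paste(edges$from, edges$to, sep = ">"))]
    data.frame(environment = env,
               ordering = paste(p$ordering, collapse = ""),
               accessible_mean = all(inc),
               accessible_significant = all(cls == "beneficial"),
               first_blocking_step = if (all(inc)) NA_integer_
                                     else which(!inc)[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fitness effects of every single-mutation step on the hypercube
#'
#' Every directed edge adds one mutation to a genotype; a complete L-locus
#' landscape has `L * 2^(L-1)` such edges (80 for L = 5). The fitness change
#' is the difference of cell means, its SD combines both cells' replicate SDs
#' in quadrature, and the per-step t-test uses the smaller cell's replication
#' for df. Steps are classified at `alpha` after the chosen multiple-testing
#' correction over all edges (Bonferroni by default).
#'
#' @inheritParams count_accessible
#' @return data.frame with columns environment, from, to, locus_added,
#'   delta_w, sd_delta, t, df, p, p_adj, classification
#'   (beneficial/deleterious/neutral).
#' @export
step_effects <- function(landscape, env, alpha = 0.05,
                         correction = c("bonferroni", "none", "bh"),
                         loci = attr(landscape, "loci")) {
  correction <- match.arg(correction)
  assert_complete_landscape(landscape, env)
  gts <- all_genotypes(loci)
  rows <- list()
  for (g in gts) {
    mask <- genotype_mask(g, loci)
    for (i in which(!mask)) {
      m2 <- mask; m2[i] <- TRUE
      to <- format_genotype(m2, loci)
      a <- landscape_cell(landscape, env, g)
      b <- landscape_cell(landscape, env, to)
      delta <- b$w_mean - a$w_mean
      sdd <- sqrt(a$w_sd^2 + b$w_sd^2)
      df <- min(a$n, b$n) - 1L
      t <- if (sdd > 0) delta / sdd else NA_real_
      p <- if (!is.na(t) && df >= 1L) 2 * stats::pt(-abs(t), df) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(environment = env, from = g, to = to,
                   locus_added = unclass(loci)[i], delta_w = delta,
                   sd_delta = sdd, t = t, df = df, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- switch(correction, none = out$p,
                      bonferroni = stats::p.adjust(out$p, "bonferroni"),
                      bh = stats::p.adjust(out$p, "BH"))
  sig <- !is.na(out$p_adj) & out$p_adj < alpha
  out$classification <- ifelse(sig & out$delta_w > 0, "beneficial",
                        ifelse(sig & out$delta_w < 0, "deleterious", "neutral"))
  rownames(out) <- NULL
  out
}

#' Fitness peaks of a landscape
#'
#' A local peak is a genotype whose mean fitness is at least that of every
#' Hamming-distance-1 neighbour (adding or removing one mutation); the global
#' maximum is the genotype with the highest mean fitness. Ties are reported
#' as sets.
#'
#' @inheritParams count_accessible
#' @return list with `local_maxima` (character vector) and `global_maximum`
#'   (character vector; length > 1 only on exact ties).
#' @export
peaks <- function(landscape, env, loci = attr(landscape, "loci")) {
  assert_complete_landscape(landscape, env)
  gts <- all_genotypes(loci)
  w <- vapply(gts, function(g) landscape_cell(landscape, env, g)$w_mean,
              numeric(1L))
  names(w) <- gts
  local <- vapply(gts, function(g) {
    mask <- genotype_mask(g, loci)
    nb <- vapply(seq_along(mask), function(i) {
      m2 <- mask; m2[i] <- !m2[i]; format_genotype(m2, loci)
    }, character(1L))
    all(w[g] >= w[nb])
  }, logical(1L))
  list(local_maxima = gts[local],
       global_maximum = gts[w == max(w)])
}
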