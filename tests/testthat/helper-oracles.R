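# Independent oracles and small fixture builders used across the suite.

# Dynamic-programming count of monotone (strictly increasing) orderings from
# the ancestor to the full mutant. Independent of enumerate_paths(): works on
# subset masks and per-edge comparisons only.
dp_accessible_count <- function(w, loci) {
  L <- length(loci)
  n_mask <- bitwShiftL(1L, L)
  label_of <- function(mask) {
    bits <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(L) - 1L)) > 0L)
    if (!any(bits)) "anc" else paste(unclass(loci)[bits], collapse = "")
  }
  labs <- vapply(seq_len(n_mask) - 1L, label_of, character(1L))
  f <- numeric(n_mask)
  f[1L] <- 1
  for (mask in seq_len(n_mask - 1L)) {
    total <- 0
    for (i in seq_len(L) - 1L) {
      bit <- bitwShiftL(1L, i)
      if (bitwAnd(mask, bit) > 0L) {
        prev <- bitwAnd(mask, bitwNot(bit))
        if (w[[labs[mask + 1L]]] > w[[labs[prev + 1L]]])
          total <- total + f[prev + 1L]
      }
    }
    f[mask + 1L] <- total
  }
  f[n_mask]
}

# Build a landscape_summary directly from a named vector of means (constant
# sd and n), bypassing the replicate machinery.
make_landscape <- function(w, loci, env = "E1", sd = 0, n = 5L) {
  df <- data.frame(environment = env, genotype = names(w),
                   n_mut = epiland::genotype_size(names(w), loci),
                   w_mean = unname(w), w_sd = sd, n = n,
                   stringsAsFactors = FALSE)
  structure(df, loci = loci, class = c("landscape_summary", "data.frame"))
}

# Random complete landscape over `loci`: means drawn uniformly.
random_landscape <- function(loci, env = "E1", lo = 0.8, hi = 1.5,
                             sd = 0, n = 5L) {
  gts <- epiland::all_genotypes(loci)
  w <- stats::setNames(stats::runif(length(gts), lo, hi), gts)
  make_landscape(w, loci, env, sd = sd, n = n)
}

loci5 <- epiland::locus_set()
loci3 <- epiland::locus_set(c("a", "b", "c"))
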