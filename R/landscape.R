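#' Define the ordered set of loci for a landscape analysis
#'
#' A landscape over L mutations is indexed by subsets of L named loci. The
#' locus order is fixed for the lifetime of an analysis: genotype labels list
#' present loci in this order, and bitstring representations assign bit i to
#' locus i. The default order `r, t, s, g, p` follows the order in which the
#' five focal beneficial mutations (rbs, topA, spoT, glmUS, pykF) arose and
#' fixed in the source population.
#'
#' @param loci character vector of unique single-character locus labels.
#' @return an object of class `locus_set` (a character vector with attributes).
#' @examples
#' locus_set()            # default five loci r,t,s,g,p
#' locus_set(c("a","b"))  # a 2-locus landscape
#' @export
locus_set <- function(loci = c("r", "t", "s", "g", "p")) {
  loci <- as.character(loci)
  if (length(loci) < 1L) stop("locus_set needs at least one locus")
  if (any(nchar(loci) != 1L)) stop("locus labels must be single characters")
  if (anyDuplicated(loci)) stop("locus labels must be unique")
  if (ANCESTOR %in% loci) stop("locus label may not equal the ancestor token")
  structure(loci, class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("<locus_set> L =", length(x), ":", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

## Token used for the empty mutation set (the ancestor). The source study uses
## no explicit token; "anc" is this package's convention.
ANCESTOR <- "anc"

#' Parse a genotype label into a canonical mutation-set label
#'
#' Accepts three spellings: the ancestor token `"anc"`, a bitstring of length
#' L (`"00011"` means only the last two loci are mutated), or a string of
#' present-locus characters in any order (`"srt"`). The return value is always
#' canonical: present loci listed in `loci` order, or `"anc"` for the empty
#' set, so `parse_genotype()` and `format_genotype()` round-trip.
#'
#' @param label genotype label (character scalar or vector).
#' @param loci a [locus_set()].
#' @return canonical genotype label(s).
#' @examples
#' loci <- locus_set()
#' parse_genotype("srt", loci)    # "rts"
#' parse_genotype("00011", loci)  # "gp"
#' parse_genotype("anc", loci)    # "anc"
#' @export
parse_genotype <- function(label, loci) {
  stopifnot(inherits(loci, "locus_set"))
  vapply(as.character(label), function(lab) {
    if (is.na(lab) || !nzchar(lab)) stop("empty genotype label")
    if (lab == ANCESTOR) return(ANCESTOR)
    chars <- strsplit(lab, "", fixed = TRUE)[[1L]]
    if (all(chars %in% c("0", "1"))) {
      if (length(chars) != length(loci))
        stop("bitstring '", lab, "' has length ", length(chars),
             ", expected ", length(loci))
      mask <- chars == "1"
    } else {
      if (!all(chars %in% loci))
        stop("unknown locus character(s) in '", lab, "': ",
             paste(setdiff(chars, loci), collapse = ","))
      if (anyDuplicated(chars))
        stop("duplicated locus character in '", lab, "'")
      mask <- loci %in% chars
    }
    format_genotype(mask, loci)
  }, character(1L), USE.NAMES = FALSE)
}

#' Format a presence mask as a canonical genotype label
#'
#' @param mask logical vector of length L (TRUE = locus mutated).
#' @param loci a [locus_set()].
#' @return canonical label; `"anc"` for the all-FALSE mask.
#' @export
format_genotype <- function(mask, loci) {
  stopifnot(inherits(loci, "locus_set"), length(mask) == length(loci))
  if (!any(mask)) return(ANCESTOR)
  paste(unclass(loci)[as.logical(mask)], collapse = "")
}

#' Presence mask of a canonical genotype label
#'
#' @inheritParams format_genotype
#' @param genotype canonical label as returned by [parse_genotype()].
#' @return logical vector of length L.
#' @export
genotype_mask <- function(genotype, loci) {
  stopifnot(inherits(loci, "locus_set"))
  if (genotype == ANCESTOR) return(rep(FALSE, length(loci)))
  unclass(loci) %in% strsplit(genotype, "", fixed = TRUE)[[1L]]
}

#' Number of mutations in a genotype
#' @inheritParams genotype_mask
#' @return integer vector, one count per label.
#' @export
genotype_size <- function(genotype, loci) {
  vapply(genotype, function(g) sum(genotype_mask(g, loci)), integer(1L),
         USE.NAMES = FALSE)
}

#' All genotypes of a landscape
#'
#' @param loci a [locus_set()].
#' @return character vector of the 2^L canonical labels, ordered by mutation
#'   count then label.
#' @export
all_genotypes <- function(loci) {
  L <- length(loci)
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), L))[, L:1, drop = FALSE]
  labs <- apply(as.matrix(masks), 1L, format_genotype, loci = loci)
  labs[order(genotype_size(labs, loci), labs)]
}

#' Proper subsets of a mutation set
#'
#' Enumerates every proper subset of `genotype` with at least `min_size`
#' mutations, in deterministic order (by size, then canonical label). This is
#' the combinatorial backbone of the higher-order epistasis decomposition,
#' which subtracts the interaction terms of all lower-order subsets.
#'
#' @inheritParams genotype_mask
#' @param min_size smallest subset size to return (>= 0).
#' @return character vector of canonical labels (possibly empty).
#' @examples
#' subsets("rts", locus_set(), min_size = 2)  # "rt" "rs" "ts"
#' @export
subsets <- function(genotype, loci, min_size = 0L) {
  stopifnot(min_size >= 0L)
  present <- unclass(loci)[genotype_mask(genotype, loci)]
  k <- length(present)
  out <- character(0L)
  for (size in seq.int(min_size, max(min_size, k - 1L))) {
    if (size >= k) break
    if (size == 0L) { out <- c(out, ANCESTOR); next }
    cmb <- utils::combn(present, size)
    out <- c(out, sort(apply(cmb, 2L, paste, collapse = "")))
  }
  ## labels built from `present` (already in loci order) are canonical;
  ## sort() within a size gives the deterministic tie order
  out
}

#' Read a tidy replicate-level fitness table
#'
#' The expected CSV has header `environment,genotype,replicate,w` with one row
#' per replicate fitness measurement. Genotype labels are canonicalised via
#' [parse_genotype()]. Relative fitness must be positive.
#'
#' @param path CSV file path.
#' @param loci a [locus_set()].
#' @return data.frame with columns environment, genotype, replicate, w.
#' @export
load_fitness_table <- function(path, loci = locus_set()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_fitness_table(df, loci)
}

#' Validate a replicate-level fitness table
#'
#' @param df data.frame with columns environment, genotype, replicate, w.
#' @inheritParams load_fitness_table
#' @return the validated data.frame with canonical genotype labels.
#' @export
validate_fitness_table <- function(df, loci = locus_set()) {
  need <- c("environment", "genotype", "replicate", "w")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fitness table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$genotype <- parse_genotype(df$genotype, loci)
  if (!is.numeric(df$w)) stop("column w must be numeric")
  if (anyNA(df$w)) stop("column w contains missing values")
  if (any(df$w <= 0)) stop("relative fitness w must be > 0")
  key <- paste(df$environment, df$genotype, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (environment, genotype, replicate) key(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  attr(df, "loci") <- loci
  df
}

#' Summarise replicate fitness observations into a landscape
#'
#' Collapses a replicate-level table to one row per (environment, genotype)
#' with the mean relative fitness, sample standard deviation (n - 1
#' denominator, so it feeds t-tests with df = n - 1) and replicate count. The
#' result is the object every downstream statistic consumes.
#'
#' @param df replicate table as from [load_fitness_table()].
#' @param loci a [locus_set()]; defaults to the table's attribute if present.
#' @return a `landscape_summary`: data.frame with columns environment,
#'   genotype, n_mut, w_mean, w_sd, n and a `loci` attribute.
#' @export
summarize_landscape <- function(df, loci = attr(df, "loci")) {
  if (is.null(loci)) loci <- locus_set()
  df <- validate_fitness_table(df, loci)
  sp <- split(df, list(df$environment, df$genotype), drop = TRUE, sep = "\r")
  rows <- lapply(sp, function(d) {
    n <- nrow(d)
    sdv <- if (n > 1L) stats::sd(d$w) else 0
    data.frame(environment = d$environment[1L], genotype = d$genotype[1L],
               w_mean = mean(d$w), w_sd = sdv, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$n == 1L))
    warning("single-replicate cell(s): sample SD set to 0 for ",
            sum(out$n == 1L), " (environment, genotype) cell(s)")
  out$n_mut <- genotype_size(out$genotype, loci)
  out <- out[order(out$environment, out$n_mut, out$genotype),
             c("environment", "genotype", "n_mut", "w_mean", "w_sd", "n")]
  rownames(out) <- NULL
  structure(out, loci = loci, class = c("landscape_summary", "data.frame"))
}

#' Environments present in a landscape summary
#' @param landscape a `landscape_summary`.
#' @return character vector.
#' @export
landscape_environments <- function(landscape) unique(landscape$environment)

## one-row lookup; errors if the (environment, genotype) cell is absent
landscape_cell <- function(landscape, env, genotype) {
  i <- which(landscape$environment == env & landscape$genotype == genotype)
  if (length(i) != 1L)
    stop("landscape has no (or duplicated) cell for environment '", env,
         "', genotype '", genotype, "'")
  landscape[i, , drop = FALSE]
}

#' Check that a landscape has all 2^L genotypes in an environment
#' @param landscape a `landscape_summary`.
#' @param env environment label.
#' @return TRUE invisibly; errors listing missing genotypes otherwise.
#' @export
assert_complete_landscape <- function(landscape, env) {
  loci <- attr(landscape, "loci")
  have <- landscape$genotype[landscape$environment == env]
  miss <- setdiff(all_genotypes(loci), have)
  if (length(miss))
    stop("incomplete landscape in environment '", env, "': missing ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Write a landscape summary to CSV
#' @param landscape a `landscape_summary`.
#' @param path output path.
#' @export
write_landscape <- function(landscape, path) {
  utils::write.csv(format_numeric(as.data.frame(landscape)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

## fixed 6-significant-digit rendering for reproducible CSV diffs
format_numeric <- function(df, digits = 6L) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}
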