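#' Average height of a kinetic respiration curve
#'
#' Phenotype-microarray wells report respiration as tetrazolium dye reduction
#' read every few minutes and graphed as a kinetic response curve. Activity in
#' a well is summarised by the average curve height h: the time-weighted mean
#' of the signal, i.e. the trapezoidal integral divided by the window length.
#'
#' @param times timepoints (ascending, length >= 2), any consistent unit.
#' @param signal respiration signal (arbitrary units, >= 0).
#' @return mean curve height h (same units as `signal`).
#' @export
curve_height <- function(times, signal) {
  if (length(times) < 2L) stop("a kinetic curve needs at least 2 timepoints")
  stopifnot(length(times) == length(signal))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(signal < 0)) stop("signal must be >= 0")
  pracma::trapz(times, signal) / (times[length(times)] - times[1L])
}

#' Call differential respiration between two strains in one environment
#'
#' Two strains differ in an environment if their mean curve heights differ by
#' more than `k` standard deviations of h for both strains: with the default
#' conjunctive rule, `|mean(h_A) - mean(h_B)|` must exceed `k * sd_A` AND
#' `k * sd_B` (the most conservative reading; `rule = "disjunctive"` requires
#' only one). The verdict is `"gain"` when the evolved strain (A) respires
#' more, `"loss"` when less, `"none"` otherwise. If either replicate SD is 0
#' the rule degenerates to "any nonzero difference"; such calls carry
#' `degenerate = TRUE`.
#'
#' @param h_reps_A replicate curve heights of the evolved/focal strain.
#' @param h_reps_B replicate curve heights of the ancestor/reference strain.
#' @param k SD multiplier (default 3).
#' @param rule `"conjunctive"` (both strains' SDs, default) or
#'   `"disjunctive"` (either).
#' @param environment optional environment label carried into the result.
#' @return one-row data.frame: environment, h_A, h_B, sd_A, sd_B,
#'   differential, verdict, degenerate.
#' @export
differential_call <- function(h_reps_A, h_reps_B, k = 3,
                              rule = c("conjunctive", "disjunctive"),
                              environment = NA_character_) {
  rule <- match.arg(rule)
  if (!length(h_reps_A) || !length(h_reps_B))
    stop("need at least one replicate height per strain")
  mA <- mean(h_reps_A); mB <- mean(h_reps_B)
  sA <- if (length(h_reps_A) > 1L) stats::sd(h_reps_A) else 0
  sB <- if (length(h_reps_B) > 1L) stats::sd(h_reps_B) else 0
  d <- abs(mA - mB)
  degenerate <- sA == 0 || sB == 0
  hitA <- if (sA == 0) d > 0 else d > k * sA
  hitB <- if (sB == 0) d > 0 else d > k * sB
  differential <- if (rule == "conjunctive") hitA && hitB else hitA || hitB
  verdict <- if (!differential) "none" else if (mA > mB) "gain" else "loss"
  data.frame(environment = environment, h_A = mA, h_B = mB,
             sd_A = sA, sd_B = sB, differential = differential,
             verdict = verdict, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Run the differential-respiration screen over a long kinetic-curve table
#'
#' @param df long data.frame with columns
#'   `strain,environment,replicate,time_h,signal`; exactly two strains.
#' @param evolved,ancestor strain labels; gains are called for `evolved`.
#' @inheritParams differential_call
#' @return calls data.frame, one row per environment.
#' @export
biolog_screen <- function(df, evolved, ancestor, k = 3,
                          rule = c("conjunctive", "disjunctive")) {
  rule <- match.arg(rule)
  need <- c("strain", "environment", "replicate", "time_h", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("kinetic-curve table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c(evolved, ancestor) %in% df$strain))
    stop("strains '", evolved, "' and '", ancestor, "' must both be present")
  heights <- function(d) {
    vapply(split(d, d$replicate), function(r) {
      r <- r[order(r$time_h), ]
      curve_height(r$time_h, r$signal)
    }, numeric(1L))
  }
  calls <- lapply(split(df, df$environment), function(d) {
    differential_call(heights(d[d$strain == evolved, ]),
                      heights(d[d$strain == ancestor, ]),
                      k = k, rule = rule, environment = d$environment[1L])
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out[order(out$environment), ]
}

#' Tally a set of differential-respiration calls
#'
#' @param calls data.frame of calls as returned by [differential_call()] /
#'   [biolog_screen()] (one row per environment).
#' @return list with counts `differential`, `gains`, `losses` and the
#'   per-category environment vectors.
#' @export
screen_summary <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L)
    return(list(differential = 0L, gains = 0L, losses = 0L,
                gain_environments = character(0L),
                loss_environments = character(0L)))
  gains <- calls$environment[calls$verdict == "gain"]
  losses <- calls$environment[calls$verdict == "loss"]
  list(differential = sum(calls$differential),
       gains = length(gains), losses = length(losses),
       gain_environments = gains, loss_environments = losses)
}
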