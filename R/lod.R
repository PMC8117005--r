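#' Limit-of-detection model configuration
#'
#' Parametrises the assay's detection-limit model: the deterministic floor
#' comes straight from the caller thresholds (a call needs `min_allele_cov`
#' reads and VAF >= `min_vaf`), while the probabilistic power model adds a
#' per-base miscall probability toward the variant allele. The power model is
#' this package's generalisation of the empirically observed detection limits;
#' strand-bias filtering is ignored here (balanced strands assumed) and its
#' effect is quantified empirically by the simulator instead.
#'
#' @param filter A [filter_config()].
#' @param error_rate Per-base miscall probability toward the variant allele
#'   (default 1e-3); must be below `filter$min_vaf`.
#' @param target_power Desired detection probability for [required_depth()]
#'   (default 0.95).
#' @return An object of class `lod_config`.
#' @export
lod_config <- function(filter = filter_config(), error_rate = 1e-3,
                       target_power = 0.95) {
  stopifnot(inherits(filter, "filter_config"),
            error_rate >= 0, error_rate < filter$min_vaf,
            target_power > 0, target_power < 1)
  structure(list(filter = filter, error_rate = error_rate,
                 target_power = target_power), class = "lod_config")
}

#' Expected VAF from mutant cell fractions
#'
#' A heterozygous somatic mutation carried by a fraction `f_dnt` of cells
#' (the double-negative T-cell compartment) plus a fraction `f_sp` (mutant
#' single-positive cells) contributes one mutant allele per carrier cell, so
#' the expected allele fraction in whole-blood DNA is `(f_dnt + f_sp) / 2`.
#'
#' @param f_dnt Mutant DNT fraction of nucleated cells, in \[0, 1\].
#' @param f_sp Mutant single-positive fraction of nucleated cells, in
#'   \[0, 1\]; `f_dnt + f_sp <= 1`.
#' @return Expected VAF(s).
#' @export
expected_vaf <- function(f_dnt, f_sp = 0) {
  stopifnot(all(f_dnt >= 0 & f_dnt <= 1), all(f_sp >= 0 & f_sp <= 1),
            all(f_dnt + f_sp <= 1))
  (f_dnt + f_sp) / 2
}

min_supporting_reads <- function(depth, filter) {
  # smallest alt-read count that clears both the read-count and VAF filters;
  # the epsilon guards ceiling() against floating error at exact multiples
  pmax(filter$min_allele_cov, ceiling(filter$min_vaf * depth - 1e-9))
}

#' Minimum detectable VAF at a given depth
#'
#' The deterministic detection floor implied by the filter chain:
#' `max(min_vaf, min_allele_cov / depth)`. With the default thresholds this
#' reproduces the assay's observed limits (8 reads of 101 = 7.9%; 4 reads of
#' 212 = 1.9% are both above the floor, while 1 read of 141 is not callable).
#' Depths below `min_allele_cov` return 1.0: nothing is detectable.
#'
#' @param depth Total read depth(s), >= 1.
#' @param config An [lod_config()].
#' @return Minimum callable VAF(s).
#' @export
min_detectable_vaf <- function(depth, config = lod_config()) {
  stopifnot(all(depth >= 1))
  f <- config$filter
  ifelse(depth < f$min_allele_cov, 1,
         pmax(f$min_vaf, f$min_allele_cov / depth))
}

#' Exact-binomial detection power
#'
#' Probability that a variant at true allele fraction `true_vaf` yields enough
#' supporting reads to be called at depth `depth`: `P(X >= k*)` with
#' `X ~ Binomial(depth, true_vaf + error_rate * (1 - true_vaf))` and
#' `k* = max(min_allele_cov, ceil(min_vaf * depth))`. Exact tail sum, no
#' normal approximation.
#'
#' Note the sawtooth: `k*` jumps by one at every depth multiple of
#' `1/min_vaf`, so power is non-decreasing in depth only between jumps (and in
#' practice for `true_vaf` well above `min_vaf`); it is always non-decreasing
#' in `true_vaf`.
#'
#' @param depth Total read depth(s), >= 1.
#' @param true_vaf True allele fraction(s) in \[0, 1\].
#' @param config An [lod_config()].
#' @return Detection probabilities.
#' @export
detection_power <- function(depth, true_vaf, config = lod_config()) {
  stopifnot(all(depth >= 1), all(true_vaf >= 0 & true_vaf <= 1))
  p <- true_vaf + config$error_rate * (1 - true_vaf)
  k <- min_supporting_reads(depth, config$filter)
  stats::pbinom(k - 1, size = depth, prob = p, lower.tail = FALSE)
}

#' Smallest depth reaching the target detection power
#'
#' Scans depths upward until [detection_power()] first reaches
#' `config$target_power`. A variant whose error-inflated allele fraction does
#' not exceed `min_vaf` can never be detected reliably (the VAF floor binds at
#' every depth); that case returns `NA_integer_` as the explicit
#' "undetectable" signal.
#'
#' @param true_vaf True allele fraction (scalar), must exceed `error_rate`.
#' @param config An [lod_config()].
#' @param max_depth Scan cap (default 1e6); exceeding it also returns `NA`.
#' @return The required depth as an integer, or `NA_integer_` if
#'   undetectable.
#' @export
required_depth <- function(true_vaf, config = lod_config(),
                           max_depth = 1e6) {
  stopifnot(length(true_vaf) == 1L, true_vaf > config$error_rate)
  p <- true_vaf + config$error_rate * (1 - true_vaf)
  if (p <= config$filter$min_vaf) return(NA_integer_)
  lo <- 1L
  chunk <- 4096L
  while (lo <= max_depth) {
    depths <- lo:min(max_depth, lo + chunk - 1L)
    pow <- detection_power(depths, true_vaf, config)
    hit <- which(pow >= config$target_power)
    if (length(hit)) return(depths[hit[1]])
    lo <- lo + chunk
  }
  NA_integer_
}
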