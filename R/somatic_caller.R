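#' Somatic-caller filter configuration
#'
#' Thresholds of the customised low-VAF somatic filter chain used for
#' whole-blood FAS screening: a candidate needs VAF >= `min_vaf` and at least
#' `min_allele_cov` supporting reads, and is removed as a strand artifact only
#' when the strand-bias score exceeds `sb_score_max` *and* the Fisher exact
#' p-value falls below `sb_pvalue_min` (a conjunction: balanced-but-significant
#' or extreme-but-insignificant evidence both survive). No per-strand coverage
#' is required by default (`min_strand_cov = 0`).
#'
#' Passing calls are classified by allele-fraction band: heterozygous germline
#' inside `germline_het_band`, homozygous germline at or above
#' `germline_hom_min`, somatic otherwise.
#'
#' @param min_vaf Minimum variant allele frequency (default 0.01).
#' @param min_allele_cov Minimum variant-supporting reads (default 3).
#' @param sb_score_max Strand-bias score cutoff (default 0.85; score ranges
#'   0.5 = balanced to 1 = fully one-sided).
#' @param sb_pvalue_min Fisher strand-bias significance cutoff (default 0.05).
#' @param min_strand_cov Minimum per-strand total coverage (default 0, i.e.
#'   none).
#' @param germline_het_band VAF interval labelled heterozygous germline
#'   (default `c(0.35, 0.65)`, covering the reported ~50% polymorphisms with
#'   margin).
#' @param germline_hom_min VAF at or above which a call is homozygous germline
#'   (default 0.90).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_vaf = 0.01, min_allele_cov = 3,
                          sb_score_max = 0.85, sb_pvalue_min = 0.05,
                          min_strand_cov = 0,
                          germline_het_band = c(0.35, 0.65),
                          germline_hom_min = 0.90) {
  stopifnot(min_vaf >= 0, min_vaf <= 1, min_allele_cov >= 0,
            sb_score_max >= 0.5, sb_score_max <= 1,
            sb_pvalue_min >= 0, sb_pvalue_min <= 1, min_strand_cov >= 0,
            length(germline_het_band) == 2L,
            germline_het_band[1] <= germline_het_band[2],
            germline_het_band[1] >= min_vaf,
            germline_hom_min > germline_het_band[2])
  structure(list(min_vaf = min_vaf, min_allele_cov = min_allele_cov,
                 sb_score_max = sb_score_max, sb_pvalue_min = sb_pvalue_min,
                 min_strand_cov = min_strand_cov,
                 germline_het_band = germline_het_band,
                 germline_hom_min = germline_hom_min),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Somatic filter chain:\n",
      sprintf("  min VAF %.3g, min supporting reads %d, strand bias > %.2f with p < %.2g removed\n",
              x$min_vaf, as.integer(x$min_allele_cov), x$sb_score_max,
              x$sb_pvalue_min),
      sprintf("  germline het band [%.2f, %.2f], hom >= %.2f\n",
              x$germline_het_band[1], x$germline_het_band[2],
              x$germline_hom_min), sep = "")
  invisible(x)
}

#' Variant allele frequency from stranded counts
#'
#' @param pileup A pileup data frame (or any data frame with `depth`,
#'   `alt_fwd`, `alt_rev`).
#' @return Numeric vector of VAFs, `(alt_fwd + alt_rev) / depth`.
#' @export
compute_vaf <- function(pileup) {
  if (any(pileup$depth <= 0L)) stop("compute_vaf requires depth > 0")
  (pileup$alt_fwd + pileup$alt_rev) / pileup$depth
}

#' Format a VAF as a percentage, rounded half-up to one decimal
#'
#' Matches the reporting convention of the published variant table (e.g.
#' 10/239 prints as 4.2).
#'
#' @param vaf Numeric VAF(s) in \[0, 1\].
#' @return Numeric percentage(s) with one decimal.
#' @export
vaf_percent <- function(vaf) {
  floor(vaf * 1000 + 0.5) / 10
}

impute_strand_depths <- function(pileup) {
  # Even split of total depth when per-strand coverage is unavailable; odd
  # depths give the extra read to the forward strand.
  miss <- is.na(pileup$depth_fwd) | is.na(pileup$depth_rev)
  pileup$depth_fwd[miss] <- as.integer(ceiling(pileup$depth[miss] / 2))
  pileup$depth_rev[miss] <- pileup$depth[miss] - pileup$depth_fwd[miss]
  pileup
}

#' Strand-bias score
#'
#' A symmetric per-strand rate imbalance score: with per-strand variant rates
#' `rate_f = alt_fwd/depth_fwd` and `rate_r = alt_rev/depth_rev`, the score is
#' `max(rate_f, rate_r) / (rate_f + rate_r)`. It is 0.5 for perfectly balanced
#' rates, 1.0 when all variant reads sit on one strand, and invariant under
#' swapping strands. When per-strand depths are absent they are imputed as an
#' even split of total depth.
#'
#' @param pileup A pileup data frame; every row needs `alt_fwd + alt_rev > 0`.
#' @return Numeric scores in \[0.5, 1\].
#' @export
strand_bias_score <- function(pileup) {
  if (any(pileup$alt_fwd + pileup$alt_rev <= 0L)) {
    stop("strand_bias_score requires at least one variant read")
  }
  pileup <- impute_strand_depths(pileup)
  if (any(pileup$depth_fwd + pileup$depth_rev <= 0L)) {
    stop("strand_bias_score requires positive depth")
  }
  rate_f <- ifelse(pileup$depth_fwd > 0L, pileup$alt_fwd / pileup$depth_fwd,
                   0)
  rate_r <- ifelse(pileup$depth_rev > 0L, pileup$alt_rev / pileup$depth_rev,
                   0)
  pmax(rate_f, rate_r) / (rate_f + rate_r)
}

#' Two-sided Fisher exact p-value for a 2x2 table, vectorised
#'
#' Exact conditional test on \[a, b; c, d\]: conditioning on the margins, the
#' first cell is hypergeometric; the two-sided p-value is the sum of table
#' probabilities not exceeding the observed one (with the conventional
#' `1 + 1e-7` relative tie tolerance, so results agree with
#' [stats::fisher.test()]).
#'
#' @param a,b,c,d Integer vectors: the cells of the 2x2 table(s).
#' @return Numeric p-values in \[0, 1\].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(a < 0L | b < 0L | c < 0L | d < 0L)) {
    stop("fisher_exact_2x2: negative cell count")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]           # row-1 margin (e.g. forward-strand depth)
    nn <- c[i] + d[i]          # row-2 margin
    k <- a[i] + c[i]           # column-1 margin (variant reads)
    if (m + nn == 0L) return(1)
    x <- max(0L, k - nn):min(k, m)
    probs <- stats::dhyper(x, m, nn, k)
    p_obs <- probs[match(a[i], x)]
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Fisher exact strand-bias p-value
#'
#' Tests independence of variant support and strand on the 2x2 table
#' `[alt_fwd, ref_fwd; alt_rev, ref_rev]` with `ref_strand = depth_strand -
#' alt_strand`. Per-strand depths are imputed as an even split when absent.
#'
#' @param pileup A pileup data frame.
#' @return Two-sided exact p-values.
#' @export
strand_bias_pvalue <- function(pileup) {
  pileup <- impute_strand_depths(pileup)
  ref_fwd <- pileup$depth_fwd - pileup$alt_fwd
  ref_rev <- pileup$depth_rev - pileup$alt_rev
  if (any(ref_fwd < 0L | ref_rev < 0L)) {
    stop("strand_bias_pvalue: variant reads exceed strand depth")
  }
  fisher_exact_2x2(pileup$alt_fwd, ref_fwd, pileup$alt_rev, ref_rev)
}

#' Apply the somatic filter chain to stranded counts
#'
#' @param pileup A pileup data frame with `depth > 0` everywhere.
#' @param config A [filter_config()].
#' @return A data frame with one row per input: logical `passed` and a
#'   comma-joined `failed_filters` string (empty when passed), plus the
#'   computed `vaf`, `strand_bias` and `sb_pvalue` columns.
#' @export
apply_filters <- function(pileup, config = filter_config()) {
  vaf <- compute_vaf(pileup)
  alt <- pileup$alt_fwd + pileup$alt_rev
  sb <- rep(NA_real_, nrow(pileup))
  sbp <- rep(NA_real_, nrow(pileup))
  has_alt <- alt > 0L
  if (any(has_alt)) {
    sb[has_alt] <- strand_bias_score(pileup[has_alt, , drop = FALSE])
    sbp[has_alt] <- strand_bias_pvalue(pileup[has_alt, , drop = FALSE])
  }
  imput <- impute_strand_depths(pileup)
  fails <- list(
    min_vaf = vaf < config$min_vaf,
    min_allele_cov = alt < config$min_allele_cov,
    strand_bias = has_alt & !is.na(sb) & sb > config$sb_score_max &
      sbp < config$sb_pvalue_min,
    min_strand_cov = pmin(imput$depth_fwd, imput$depth_rev) <
      config$min_strand_cov
  )
  failed <- vapply(seq_len(nrow(pileup)), function(i) {
    paste(names(fails)[vapply(fails, `[`, NA, i)], collapse = ",")
  }, character(1))
  data.frame(passed = !nzchar(failed), failed_filters = failed,
             vaf = vaf, strand_bias = sb, sb_pvalue = sbp,
             stringsAsFactors = FALSE)
}

#' Classify a passing call by allele-fraction band
#'
#' @param vaf Numeric VAF(s) in \[0, 1\].
#' @param config A [filter_config()].
#' @return Character vector: `"germline_het"`, `"germline_hom"` or
#'   `"somatic"`.
#' @export
classify_call <- function(vaf, config = filter_config()) {
  stopifnot(all(vaf >= 0 & vaf <= 1))
  ifelse(vaf >= config$germline_het_band[1] &
           vaf <= config$germline_het_band[2], "germline_het",
         ifelse(vaf >= config$germline_hom_min, "germline_hom", "somatic"))
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), depth = integer(),
             alt_fwd = integer(), alt_rev = integer(), vaf = numeric(),
             strand_bias = numeric(), sb_pvalue = numeric(),
             filters_passed = logical(), failed_filters = character(),
             classification = character(), stringsAsFactors = FALSE)
}

#' Run the somatic caller on a stranded pileup
#'
#' Restricts the pileup to the target regions, computes VAF and strand-bias
#' statistics per record, applies the filter chain, and classifies passing
#' records as somatic or germline by allele-fraction band. Rejected records
#' are retained with `classification = "rejected"` and their failed filter
#' names. Output order is deterministic: position, then alt allele.
#'
#' @param pileup A pileup data frame; a `sample` column, when present, is
#'   carried through as `sample_id`.
#' @param regions Optional region data frame (e.g. [default_regions()]).
#' @param config A [filter_config()].
#' @param sample_id Sample identifier used when the pileup has no `sample`
#'   column.
#' @return A calls data frame (see [empty_calls()] for the column layout).
#' @export
call_sample <- function(pileup, regions = NULL, config = filter_config(),
                        sample_id = NA_character_) {
  pileup <- filter_regions(pileup, regions)
  if (nrow(pileup) == 0L) return(empty_calls())
  res <- apply_filters(pileup, config)
  calls <- data.frame(
    sample_id = if ("sample" %in% names(pileup)) pileup$sample else
      rep(sample_id, nrow(pileup)),
    chrom = pileup$chrom, pos = pileup$pos, ref = pileup$ref,
    alt = pileup$alt, depth = pileup$depth,
    alt_fwd = pileup$alt_fwd, alt_rev = pileup$alt_rev,
    vaf = res$vaf, strand_bias = res$strand_bias, sb_pvalue = res$sb_pvalue,
    filters_passed = res$passed, failed_filters = res$failed_filters,
    classification = ifelse(res$passed, classify_call(res$vaf, config),
                            "rejected"),
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
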