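#' Truncate a percentage to one decimal
#'
#' The reporting convention for the screen's sensitivity/specificity: floor to
#' one decimal (41/44 = 93.18...% prints as 93.1, not 93.2).
#'
#' @param x Numeric percentage(s).
#' @return `floor(x * 10) / 10`.
#' @export
pct_floor1 <- function(x) {
  floor(x * 10) / 10
}

split_sample_ids <- function(x) {
  # a call's sample field may list several carriers ("P1,P4")
  strsplit(x, ",", fixed = TRUE)
}

#' Score calls against sample-level truth
#'
#' Per-sample accounting of the screen: a patient is a true positive iff a
#' somatic-classified call matches its known variant's site and alleles (a
#' patient with a known-but-uncalled variant is a false negative); a control
#' is a true negative iff it has no passing call of any classification
#' in-region -- germline polymorphism calls count against specificity, since
#' the screen is scored without downstream annotation.
#'
#' @param calls A calls data frame ([call_sample()] layout); `sample_id` may
#'   name several samples comma-separated.
#' @param samples A sample table with `sample_id`, `group`
#'   (`"patient"`/`"control"`) and, for patients, `known_chrom`, `known_pos`,
#'   `known_ref`, `known_alt` (all-`NA` site = known but expected undetected).
#' @return An object of class `validation_result`: confusion counts (`tp`,
#'   `fn`, `fp_samples`, `tn`), raw and floor-formatted percentages
#'   (`sensitivity_pct`, `specificity_pct`), and a `per_sample` detail table.
#' @export
confusion_counts <- function(calls, samples) {
  if (!all(samples$group %in% c("patient", "control"))) {
    stop("every sample must be labelled patient or control")
  }
  passing <- calls[calls$filters_passed, , drop = FALSE]
  carriers <- split_sample_ids(passing$sample_id)
  per_sample <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    mine <- which(vapply(carriers, function(ids) s$sample_id %in% ids, NA))
    n_calls <- length(mine)
    if (s$group == "patient") {
      matched <- FALSE
      if (!is.na(s$known_pos)) {
        matched <- any(passing$classification[mine] == "somatic" &
                         passing$chrom[mine] == s$known_chrom &
                         passing$pos[mine] == s$known_pos &
                         passing$ref[mine] == s$known_ref &
                         passing$alt[mine] == s$known_alt)
      }
      outcome <- if (matched) "TP" else "FN"
    } else {
      outcome <- if (n_calls == 0L) "TN" else "FP"
    }
    data.frame(sample_id = s$sample_id, group = s$group, n_calls = n_calls,
               outcome = outcome, stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, per_sample)
  tp <- sum(per_sample$outcome == "TP")
  fn <- sum(per_sample$outcome == "FN")
  fp <- sum(per_sample$outcome == "FP")
  tn <- sum(per_sample$outcome == "TN")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fn = fn, fp_samples = fp, tn = tn,
                 sensitivity_raw = sens, specificity_raw = spec,
                 sensitivity_pct = if (is.na(sens)) NA_real_ else
                   pct_floor1(sens),
                 specificity_pct = if (is.na(spec)) NA_real_ else
                   pct_floor1(spec),
                 per_sample = per_sample),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Screen validation: TP %d, FN %d, FP samples %d, TN %d\n",
              x$tp, x$fn, x$fp_samples, x$tn))
  cat(sprintf("  sensitivity %s%%, specificity %s%%\n",
              format(x$sensitivity_pct), format(x$specificity_pct)))
  invisible(x)
}

#' Reproduce the published whole-blood screen validation
#'
#' Runs the somatic caller with default thresholds on the bundled 12-record
#' variant report, assembles per-sample outcomes for the 8 patients and 44
#' controls (samples without a reported record have no calls; the recurrent
#' `RV` polymorphism is not attributed to any single cohort sample), and
#' scores the confusion matrix. Fully deterministic: no RNG involved.
#'
#' @param config A [filter_config()].
#' @return A list with `validation` (a `validation_result`) and `calls` (the
#'   12-row classified call table).
#' @export
reproduce_validation <- function(config = filter_config()) {
  fx <- load_fixtures()
  calls <- call_sample(fx$variants, regions = default_regions(),
                       config = config)
  cohort_ids <- fx$samples$sample_id
  attributed <- vapply(split_sample_ids(calls$sample_id),
                       function(ids) any(ids %in% cohort_ids), NA)
  validation <- confusion_counts(calls[attributed, , drop = FALSE],
                                 fx$samples)
  list(validation = validation, calls = calls)
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Empirical vs model detection power over a parameter grid
#'
#' For each (depth, mutant DNT fraction, mutant single-positive fraction)
#' cell, simulates `n_reps` patient samples end-to-end (pileup generation then
#' the somatic caller) at fixed depth and reports the empirical detection
#' frequency -- the fraction of replicates whose injected somatic variant is
#' recovered as a somatic-classified call -- next to the exact-binomial
#' [detection_power()] at the cell's expected VAF, with a Wilson 95% interval
#' on the empirical rate.
#'
#' @param depths Integer vector of depths.
#' @param f_dnt,f_sp Mutant cell fractions (vectors crossed with `depths`).
#' @param n_reps Replicates per grid cell (>= 100).
#' @param config An [lod_config()]; its filter is used for calling.
#' @param error_rate Sequencing error rate used in both simulation and model.
#' @param seed Master seed.
#' @return A data frame with columns `depth`, `f_dnt`, `f_sp`,
#'   `expected_vaf`, `n_reps`, `n_detected`, `empirical_rate`,
#'   `wilson_lower`, `wilson_upper`, `model_power`.
#' @export
power_sweep <- function(depths, f_dnt, f_sp = 0, n_reps = 500,
                        config = lod_config(), error_rate = config$error_rate,
                        seed = 1L) {
  stopifnot(n_reps >= 100)
  grid <- expand.grid(depth = depths, f_dnt = f_dnt, f_sp = f_sp,
                      KEEP.OUT.ATTRS = FALSE)
  lodcfg <- lod_config(filter = config$filter, error_rate = error_rate,
                       target_power = config$target_power)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    depth <- grid$depth[g]
    scfg <- sim_config(n_patients = 1, n_controls = 0,
                       dnt_range = c(100 * grid$f_dnt[g], 100 * grid$f_dnt[g]),
                       sp_fraction_range = rep(grid$f_sp[g], 2),
                       sp_compartment = 1, sp_proportion = 1,
                       depth_median = depth, depth_sdlog = 0,
                       error_rate = error_rate, germline_snp_rate = 0,
                       indel_fraction = 0, n_background_sites = 0)
    detected <- 0L
    for (r in seq_len(n_reps)) {
      sim <- simulate_sample(scfg, "SIM", "patient",
                             dnt_percent = 100 * grid$f_dnt[g],
                             seed = child_seed(seed, g * 1000003 + r))
      calls <- call_sample(sim$pileup, config = lodcfg$filter)
      hit <- calls$filters_passed & calls$classification == "somatic" &
        calls$pos == sim$truth$pos[1]
      detected <- detected + as.integer(any(hit))
    }
    ev <- expected_vaf(grid$f_dnt[g], grid$f_sp[g])
    ci <- wilson_interval(detected, n_reps)
    out[[g]] <- data.frame(
      depth = depth, f_dnt = grid$f_dnt[g], f_sp = grid$f_sp[g],
      expected_vaf = ev, n_reps = n_reps, n_detected = detected,
      empirical_rate = detected / n_reps,
      wilson_lower = ci[["lower"]], wilson_upper = ci[["upper"]],
      model_power = detection_power(depth, ev, lodcfg))
  }
  do.call(rbind, out)
}
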