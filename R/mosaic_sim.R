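#' Mosaic pileup simulation configuration
#'
#' Generative model for whole-blood amplicon pileups of an ALPS-sFAS screen:
#' each patient carries one heterozygous somatic FAS variant in a mutant-cell
#' fraction set by its DNT percentage (all DNT assumed carriers by default)
#' plus a single-positive contribution, each control optionally carries an
#' in-region heterozygous polymorphism, and every covered site accumulates
#' error reads. Per-site depth is lognormal around the panel's typical
#' coverage; reads are assigned to strands independently.
#'
#' Defaults mirror the published study conditions: 8 patients and 44 controls;
#' DNT drawn from 4-30.7% (the cohort's observed range); 10-20% of
#' single-positive cells carrying the mutation, applied to all patients, with
#' the single-positive compartment taken as 25% of nucleated cells; depth
#' median 200 with lognormal sdlog 0.35 (central 95% roughly 100-400 reads,
#' the published coverage range); a quarter of somatic events are deletions
#' (2 of the 8 published mutations).
#'
#' @param n_patients,n_controls Cohort sizes (defaults 8 and 44).
#' @param dnt_range DNT percentage interval patients are drawn from (default
#'   `c(4, 30.7)`).
#' @param sp_fraction_range Fraction of single-positive mononuclear cells
#'   carrying the mutation (default `c(0.10, 0.20)`).
#' @param sp_compartment Single-positive compartment as a fraction of
#'   nucleated cells (default 0.25); the mutant single-positive cell fraction
#'   is `U(sp_fraction_range) * sp_compartment`.
#' @param sp_proportion Proportion of patients with any single-positive
#'   involvement (default 1).
#' @param mutant_dnt_fraction Fraction of DNT cells carrying the mutation
#'   (default 1).
#' @param lymph_multiplier Scales both mutant-cell fractions downward to model
#'   T-cell lymphopenia (default 1 = none).
#' @param depth_median,depth_sdlog Lognormal per-site depth model (median 200,
#'   sdlog 0.35; sdlog 0 gives fixed depth).
#' @param error_rate Per-base miscall probability toward a specific wrong
#'   allele (default 1e-3).
#' @param strand_balance Probability a read is on the forward strand (default
#'   0.5).
#' @param germline_snp_rate Probability a sample carries a heterozygous
#'   polymorphism in-region (default 0.05).
#' @param indel_fraction Fraction of injected somatic mutations that are 3-bp
#'   deletions (default 0.25).
#' @param n_background_sites Error-only sites per sample (default 100).
#' @param region A one-row region data frame sites are drawn from (default
#'   [default_regions()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 8, n_controls = 44,
                       dnt_range = c(4, 30.7),
                       sp_fraction_range = c(0.10, 0.20),
                       sp_compartment = 0.25, sp_proportion = 1,
                       mutant_dnt_fraction = 1, lymph_multiplier = 1,
                       depth_median = 200, depth_sdlog = 0.35,
                       error_rate = 1e-3, strand_balance = 0.5,
                       germline_snp_rate = 0.05, indel_fraction = 0.25,
                       n_background_sites = 100, region = default_regions()) {
  stopifnot(n_patients >= 0, n_controls >= 0,
            all(dnt_range >= 0 & dnt_range <= 100),
            dnt_range[1] <= dnt_range[2],
            all(sp_fraction_range >= 0 & sp_fraction_range <= 1),
            sp_compartment >= 0, sp_compartment <= 1,
            sp_proportion >= 0, sp_proportion <= 1,
            mutant_dnt_fraction >= 0, mutant_dnt_fraction <= 1,
            lymph_multiplier >= 0, lymph_multiplier <= 1,
            depth_median >= 1, depth_sdlog >= 0,
            error_rate >= 0, error_rate < 1,
            strand_balance >= 0, strand_balance <= 1,
            germline_snp_rate >= 0, germline_snp_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            n_background_sites >= 0, nrow(region) == 1L)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 dnt_range = dnt_range,
                 sp_fraction_range = sp_fraction_range,
                 sp_compartment = sp_compartment,
                 sp_proportion = sp_proportion,
                 mutant_dnt_fraction = mutant_dnt_fraction,
                 lymph_multiplier = lymph_multiplier,
                 depth_median = depth_median, depth_sdlog = depth_sdlog,
                 error_rate = error_rate, strand_balance = strand_balance,
                 germline_snp_rate = germline_snp_rate,
                 indel_fraction = indel_fraction,
                 n_background_sites = as.integer(n_background_sites),
                 region = region),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

sim_depth <- function(n, config) {
  if (config$depth_sdlog == 0) {
    rep(as.integer(round(config$depth_median)), n)
  } else {
    pmax(1L, as.integer(round(stats::rlnorm(n, log(config$depth_median),
                                            config$depth_sdlog))))
  }
}

# strand assignment: each read independently forward with prob strand_balance
split_strands <- function(depth, alt, balance) {
  alt_fwd <- stats::rbinom(length(alt), alt, balance)
  ref_fwd <- stats::rbinom(length(alt), depth - alt, balance)
  list(alt_fwd = alt_fwd, alt_rev = alt - alt_fwd,
       depth_fwd = alt_fwd + ref_fwd,
       depth_rev = depth - alt_fwd - ref_fwd)
}

empty_truth <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), true_class = character(),
             true_cell_fraction = numeric(), true_vaf = numeric(),
             stringsAsFactors = FALSE)
}

#' Simulate one sample's stranded pileup with ground truth
#'
#' Draws `n_background_sites` error-only sites plus, for a patient, one
#' somatic variant site with mutant-cell fraction
#' `c = f_dnt + f_sp` and alt reads ~ Binomial(depth, c/2 + error), and, at
#' rate `germline_snp_rate`, one heterozygous polymorphism with alt reads
#' ~ Binomial(depth, 0.5). Strand assignment is per-read Bernoulli. A truth
#' record is emitted for every injected variant.
#'
#' @param config A [sim_config()].
#' @param sample_id Sample identifier.
#' @param group `"patient"` or `"control"`.
#' @param dnt_percent DNT percentage (patients; default drawn from
#'   `config$dnt_range`).
#' @param seed Optional integer seed for this sample.
#' @return A list with `pileup` (with `sample` column) and `truth` data
#'   frames.
#' @export
simulate_sample <- function(config, sample_id, group = c("patient", "control"),
                            dnt_percent = NULL, seed = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  reg <- config$region
  n_var <- (group == "patient") +
    (stats::runif(1) < config$germline_snp_rate)
  # distinct site positions: background plus up to two variant sites
  pos <- sample(seq.int(reg$start, reg$end),
                config$n_background_sites + 2L)
  var_pos <- pos[seq_len(2L)]
  bg_pos <- if (config$n_background_sites > 0L)
    sort(pos[-(1:2)]) else integer()

  truth <- empty_truth()
  rows <- list()

  if (config$n_background_sites > 0L) {
    depth <- sim_depth(length(bg_pos), config)
    alt <- stats::rbinom(length(bg_pos), depth, config$error_rate)
    ref <- sample(BASES, length(bg_pos), replace = TRUE)
    alt_allele <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
    st <- split_strands(depth, alt, config$strand_balance)
    rows$background <- data.frame(
      sample = sample_id, chrom = reg$chrom, pos = bg_pos, ref = ref,
      alt = alt_allele, depth = depth, alt_fwd = st$alt_fwd,
      alt_rev = st$alt_rev, depth_fwd = st$depth_fwd,
      depth_rev = st$depth_rev, stringsAsFactors = FALSE)
  }

  if (group == "patient") {
    if (is.null(dnt_percent)) {
      dnt_percent <- stats::runif(1, config$dnt_range[1], config$dnt_range[2])
    }
    f_dnt <- dnt_percent / 100 * config$mutant_dnt_fraction *
      config$lymph_multiplier
    f_sp <- 0
    if (stats::runif(1) < config$sp_proportion) {
      f_sp <- stats::runif(1, config$sp_fraction_range[1],
                           config$sp_fraction_range[2]) *
        config$sp_compartment * config$lymph_multiplier
    }
    cf <- min(1, f_dnt + f_sp)
    tv <- cf / 2
    depth <- sim_depth(1L, config)
    alt <- stats::rbinom(1L, depth, tv + config$error_rate * (1 - tv))
    is_del <- stats::runif(1) < config$indel_fraction
    if (is_del) {
      ref <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
      alt_allele <- "-"
    } else {
      ref <- sample(BASES, 1L)
      alt_allele <- sample(setdiff(BASES, ref), 1L)
    }
    st <- split_strands(depth, alt, config$strand_balance)
    rows$somatic <- data.frame(
      sample = sample_id, chrom = reg$chrom, pos = var_pos[1], ref = ref,
      alt = alt_allele, depth = depth, alt_fwd = st$alt_fwd,
      alt_rev = st$alt_rev, depth_fwd = st$depth_fwd,
      depth_rev = st$depth_rev, stringsAsFactors = FALSE)
    truth <- rbind(truth, data.frame(
      sample_id = sample_id, chrom = reg$chrom, pos = var_pos[1], ref = ref,
      alt = alt_allele, true_class = "somatic", true_cell_fraction = cf,
      true_vaf = tv, stringsAsFactors = FALSE))
  }

  if (n_var == 2L || (group == "control" && n_var == 1L)) {
    depth <- sim_depth(1L, config)
    alt <- stats::rbinom(1L, depth, 0.5)
    ref <- sample(BASES, 1L)
    alt_allele <- sample(setdiff(BASES, ref), 1L)
    st <- split_strands(depth, alt, config$strand_balance)
    rows$germline <- data.frame(
      sample = sample_id, chrom = reg$chrom, pos = var_pos[2], ref = ref,
      alt = alt_allele, depth = depth, alt_fwd = st$alt_fwd,
      alt_rev = st$alt_rev, depth_fwd = st$depth_fwd,
      depth_rev = st$depth_rev, stringsAsFactors = FALSE)
    truth <- rbind(truth, data.frame(
      sample_id = sample_id, chrom = reg$chrom, pos = var_pos[2], ref = ref,
      alt = alt_allele, true_class = "germline_het", true_cell_fraction = 1,
      true_vaf = 0.5, stringsAsFactors = FALSE))
  }

  pileup <- do.call(rbind, rows)
  if (is.null(pileup)) {
    pileup <- data.frame(sample = character(), chrom = character(),
                         pos = integer(), ref = character(),
                         alt = character(), depth = integer(),
                         alt_fwd = integer(), alt_rev = integer(),
                         depth_fwd = integer(), depth_rev = integer(),
                         stringsAsFactors = FALSE)
  }
  pileup <- pileup[order(pileup$pos), , drop = FALSE]
  rownames(pileup) <- NULL
  list(pileup = as_pileup(pileup), truth = truth)
}

child_seed <- function(master, i) {
  # stable per-sample stream: linear-congruential style mix, kept in 32-bit
  # integer range so cohorts reproduce across platforms
  as.integer((as.numeric(master) * 48271 + i * 1009) %% 2147483629)
}

#' Simulate a screening cohort
#'
#' Generates `n_patients + n_controls` samples with per-sample pileups, a
#' pooled truth table and a manifest. Each sample draws from its own child
#' seed derived deterministically from `seed`, so cohorts are reproducible
#' and individual samples can be regenerated in isolation.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @return A list with `pileups` (named list of pileup data frames), `truth`
#'   (pooled truth data frame) and `manifest` (sample_id, group, dnt_percent,
#'   seed).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_patients + config$n_controls
  ids <- c(paste0("SP", seq_len(config$n_patients), recycle0 = TRUE),
           paste0("SC", seq_len(config$n_controls), recycle0 = TRUE))
  groups <- rep(c("patient", "control"),
                c(config$n_patients, config$n_controls))
  dnt <- ifelse(groups == "patient",
                stats::runif(max(n, 1L), config$dnt_range[1],
                             config$dnt_range[2])[seq_len(n)],
                NA_real_)
  manifest <- data.frame(sample_id = ids, group = groups, dnt_percent = dnt,
                         seed = vapply(seq_len(n), child_seed, 1L,
                                       master = seed),
                         stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(pileups = list(), truth = empty_truth(),
                manifest = manifest[0, ]))
  }
  pileups <- vector("list", n)
  names(pileups) <- ids
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_sample(config, ids[i], groups[i],
                           dnt_percent = if (groups[i] == "patient")
                             dnt[i] else NULL,
                           seed = manifest$seed[i])
    pileups[[i]] <- sim$pileup
    truth[[i]] <- sim$truth
  }
  list(pileups = pileups, truth = do.call(rbind, truth), manifest = manifest)
}
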