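#' @keywords internal
"_PACKAGE"

PILEUP_COLS <- c("chrom", "pos", "ref", "alt", "depth", "alt_fwd", "alt_rev")
STRAND_COLS <- c("depth_fwd", "depth_rev")

#' Construct a genomic region table
#'
#' Regions are plain data frames with 1-based inclusive coordinates, matching
#' how positions are reported in amplicon-panel variant tables
#' (e.g. "chr10:90771840").
#'
#' @param chrom Chromosome names (non-empty strings).
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param label Optional free-text labels.
#' @return A data frame with columns `chrom`, `start`, `end`, `label`.
#' @export
genomic_regions <- function(chrom, start, end, label = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(!nzchar(chrom)) || anyNA(chrom)) {
    stop("chrom must be non-empty")
  }
  if (anyNA(start) || anyNA(end) || any(start > end)) {
    stop("regions require start <= end (1-based inclusive)")
  }
  data.frame(chrom = chrom, start = start, end = end,
             label = as.character(label), stringsAsFactors = FALSE)
}

#' Default target regions: FAS exons 7-9 with splice flanks (GRCh37)
#'
#' A single interval chr10:90770500-90774500 covering the FAS exon 7-9 cluster
#' and its intronic splice sites with margin. Exact exon boundaries are not
#' needed for screening: intronic splice-site variants (e.g. c.651+2T>C) must
#' be callable, so the target is deliberately a padded superset.
#'
#' @return A one-row region data frame (see [genomic_regions()]).
#' @export
default_regions <- function() {
  read_bed(system.file("extdata", "fas_target.bed", package = "fasmosaic",
                       mustWork = TRUE))
}

#' Read a BED file of target regions
#'
#' Standard BED (0-based, half-open) is converted on read to the package's
#' 1-based inclusive convention. Overlapping lines are kept as-is, never
#' merged.
#'
#' @param path Path to a BED file with at least 3 columns; a 4th column, when
#'   present, becomes the region label. `track`/`browser`/`#` lines are
#'   ignored.
#' @return A region data frame (see [genomic_regions()]); zero rows for an
#'   empty file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(genomic_regions(character(), integer(), integer(), character())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("BED line ", which(n < 3L)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    stop("BED line ", which(is.na(start0) | is.na(end0))[1],
         ": non-integer coordinates")
  }
  if (any(start0 >= end0)) {
    stop("BED line ", which(start0 >= end0)[1],
         ": start >= end (zero- or negative-width interval)")
  }
  label <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                  NA_character_)
  genomic_regions(chrom, start0 + 1L, end0, label)
}

#' Restrict a pileup to target regions
#'
#' @param pileup A stranded pileup data frame (see [read_pileup_tsv()]).
#' @param regions A region data frame, or `NULL` to keep everything.
#' @return The pileup rows whose position falls in at least one region, in
#'   their original order (filtering is idempotent and order-preserving).
#' @export
filter_regions <- function(pileup, regions = NULL) {
  if (is.null(regions) || nrow(pileup) == 0L) return(pileup)
  keep <- rep(FALSE, nrow(pileup))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (pileup$chrom == regions$chrom[i] &
                      pileup$pos >= regions$start[i] &
                      pileup$pos <= regions$end[i])
  }
  pileup[keep, , drop = FALSE]
}

validate_pileup <- function(pileup, where = "pileup") {
  counts <- c("depth", "alt_fwd", "alt_rev")
  for (col in counts) {
    if (any(pileup[[col]] < 0L, na.rm = TRUE)) {
      stop(where, ": negative ", col)
    }
  }
  bad <- which(pileup$alt_fwd + pileup$alt_rev > pileup$depth)
  if (length(bad)) {
    stop(where, ": alt_fwd + alt_rev exceeds depth at row ", bad[1],
         " (", pileup$chrom[bad[1]], ":", pileup$pos[bad[1]], ")")
  }
  if (all(STRAND_COLS %in% names(pileup))) {
    has <- !is.na(pileup$depth_fwd) & !is.na(pileup$depth_rev)
    if (any(has & pileup$depth_fwd + pileup$depth_rev != pileup$depth)) {
      stop(where, ": depth_fwd + depth_rev != depth")
    }
    if (any(has & (pileup$alt_fwd > pileup$depth_fwd |
                     pileup$alt_rev > pileup$depth_rev))) {
      stop(where, ": per-strand variant reads exceed per-strand depth")
    }
  }
  invisible(pileup)
}

as_pileup <- function(df) {
  for (col in STRAND_COLS) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_integer_, nrow(df))
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  for (col in c("depth", "alt_fwd", "alt_rev", STRAND_COLS)) {
    df[[col]] <- as.integer(df[[col]])
  }
  rownames(df) <- NULL
  validate_pileup(df)
}

#' Read a stranded pileup TSV
#'
#' The pileup TSV is the package's tabular exchange format for per-site,
#' per-allele read evidence split by strand: tab-separated with a mandatory
#' header `chrom pos ref alt depth alt_fwd alt_rev` and optional
#' `depth_fwd depth_rev` columns. Positions are 1-based. Deletion alleles are
#' encoded as `alt = "-"` with `ref` holding the deleted bases.
#'
#' @param path Path to the TSV file.
#' @param regions Optional region data frame; rows outside the regions are
#'   dropped (order preserved).
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_fwd`, `alt_rev`, `depth_fwd`, `depth_rev` (the last two `NA` when
#'   absent from the file). Extra columns in the file (e.g. `sample`) are
#'   carried through.
#' @export
read_pileup_tsv <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("pileup file is empty (header required): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(PILEUP_COLS, header)
  if (length(missing_cols)) {
    stop("pileup header lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    out <- as.data.frame(setNames(rep(list(character()), length(header)), header),
                         stringsAsFactors = FALSE)
    return(as_pileup(out))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != length(header))) {
    bad <- which(n != length(header))[1]
    stop("pileup line ", bad + 1L, ": expected ", length(header),
         " fields, found ", n[bad])
  }
  mat <- do.call(rbind, fields)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- header
  int_cols <- intersect(c("pos", "depth", "alt_fwd", "alt_rev", STRAND_COLS),
                        header)
  for (col in int_cols) {
    parsed <- suppressWarnings(as.integer(out[[col]]))
    bad <- which(is.na(parsed) & !out[[col]] %in% c("NA", ".", ""))
    if (length(bad)) {
      stop("pileup line ", bad[1] + 1L, ": non-integer value '",
           out[[col]][bad[1]], "' in column ", col)
    }
    out[[col]] <- parsed
  }
  out <- as_pileup(out)
  filter_regions(out, regions)
}

#' Write a stranded pileup TSV
#'
#' @param pileup A pileup data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  cols <- c(intersect("sample", names(pileup)), PILEUP_COLS,
            intersect(STRAND_COLS, names(pileup)))
  utils::write.table(pileup[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Load the bundled published fixtures
#'
#' Returns the study cohort and variant report bundled with the package: 8
#' ALPS-sFAS patients (P1-P8) with their DNT percentages, serum biomarkers and
#' known FAS mutations, 44 non-ALPS controls (C1-C44), and the 12 reported
#' variant records with strand-resolved read counts. Variant records carry the
#' published VAF and vendor strand-bias values as metadata columns
#' (`vaf_printed_pct`, `strand_bias_printed`); classification is left to
#' [call_sample()]. The `RV` record is a recurrent polymorphism not tied to a
#' single cohort sample.
#'
#' P8's known 3-bp deletion (c.812_814del) was never assigned printed genomic
#' coordinates, so its `known_pos` is `NA`; it is the expected false negative
#' of the screen (one supporting read, below the minimum allele coverage).
#'
#' @return A list with `samples` (52-row data frame: `sample_id`, `group`,
#'   `dnt_percent`, biomarker metadata, `known_*` columns) and `variants`
#'   (12-row pileup-style data frame with a `sample` column).
#' @export
load_fixtures <- function() {
  samples_path <- system.file("extdata", "table1_samples.tsv",
                              package = "fasmosaic", mustWork = TRUE)
  variants_path <- system.file("extdata", "table2_variants.tsv",
                               package = "fasmosaic", mustWork = TRUE)
  patients <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                                na.strings = "NA")
  patients$group <- "patient"
  patients$known_pos <- as.integer(patients$known_pos)
  controls <- data.frame(
    sample_id = paste0("C", 1:44),
    age_years = NA, dnt_percent = NA_real_,
    vitb12 = NA_character_, sfasl = NA_character_, il10 = NA_character_,
    igg = NA_character_, iga = NA_character_, igm = NA_character_,
    known_chrom = NA_character_, known_pos = NA_integer_,
    known_ref = NA_character_, known_alt = NA_character_,
    known_cdna = NA_character_,
    group = "control", stringsAsFactors = FALSE
  )
  samples <- rbind(patients, controls)
  rownames(samples) <- NULL

  variants <- utils::read.delim(variants_path, stringsAsFactors = FALSE)
  variants <- as_pileup(variants)
  list(samples = samples, variants = variants)
}

vcf_alleles <- function(chrom, pos, ref, alt) {
  # Deletions ("-" alt with ref holding the deleted bases) are anchored per
  # VCF: an N anchor base is used because no reference sequence is bundled.
  if (alt == "-") {
    list(pos = pos - 1L, ref = paste0("N", ref), alt = "N")
  } else {
    list(pos = pos, ref = ref, alt = alt)
  }
}

#' Write variant calls to a minimal VCF 4.2 file
#'
#' One record per call; deletions are anchored (`POS-1`, `REF = N<deleted>`,
#' `ALT = N`). INFO carries the sample id, depth, VAF, per-strand variant
#' counts, strand-bias score and p-value, and the germline/somatic
#' classification. FILTER is `PASS` or the semicolon-joined failed filter
#' names.
#'
#' @param calls A calls data frame from [call_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fasmosaic",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Variant reads forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Variant reads reverse strand\">",
    "##INFO=<ID=SBSCORE,Number=1,Type=Float,Description=\"Strand-bias score (0.5 balanced, 1 one-sided)\">",
    "##INFO=<ID=SBPVAL,Number=1,Type=Float,Description=\"Fisher exact strand-bias p-value\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"somatic, germline_het, germline_hom or rejected\">",
    "##FILTER=<ID=min_vaf,Description=\"VAF below minimum allele frequency\">",
    "##FILTER=<ID=min_allele_cov,Description=\"Fewer supporting reads than minimum allele coverage\">",
    "##FILTER=<ID=strand_bias,Description=\"Strand-bias score above cutoff with significant Fisher p\">",
    "##FILTER=<ID=min_strand_cov,Description=\"Per-strand coverage below minimum\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    al <- vcf_alleles(calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i])
    filt <- if (isTRUE(calls$filters_passed[i])) "PASS" else
      gsub(",", ";", calls$failed_filters[i])
    info <- sprintf(
      "SAMPLE=%s;DP=%d;AF=%s;SAF=%d;SAR=%d;SBSCORE=%s;SBPVAL=%s;CLASS=%s",
      calls$sample_id[i], calls$depth[i],
      format(calls$vaf[i], digits = 15),
      calls$alt_fwd[i], calls$alt_rev[i],
      format(calls$strand_bias[i], digits = 15),
      format(calls$sb_pvalue[i], digits = 15),
      calls$classification[i])
    rows[i] <- paste(calls$chrom[i], al$pos, ".", al$ref, al$alt, ".",
                     filt, info, sep = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a VCF written by [write_vcf()]
#'
#' Restores the original site and allele encoding (anchored deletions become
#' `alt = "-"` at the deleted position) along with counts, VAF, strand-bias
#' statistics and classification from INFO.
#'
#' @param path Path to a VCF produced by [write_vcf()].
#' @return A calls data frame in the [call_sample()] layout.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) < 3L) NA_character_ else m[3]
  }
  out <- lapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    pos <- as.integer(f[2]); ref <- f[4]; alt <- f[5]
    if (nchar(ref) > nchar(alt) && alt == substr(ref, 1L, nchar(alt))) {
      # anchored deletion
      ref <- substr(ref, nchar(alt) + 1L, nchar(ref))
      pos <- pos + 1L
      alt <- "-"
    }
    info <- f[8]
    passed <- identical(f[7], "PASS")
    data.frame(
      sample_id = info_field(info, "SAMPLE"),
      chrom = f[1], pos = pos, ref = ref, alt = alt,
      depth = as.integer(info_field(info, "DP")),
      alt_fwd = as.integer(info_field(info, "SAF")),
      alt_rev = as.integer(info_field(info, "SAR")),
      vaf = as.numeric(info_field(info, "AF")),
      strand_bias = as.numeric(info_field(info, "SBSCORE")),
      sb_pvalue = as.numeric(info_field(info, "SBPVAL")),
      filters_passed = passed,
      failed_filters = if (passed) "" else gsub(";", ",", f[7]),
      classification = info_field(info, "CLASS"),
      stringsAsFactors = FALSE)
  })
  if (length(out) == 0L) {
    return(empty_calls())
  }
  do.call(rbind, out)
}
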