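test_that("pileup TSV reading parses, validates and region-filters", {
  path <- write_table2_tsv()

  full <- read_pileup_tsv(path)
  expect_equal(nrow(full), 12L)
  expect_equal(full$pos[1], 90771840L)
  expect_true(all(full$alt_fwd + full$alt_rev <= full$depth))

  # manual interval check: exactly 7 reported positions fall in this window
  sub <- read_pileup_tsv(path, genomic_regions("chr10", 90773000, 90774000))
  expect_setequal(sub$pos, c(90773099L, 90773100L, 90773123L, 90773125L,
                             90773876L, 90773878L, 90773947L))
  expect_equal(nrow(sub), 7L)
  # order preserved and filtering idempotent
  expect_equal(sub$pos, full$pos[full$pos %in% sub$pos])
  expect_identical(filter_regions(sub, genomic_regions("chr10", 90773000,
                                                       90774000)), sub)

  # header-only file gives an empty pileup
  empty_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt\tdepth\talt_fwd\talt_rev", empty_path)
  expect_equal(nrow(read_pileup_tsv(empty_path)), 0L)
})

test_that("malformed pileup rows are rejected with their line number", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tdepth\talt_fwd\talt_rev",
               "chr10\t100\tA\tG\t50\t2\t1",
               "chr10\toops\tA\tG\t50\t2\t1"), bad)
  expect_error(read_pileup_tsv(bad), "line 3")

  short <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tdepth\talt_fwd\talt_rev",
               "chr10\t100\tA\tG"), short)
  expect_error(read_pileup_tsv(short), "line 2")

  over <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tdepth\talt_fwd\talt_rev",
               "chr10\t100\tA\tG\t5\t4\t3"), over)
  expect_error(read_pileup_tsv(over), "exceeds depth")
})

test_that("BED regions convert from 0-based half-open to 1-based inclusive", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr10\t90770000\t90775000\tFAS_target", bed)
  reg <- read_bed(bed)
  expect_equal(reg$start, 90770001L)
  expect_equal(reg$end, 90775000L)
  expect_equal(reg$label, "FAS_target")

  # empty file -> empty region set
  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  expect_equal(nrow(read_bed(empty)), 0L)

  # overlapping lines are kept distinct, never merged
  two <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t100\ta", "chr1\t50\t150\tb"), two)
  expect_equal(nrow(read_bed(two)), 2L)

  # degenerate interval is an error
  degen <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100", degen)
  expect_error(read_bed(degen), "start >= end")
})

test_that("BED conversion agrees with rtracklayer's import", {
  skip_if_not_installed("rtracklayer")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr10\t90770499\t90774500\tFAS", "chr2\t0\t10\tx"), bed)
  ours <- read_bed(bed)
  theirs <- rtracklayer::import(bed)
  expect_equal(ours$start, BiocGenerics::start(theirs))
  expect_equal(ours$end, BiocGenerics::end(theirs))
  expect_equal(ours$chrom, as.character(GenomicRanges::seqnames(theirs)))
})

test_that("VCF round trip preserves sites, counts and classification", {
  fx <- load_fixtures()
  calls <- call_sample(fx$variants, regions = default_regions())
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)

  back <- read_vcf(path)
  expect_equal(nrow(back), nrow(calls))
  expect_equal(back$chrom, calls$chrom)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$alt_fwd, calls$alt_fwd)
  expect_equal(back$alt_rev, calls$alt_rev)
  expect_equal(back$vaf, calls$vaf, tolerance = 1e-9)
  expect_equal(back$classification, calls$classification)

  # the deletion row is written as an anchored-REF record
  lines <- readLines(path)
  del <- grep("\t90773877\t", lines, value = TRUE)
  expect_length(del, 1L)
  expect_match(del, "\tNG\tN\t")

  # a P1-style somatic SNV is a PASS record at its original position
  p1 <- grep("\t90771840\t", lines, value = TRUE)
  expect_match(p1, "\tPASS\t")
  expect_match(p1, "CLASS=somatic")

  # empty call set -> header-only VCF
  empty_path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], empty_path)
  expect_true(all(grepl("^#", readLines(empty_path))))
  expect_equal(nrow(read_vcf(empty_path)), 0L)
})

test_that("written VCF parses with vcfR", {
  skip_if_not_installed("vcfR")
  fx <- load_fixtures()
  calls <- call_sample(fx$variants, regions = default_regions())
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), nrow(calls))
  expect_setequal(as.integer(v@fix[, "POS"]),
                  ifelse(calls$alt == "-", calls$pos - 1L, calls$pos))
})

test_that("bundled fixtures carry the published cohort and read counts", {
  fx <- load_fixtures()
  expect_equal(nrow(fx$samples), 52L)
  expect_equal(sum(fx$samples$group == "patient"), 8L)
  expect_equal(sum(fx$samples$group == "control"), 44L)

  # 7 patients have their known somatic variant among the reported records
  pat <- fx$samples[fx$samples$group == "patient", ]
  in_table <- !is.na(pat$known_pos) &
    pat$known_pos %in% fx$variants$pos
  expect_equal(sum(in_table), 7L)
  expect_false(in_table[pat$sample_id == "P8"])
  expect_equal(pat$dnt_percent[pat$sample_id == "P8"], 4)

  # each reported record satisfies alt_fwd + alt_rev = printed allele coverage
  allele_cov <- c(10L, 30L, 46L, 10L, 8L, 17L, 4L, 3L, 3L, 96L, 190L, 112L)
  expect_equal(fx$variants$alt_fwd + fx$variants$alt_rev, allele_cov)
  # and all positions sit inside the default target region
  reg <- default_regions()
  expect_true(all(fx$variants$pos >= reg$start & fx$variants$pos <= reg$end))
})
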