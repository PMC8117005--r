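test_that("VAF computation and percent formatting match the published report", {
  # (alt reads, depth, printed percent) for the internally consistent records
  cases <- list(c(10, 239, 4.2), c(30, 394, 7.6), c(46, 399, 11.5),
                c(10, 367, 2.7), c(8, 101, 7.9), c(17, 195, 8.7),
                c(4, 212, 1.9), c(3, 141, 2.1), c(3, 104, 2.9),
                c(190, 395, 48.1))
  for (cs in cases) {
    p <- make_pileup(pos = 1, depth = cs[2], alt_fwd = cs[1], alt_rev = 0)
    expect_equal(vaf_percent(compute_vaf(p)), cs[3])
  }
  expect_equal(compute_vaf(make_pileup(pos = 1, depth = 100, alt_fwd = 0,
                                       alt_rev = 0)), 0)
  expect_error(compute_vaf(make_pileup(pos = 1, depth = 0, alt_fwd = 0,
                                       alt_rev = 0)), "depth > 0")
  # half-up rounding at the boundary
  expect_equal(vaf_percent(0.0415), 4.2)
  expect_equal(vaf_percent(0.04149), 4.1)
})

test_that("strand-bias score is symmetric, bounded and matches direct evaluation", {
  expect_equal(strand_bias_score(make_pileup(pos = 1, depth = 200,
                                             alt_fwd = 5, alt_rev = 5,
                                             depth_fwd = 100,
                                             depth_rev = 100)), 0.5)
  expect_equal(strand_bias_score(make_pileup(pos = 1, depth = 200,
                                             alt_fwd = 10, alt_rev = 0,
                                             depth_fwd = 120,
                                             depth_rev = 80)), 1.0)
  # direct evaluation: (6/119) / ((4/120) + (6/119))
  expect_equal(strand_bias_score(make_pileup(pos = 1, depth = 239,
                                             alt_fwd = 4, alt_rev = 6,
                                             depth_fwd = 120,
                                             depth_rev = 119)),
               (6 / 119) / ((4 / 120) + (6 / 119)), tolerance = 1e-12)
  expect_equal(round((6 / 119) / ((4 / 120) + (6 / 119)), 3), 0.602)

  expect_error(strand_bias_score(make_pileup(pos = 1, depth = 10,
                                             alt_fwd = 0, alt_rev = 0)),
               "variant read")

  # swap invariance and range, over random stranded pileups
  set.seed(41)
  for (i in 1:50) {
    df <- sample(50:200, 1); dr <- sample(50:200, 1)
    af <- sample(0:20, 1); ar <- sample(0:20, 1)
    if (af + ar == 0) af <- 1
    a <- make_pileup(pos = 1, depth = df + dr, alt_fwd = af, alt_rev = ar,
                     depth_fwd = df, depth_rev = dr)
    b <- make_pileup(pos = 1, depth = df + dr, alt_fwd = ar, alt_rev = af,
                     depth_fwd = dr, depth_rev = df)
    sa <- strand_bias_score(a)
    expect_equal(sa, strand_bias_score(b))
    expect_gte(sa, 0.5)
    expect_lte(sa, 1)
    expect_equal(strand_bias_pvalue(a), strand_bias_pvalue(b),
                 tolerance = 1e-12)
  }
})

test_that("Fisher strand-bias p-value matches enumeration oracle and fisher.test", {
  expect_equal(fisher_exact_2x2(5, 95, 5, 95), 1)
  expect_equal(fisher_exact_2x2(3, 100, 3, 100), 1)
  expect_lt(fisher_exact_2x2(10, 90, 0, 100), 0.05)

  # random tables: implementation vs combinatorial oracle vs stats::fisher.test
  set.seed(7)
  for (i in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:30, 1)
    c <- sample(0:15, 1); d <- sample(0:30, 1)
    if (a + b + c + d == 0) a <- 1
    p <- fisher_exact_2x2(a, b, c, d)
    expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
    expect_equal(p,
                 stats::fisher.test(matrix(c(a, b, c, d), 2,
                                           byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "negative")
})

test_that("filter chain applies the published thresholds", {
  cfg <- filter_config()
  # P7-style record: 4 of 212, balanced strands -> passes everything
  p7 <- make_pileup(pos = 90773099, ref = "G", alt = "T", depth = 212,
                    alt_fwd = 2, alt_rev = 2)
  res <- apply_filters(p7, cfg)
  expect_true(res$passed)
  expect_equal(res$failed_filters, "")

  # 2 supporting reads of 200 fails only the read-count filter
  low <- apply_filters(make_pileup(pos = 1, depth = 200, alt_fwd = 1,
                                   alt_rev = 1), cfg)
  expect_false(low$passed)
  expect_equal(low$failed_filters, "min_allele_cov")

  # fully one-sided support is removed only because BOTH conditions hold
  onesided <- make_pileup(pos = 1, depth = 200, alt_fwd = 10, alt_rev = 0,
                          depth_fwd = 100, depth_rev = 100)
  res1 <- apply_filters(onesided, cfg)
  expect_false(res1$passed)
  expect_equal(res1$failed_filters, "strand_bias")
  expect_equal(res1$strand_bias, 1.0)
  expect_lt(res1$sb_pvalue, 0.05)
  # same score with an insignificant p survives (conjunction, not disjunction)
  mild <- make_pileup(pos = 1, depth = 200, alt_fwd = 3, alt_rev = 0,
                      depth_fwd = 100, depth_rev = 100)
  resm <- apply_filters(mild, cfg)
  expect_equal(resm$strand_bias, 1.0)
  expect_gte(resm$sb_pvalue, 0.05)
  expect_true(resm$passed)

  # a raised min_strand_cov rejects thin strands
  thin <- make_pileup(pos = 1, depth = 100, alt_fwd = 5, alt_rev = 0,
                      depth_fwd = 95, depth_rev = 5)
  expect_true(apply_filters(thin, cfg)$passed)
  expect_match(apply_filters(thin, filter_config(min_strand_cov = 10))$
                 failed_filters, "min_strand_cov")
})

test_that("allele-fraction bands separate somatic from germline calls", {
  cfg <- filter_config()
  expect_equal(classify_call(0.481, cfg), "germline_het")
  expect_equal(classify_call(0.042, cfg), "somatic")
  expect_equal(classify_call(1.0, cfg), "germline_hom")
  expect_equal(classify_call(c(0.35, 0.65, 0.9, 0.349, 0.89), cfg),
               c("germline_het", "germline_het", "germline_hom", "somatic",
                 "somatic"))
})

test_that("calling the published records gives 12 passes: 9 somatic, 3 germline het", {
  fx <- load_fixtures()
  calls <- call_sample(fx$variants, regions = default_regions())
  expect_equal(nrow(calls), 12L)
  expect_true(all(calls$filters_passed))
  expect_equal(sum(calls$classification == "somatic"), 9L)
  expect_equal(sum(calls$classification == "germline_het"), 3L)
  expect_setequal(calls$sample_id[calls$classification == "germline_het"],
                  c("C18", "C32", "RV"))
  # deterministic output order: position then alt allele
  expect_equal(calls$pos, sort(calls$pos))

  # empty pileup -> empty calls
  expect_equal(nrow(call_sample(fx$variants[0, ])), 0L)

  # P8-like single-read deletion is rejected by read-count and VAF floors
  p8 <- make_pileup(pos = 90774000, ref = "TGC", alt = "-", depth = 141,
                    alt_fwd = 1, alt_rev = 0)
  rej <- call_sample(p8, regions = default_regions())
  expect_false(rej$filters_passed)
  expect_equal(rej$classification, "rejected")
  expect_match(rej$failed_filters, "min_vaf")
  expect_match(rej$failed_filters, "min_allele_cov")
})

test_that("raising thresholds never lets more records through", {
  set.seed(101)
  base <- filter_config()
  for (i in 1:20) {
    pile <- random_pileup(50)
    n_base <- sum(apply_filters(pile, base)$passed)
    stricter_vaf <- filter_config(min_vaf = 0.05)
    stricter_cov <- filter_config(min_allele_cov = 6)
    expect_lte(sum(apply_filters(pile, stricter_vaf)$passed), n_base)
    expect_lte(sum(apply_filters(pile, stricter_cov)$passed), n_base)
  }
})
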