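# helpers for building small stranded pileups and writing temp fixtures

make_pileup <- function(pos, ref = "A", alt = "G", depth, alt_fwd, alt_rev,
                        depth_fwd = NA_integer_, depth_rev = NA_integer_,
                        chrom = "chr10") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             depth = as.integer(depth), alt_fwd = as.integer(alt_fwd),
             alt_rev = as.integer(alt_rev),
             depth_fwd = as.integer(depth_fwd),
             depth_rev = as.integer(depth_rev),
             stringsAsFactors = FALSE)
}

write_pileup_fixture <- function(pileup, strand_depths = FALSE,
                                 env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  cols <- c("chrom", "pos", "ref", "alt", "depth", "alt_fwd", "alt_rev")
  if (strand_depths) cols <- c(cols, "depth_fwd", "depth_rev")
  write.table(pileup[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

# table-2 fixture re-expressed as a plain (sample-less) pileup TSV on disk
write_table2_tsv <- function(env = parent.frame()) {
  fx <- load_fixtures()
  write_pileup_fixture(fx$variants, strand_depths = FALSE, env = env)
}

# brute-force two-sided Fisher p by direct combinatorial enumeration
# (independent of dhyper / fisher.test): P(table) via lchoose, summing all
# tables with the observed margins whose probability <= observed
oracle_fisher_p <- function(a, b, c, d) {
  nf <- a + b
  nr <- c + d
  k <- a + c
  if (nf + nr == 0) return(1)
  xs <- max(0, k - nr):min(k, nf)
  logp <- lchoose(nf, xs) + lchoose(nr, k - xs) - lchoose(nf + nr, k)
  probs <- exp(logp)
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# brute-force binomial upper tail by direct PMF summation
oracle_binom_tail <- function(n, p, k) {
  if (k > n) return(0)
  sum(vapply(k:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
             numeric(1)))
}

random_pileup <- function(n, max_depth = 400) {
  depth <- sample(10:max_depth, n, replace = TRUE)
  alt <- rbinom(n, depth, runif(n, 0, 0.2))
  alt_fwd <- rbinom(n, alt, 0.5)
  make_pileup(pos = sample(90770501:90774400, n), depth = depth,
              alt_fwd = alt_fwd, alt_rev = alt - alt_fwd)
}
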