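---
title: "Screening whole blood for mosaic FAS mutations: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening whole blood for mosaic FAS mutations: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasmosaic)
```

## The problem

Autoimmune lymphoproliferative syndrome (ALPS) is a disorder of FAS-mediated
lymphocyte apoptosis. In the somatic form (ALPS-sFAS), a heterozygous FAS
mutation — usually in the exon 7–9 region encoding the intracellular
domain — is carried only by a subpopulation of blood cells, enriched in
CD3+TCRαβ+CD4−CD8− double-negative T cells (DNT). The classical diagnostic
route sorts DNT and Sanger-sequences them; the alternative this package
models is to sequence DNA from *whole blood* on a targeted amplicon panel at
moderate depth and look for low allele-fraction variants in the FAS exon 7–9
window with a customised somatic caller.

A heterozygous mutation in a mutant-cell fraction $c$ contributes one mutant
allele per carrier cell, so the expected variant allele frequency (VAF) is

$$ \mathrm{E}[\mathrm{VAF}] = c/2, \qquad c = f_{\mathrm{DNT}} + f_{\mathrm{SP}}, $$

where $f_{\mathrm{DNT}}$ is the mutant DNT fraction of nucleated cells and
$f_{\mathrm{SP}}$ the mutant single-positive (CD4+ or CD8+) fraction. With
DNT percentages of 4–30% this puts the signal at VAF ≈ 2–16%: well above
sequencing error, but far below a germline heterozygote.

## The filter chain

`call_sample()` applies, per site and allele, the filter chain of
`filter_config()`:

| parameter | default | meaning |
|---|---|---|
| `min_vaf` | 0.01 | minimum allele frequency (fraction of reads) |
| `min_allele_cov` | 3 | minimum variant-supporting reads |
| `sb_score_max` | 0.85 | strand-bias score cutoff (0.5 balanced … 1 one-sided) |
| `sb_pvalue_min` | 0.05 | Fisher strand-bias significance cutoff |
| `min_strand_cov` | 0 | minimum per-strand total coverage (none by default) |

A record is removed as a strand artifact only when **both** the score exceeds
`sb_score_max` **and** the Fisher exact p-value falls below `sb_pvalue_min`.
The conjunction matters: genuinely strong signals often reach Fisher
significance with only mild rate imbalance (a 46%-vs-65% strand split at
depth 172 has p ≈ 0.01 but a score of 0.58) and must not be discarded.

Passing records are classified by allele-fraction band: `germline_het` in
[0.35, 0.65], `germline_hom` at ≥ 0.90, `somatic` otherwise. The het band is
deliberately wide around 0.5 so that sampling noise on a true heterozygote
(binomial sd ≈ 0.04 at depth 150) stays inside it.

### The strand-bias score

Vendor pipelines report a proprietary strand-bias statistic whose formula is
not public and whose inputs (per-strand total coverage) are not part of the
tabulated variant reports this package bundles. The package therefore defines
its own documented score with the same range convention: with per-strand
variant rates $r_f = \mathrm{alt}_f/\mathrm{depth}_f$ and
$r_r = \mathrm{alt}_r/\mathrm{depth}_r$,

$$ \mathrm{SB} = \frac{\max(r_f, r_r)}{r_f + r_r} \in [0.5, 1], $$

0.5 for balanced rates, 1.0 when one strand carries no variant reads, and
invariant under swapping strands. Bundled published scores are kept as
fixture metadata (`strand_bias_printed`) and are *not* recomputed. When
per-strand depths are absent, they are imputed as an even split of total
depth (ties to forward) — the least-informative assumption, overridden
whenever real data provides them.

The Fisher test is the exact conditional test on
[altF, refF; altR, refR]. It is implemented as a vectorised hypergeometric
tail sum using the conventional `1 + 1e-7` relative tie tolerance, so it
agrees with `stats::fisher.test()` to numerical precision (the test suite
checks both that agreement and an independent combinatorial enumeration).

## The detection-limit model

Two layers, in `min_detectable_vaf()` and `detection_power()`:

1. **Deterministic floor.** A call needs `min_allele_cov` reads and VAF ≥
   `min_vaf`, so the smallest callable VAF at depth $d$ is
   $\max(\texttt{min\_vaf},\ \texttt{min\_allele\_cov}/d)$ — read-count-bound
   below depth 300 (at defaults), VAF-bound above. Depths below
   `min_allele_cov` return 1: nothing is detectable. This floor reproduces
   the supporting-reads/depth arithmetic of the assay's reported limits
   (8/101 = 7.9%, 4/212 = 1.9%).

2. **Exact-binomial power.** The floor says what *could* be called; the
   power model says how often it *will* be. With alt reads
   $X \sim \mathrm{Bin}(d,\ v + e(1-v))$ — $v$ the true VAF, $e$ the
   per-base error rate pushed toward the variant allele — detection
   probability is $P(X \ge k^*)$ with
   $k^* = \max(\texttt{min\_allele\_cov}, \lceil \texttt{min\_vaf}\cdot d\rceil)$,
   computed as an exact tail sum. This probabilistic layer is the package's
   generalisation of the assay's empirical limits, not something the
   original validation reported.

Numerical choices: the ceiling in $k^*$ is evaluated with a $10^{-9}$ guard
so that exact multiples (e.g. $0.01 \times 300$) do not round up through
floating-point noise; `required_depth()` scans depths in vectorised chunks
and returns `NA` (undetectable) when the error-inflated VAF does not exceed
`min_vaf`, since the VAF floor then binds at every depth.

Two modelling caveats are deliberate. First, power is *not* globally
monotone in depth: $k^*$ jumps by one at every depth multiple of
$1/\texttt{min\_vaf}$, producing a small sawtooth (depth 300 with $k^*=3$
can out-power depth 301 with $k^*=4$); the property tests assert
monotonicity within constant-$k^*$ segments and in true VAF everywhere.
Second, the model ignores the strand-bias filter (balanced strands assumed).
The simulator quantifies what that omission costs: at operating points with
high power the full chain detects a fraction of a percent to ~2% fewer
variants than the model, because occasionally all supporting reads land on
one strand by chance and trip the filter. Model-vs-simulation agreement is
therefore checked with the strand filter neutralised, and the filter's
detection loss is reported separately.

## The synthetic-data generator

`simulate_cohort()` replaces patient sequencing data. Per sample it
generates a stranded pileup over the FAS target window plus ground-truth
records. Defaults are the study conditions:

* cohort shape 8 patients / 44 controls;
* patient DNT drawn uniformly from 4–30.7% (the observed cohort range), all
  DNT assumed mutation carriers (`mutant_dnt_fraction = 1`, configurable
  down);
* single-positive involvement in all patients
  (`sp_proportion = 1`): the mutant fraction *within* the single-positive
  compartment is drawn from 10–20% (`sp_fraction_range`) and multiplied by
  the compartment's share of nucleated cells (`sp_compartment`, default
  0.25). That composition puts the SP contribution at ≈ 2.5–5 cell-fraction
  points, which is what the reported patient VAFs imply (a patient with DNT
  5.2% and VAF 4.2% carries the mutation in ≈ 8.4% of cells); reading the
  10–20% as a direct cell fraction would more than double every patient's
  expected VAF and contradict those observations;
* per-site depth lognormal with median 200 and `sdlog` 0.35 (central 95%
  ≈ 100–400 reads, the panel's reported coverage range);
* per-base error $10^{-3}$ toward the variant allele; strand balance 0.5
  with per-read Bernoulli assignment (so per-strand depths always sum
  correctly);
* a heterozygous in-region polymorphism in 5% of samples
  (`germline_snp_rate`; the original control set contained a few such
  carriers, and no rate is published — this is the package's choice);
* 25% of injected somatic events are 3-bp deletions (2 of the 8 published
  patient mutations are deletions);
* 100 error-only background sites per sample.

Whole-blood cell composition is collapsed into the single mutant-cell
fraction $c$ — the caller only ever sees allele counts. T-cell lymphopenia
under treatment is modelled only as a multiplicative shrinkage of both
mutant fractions (`lymph_multiplier`). Reproducibility: each sample draws
from a child seed derived deterministically from the master seed
(`child_seed()`, a fixed 32-bit linear mix), so cohorts are byte-identical
across runs and single samples can be regenerated in isolation.

What the generator does **not** emulate: read-level artifacts (homopolymer
indel error typical of semiconductor sequencing, PCR duplicates, mapping
error), amplicon-boundary effects, correlated error between strands, and
germline variation beyond a single het polymorphism per sample. Passing
simulation tests therefore demonstrate the statistical behaviour of the
filter chain under idealised noise, not robustness to platform-specific
artifact classes — on real data those are handled upstream (alignment,
visual inspection) and by the strand-bias filter itself.

## Validation accounting

`confusion_counts()` scores the screen per sample: a patient is a true
positive iff a *somatic-classified* call matches its known variant's site
and alleles; a control is a true negative iff it has *no passing call of any
classification* in-region. Germline polymorphism calls count against
specificity because the screen is scored before any annotation or
interpretation step — the accounting that matches the published 93.1% (41
of 44 controls call-free; the value is an inference from the three reported
control records, as the original report does not spell out its denominator).
Percentages are truncated (floored) to one decimal, the convention under
which 41/44 = 93.18% prints as 93.1; raw values are kept alongside
(`specificity_raw`). The expected false negative is the patient whose 3-bp
deletion had a single supporting read — below the 3-read floor — with DNT
at the 4% clinical cutoff.

VAF reporting rounds half-up to one decimal in percent (`vaf_percent()`),
matching the published table. Two of the twelve bundled records (C18, RV)
print VAFs inconsistent with their own counts/coverage (presumably
vendor-internal downsampling); the package reproduces VAFs only for the ten
internally consistent records and carries the printed values as metadata.

## Problem sizes

The test suite and the analysis scripts run everything at desk scale, chosen
so the full statistical checks stay cheap while estimates remain tight:
power sweeps use 2,000 replicates per grid cell (binomial SE ≤ 1.1 points),
slope recovery uses 200 patients at 5,000× coverage (slope SE ≈ 0.004), the
Fisher implementation is checked against enumeration on all 2×2 tables with
margins ≤ 30, and filter monotonicity on 1,000 random pileups.

## Known limitations

* The germline/somatic classification is a VAF-band heuristic standing in
  for a full germline caller; near-band VAFs (e.g. a somatic clone at 35%)
  are misclassified by construction.
* The LoD power model shares the simulator's idealisations (no
  platform-specific error, independent reads).
* Specificity accounting is cohort-level (a control with any call fails);
  there is no per-variant FDR model.
* Deletions are simulated as whole-allele counts; no attempt is made to
  model the lower per-read sensitivity of indel detection that likely
  contributed to the screen's one false negative.
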