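---
title: "Methods: mtDNA case-control variant analysis with mitovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA case-control variant analysis with mitovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovar)
```

## The problem

Post-mortem nervous-system tissue from neurodegenerative-disease donors
carries a mixture of inherited (homoplasmic) and somatically acquired
(heteroplasmic) mitochondrial DNA variants. Case-control comparisons of such
cohorts ask whether variants accumulate preferentially in particular
compartments of the 16,569-bp circular mitochondrial genome — above all in
the non-coding control region (CR), which hosts the regulatory machinery for
mtDNA replication and transcription — and whether nuclear-encoded
mitochondrial genes carry an excess of rare, predicted-deleterious variants.
`mitovar` implements the post-variant-calling layer of that analysis:
retention filtering and heteroplasmy classification, circular-genome region
annotation, rare-variant prioritisation, pathogenicity-predictor concordance
scoring, contingency-table enrichment statistics, and mtDNA copy-number
estimation, together with a synthetic-cohort generator that makes every
stage testable without access to controlled sequencing data.

Upstream steps — read alignment, NUMT removal, consensus assembly, variant
calling, and annotation (impact classes, population frequencies, CADD,
predictor labels) — are out of scope: the package consumes their outputs.

## The region atlas

Coordinates are 1-based inclusive on the circular rCRS; intervals with
`start > end` wrap through the origin. The bundled atlas
(`inst/extdata/rcrs_atlas.tsv`, editable and overridable via `load_atlas()`)
encodes:

* **Top level** — a strict partition of all 16,569 positions into the CR
  (16024-576, 1,122 positions), the protein-coding/rRNA/tRNA loci, and the
  short non-coding spacers. Three pairs of genuinely overlapping mtDNA loci
  (MT-TI/MT-TQ, MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4) are trimmed so each
  position has exactly one gene; per-position counting, not transcript
  biology, is the goal here.
* **Hypervariable segments** — HV1 16024-16383, HV2 57-372, HV3 438-574
  (the MITOMAP convention; the region statistics always consume the atlas,
  never hard-coded spans, so users can substitute coordinates).
* **CR functional domains** — ETAS1/2, CSB1-3, LSP and the central domain.
  Only the ETAS2 span (16294-16357) is documented in the motivating
  literature at full precision; the remaining coordinates are
  *reconstructions* from the cited locus sources and are flagged as editable
  defaults. Statistical tests in the package's own suite rely only on the
  documented spans.
* **Secondary-structure elements A-M** — single-strand DNA fold elements of
  the CR. J (116-149) and K (181-226) are documented spans; the others are
  reconstructions placed inside the CR and marked as such.
* **Homopolymeric tracts** — 66-71, 300-316, 513-525, 5892, 3106-3107,
  12418-12425, 16182-16194; artifact-prone in short-read data and excluded
  by the retention filter.

With this reconstruction the central domain lies entirely outside HV1-3, so
fixtures cannot simultaneously reproduce arbitrary joint HV-by-domain
printed counts; domain tests therefore validate against direct assignment
rather than against a second source.

## Retention filter and ploidy

Rules are applied in a fixed order, all failures reported: depth >= 5 reads,
aggregate mapping quality >= 25, position outside homopolymer tracts, at
least one alt read on *each* strand (the weakest faithful reading of the
both-strands requirement; configurable), and heteroplasmy fraction (HF)
>= 0.01. All boundaries are closed as quoted in the motivating conventions.
HF in [0.95, 1] is homoplasmic; below 0.95 heteroplasmic. Duplicate call
keys (sample, position, ref, alt) keep the first-seen record, or under
conflicting HF the maximum-HF record with a warning — conservative toward
detection; upstream callers do not document a convention.

## Prioritisation cascades

Nuclear: drop LOW impact; drop sites seen in any control sample (matching
by site key, not genotype); keep population frequency < 0.01 *or absent*
(private, never-reported variants are retained — they are part of the
phenomenon of interest); keep CADD >= 10 (a missing CADD fails by default:
rarity without certified deleteriousness is not enough; configurable);
keep caller-PASS. The source conventions state both ">= 10" and "> 10" for
CADD in different places; we adopt >= 10 and expose the threshold. The five
predicates commute, so the retained set is order-independent; attrition
counts are reported per stage in cascade order. mtDNA prioritisation uses
the first three stages only. Gene windows pad gene spans by 10 kb on both
sides, floored at position 1.

## Concordance score

Raw predictor labels are simplified to D (deleterious lexicon) or B (benign
lexicon), case-insensitively; everything else is NA. With `n_D` and `n_B`
counts per variant: >= 4 unanimous D gives +2, 1-3 D gives +1, symmetric
for B, no calls gives 0. Any profile containing both D and B is treated as
conflicting and scores 0 — the levels therefore require unanimity among
non-NA calls. The boundary between "consistent" and "conflicting" is not
defined by the motivating description for mixed profiles such as 3xD + 1xB;
unanimity is the strictest consistent reading, is flagged here prominently,
and can be relaxed (`conflicting_zero = FALSE` scores mixed profiles by the
majority class).

## Statistics

* **Fisher exact (2x2, two-sided)**: sum of hypergeometric point
  probabilities not exceeding the observed one, with ties admitted at 1e-7
  relative tolerance — the convention of mainstream statistics packages,
  validated against an exhaustive enumeration oracle on small tables.
* **Chi-square**: uncorrected Pearson statistic, df = (r-1)(c-1), no Yates
  correction and no small-count guard (a warning is emitted instead),
  mirroring the uncorrected practice of the tables being reproduced.
  All-zero strata are pruned before testing, with a note.
* **Panel convention**: 2-row blocks get Fisher, >= 3-row blocks get
  chi-square. Two results described in the motivating text as Fisher tests
  on 4-row spectrum blocks numerically match the uncorrected chi-square;
  the implementation follows the table-shape convention and documents the
  discrepancy.
* **Counting unit** is the variant observation (sample x site), forced by
  the printed denominators; distinct-site counts are reported separately.
* **t-test**: pooled-variance two-tailed Student t from (n, mean, SD)
  summaries, df = n_a + n_b - 2. Validated against the printed
  copy-number comparison (p = 0.0377).
* No multiple-testing correction is applied across the panel, matching the
  descriptive tables being reproduced.

Two printed values cannot be reproduced exactly from printed inputs: a
variant-burden t-test whose printed group means are rounded (recomputed
0.617 vs printed 0.603) and one spectrum chi-square printed one unit of
least precision away (recomputed 0.0077 vs printed 0.007). The tests assert
agreement within one printed ulp and the acceptance report carries the
honestly computed values.

## The synthetic cohort generator

The generator states a world and sticks to it. Per sample, a Poisson number
of variants (default mean 54, matching a deep 8-vs-4 cohort; the shallow
preset uses 20 in a 3-vs-3 design); positions fall in the CR vs elsewhere
with probability proportional to span length times a group-specific CR odds
multiplier (default 1.5, the deep-cohort contrast; power checks use 2.5);
substitution classes follow the pooled observed transition spectrum
(A>G 0.24, C>T 0.18, G>A 0.45, T>C 0.13, no transversions).

True HF is 1 with probability `1 - p_heteroplasmic`, otherwise a Beta draw
truncated to [0.01, 0.95). Observed evidence follows the simplest model
that reproduces coverage-dependent detection: depth ~ Poisson(coverage),
alt reads ~ Binomial(depth, HF), strands split Binomial(alt, 1/2), and a
call is emitted only when at least one alt read exists. This is a modelling
choice of this package, not a description of any caller.

**Calibration.** `p_heteroplasmic = 0.52` equals the heteroplasmic share
observed at ultra-deep (~25,000x) coverage, where essentially every true
HF >= 0.01 is detected. The Beta shape (25, 2300), mean HF ~1.1%, places
most heteroplasmic mass just above the 0.01 retention floor — which is what
the shallow-vs-deep detection gap implies: about 80% of the
deep-detectable heteroplasmies must be invisible at ~107x. With these
defaults a shallow run retains ~20% heteroplasmic calls and a deep run
~50%, inside the intended calibration bands. These numbers were derived
from the binomial detection model before freezing, not tuned against test
outcomes.

**Contamination channels** plant filter-rule violations (homopolymer
positions, single-strand support, true HF < 0.01) at 2% each. The truth
ledger records, for every emitted call, the retention verdict expected from
its *observed* evidence, computed at generation time by plain arithmetic
independent of `filter_calls()`. The filter audit then demands exact
agreement: every planted contaminant excluded with its planted reason among
the verdict reasons, and no ledger-clean call excluded. A clean
heteroplasmic variant whose observed HF fluctuates below 0.01 is expected
(and required) to be excluded as `low_hf` by both routes — that is the
correct behaviour of a threshold filter under sampling noise, not a false
exclusion.

**What a green test does not establish.** The generator draws positions
uniformly within compartments (no site-level mutational hotspots, no
haplogroup structure), uses a single Beta HF family (no per-sample HF
correlation), splits strands symmetrically (no systematic strand bias
outside the planted channel), and simulates no NUMTs, no indels beyond the
class label, and no sequencing-error model beyond binomial sampling.
Passing tests establish the *pipeline's* correctness on this stated world,
not biological claims about real cohorts.

**Depth tables** draw autosomal depths as Poisson totals over a sampled
1-Mb segment per autosome (mirroring depth tools that subsample) and the
mitochondrial depth as a Poisson total over the 16,569-bp genome at
coverage x cn/2, so the planted copy number is recoverable as twice the
depth ratio; sex chromosomes are always excluded as a copy-number
confound.

## Numerical and interface choices

* Fisher tie tolerance 1e-7 (relative); enumeration oracle agreement within
  1e-9 on small tables.
* Truncated Beta sampling by inverse-CDF, so the truncation is exact.
* All generators are deterministic under `seed`; derived seeds stay below
  2^31.
* Config and lexicon files use JSON (the environment provides `jsonlite`;
  no YAML parser is assumed).
* VCF output is VCF 4.2 with HF/CI/DP/strand counts in FORMAT; the bundled
  reader targets exactly this dialect and is cross-checked in the test
  suite against Bioconductor's VariantAnnotation parser.

## Known limitations

* CR functional-domain and structure-element coordinates other than the
  documented spans are reconstructions; region statistics depend on the
  atlas supplied.
* The mtDNA prioritisation consumes impact and frequency annotations as
  given; it does not recompute them.
* The concordance module accepts categorical labels only; numeric scores
  must be thresholded upstream.
* `fisher_exact_2x2` enumerates a single 2x2 support and is not a
  general r x c exact test.
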