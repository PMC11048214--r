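# mitovar

Post-variant-calling analysis of human mitochondrial DNA (mtDNA) and
nuclear-encoded mitochondrial-gene variants in case-control cohorts, built
for studies that ask whether disease tissue (e.g. ALS spinal cord)
accumulates variants in specific compartments of the mitochondrial genome —
above all the non-coding control region (CR) — and whether nuclear
mitochondrial genes carry an excess of rare deleterious variants.

The package implements, as tested reusable components:

* **Region atlas** (`load_atlas`, `assign_region`, `is_homopolymer`) — a
  circular 1-based model of the 16,569-bp rCRS with the CR
  (16024–576), genes/rRNAs/tRNAs, hypervariable segments HV1–3, CR
  functional domains (ETAS, CSB, LSP, central domain), single-strand
  secondary-structure elements A–M, and the artifact-prone homopolymeric
  tracts (66–71, 300–316, 513–525, 5892, 3106–3107, 12418–12425,
  16182–16194).
* **Retention filter** (`filter_calls`, `classify_ploidy`, `dedupe_calls`)
  — depth ≥ 5, mapping quality ≥ 25, no homopolymer tract, alt support on
  both strands, heteroplasmy fraction HF ≥ 0.01; HF ∈ [0.95, 1] is
  homoplasmic, HF < 0.95 heteroplasmic.
* **Prioritisation cascades** (`prioritize_nuclear`, `prioritize_mito`,
  `assign_gene_windows`, `gene_burden`) — drop LOW impact, drop
  control-shared sites, keep MAF < 0.01 or unreported, CADD ≥ 10, caller
  PASS; genes matched within ±10 kb windows.
* **Concordance score** (`simplify_label`, `score_variant`, `score_table`)
  — condenses heterogeneous pathogenicity predictors into the five-level
  −2…+2 scale (±2 = at least four unanimous calls, ±1 = up to three, 0 =
  none or conflicting).
* **Enrichment statistics** (`fisher_exact_2x2`, `chi_square`,
  `t_test_from_summary`, `build_tables`, `run_panel`, `render_summary`) —
  two-sided exact test *p* = Σ {P(T) : P(T) ≤ P(observed)} over
  margin-fixed tables; uncorrected Pearson χ² with df = (r−1)(c−1); pooled
  two-tailed Student *t* from (n, mean, SD) summaries.
* **Copy number** (`estimate_cn`, `depth_from_coverage_table`,
  `compare_cn_groups`) — mtDNA-CN = 2 × (mean mtDNA depth / mean autosomal
  depth).
* **Synthetic cohorts** (`cohort_config`, `wes_like_config`,
  `generate_mt_cohort`, `generate_nuclear_cohort`, `generate_depth_table`)
  — a fully seeded generator with a binomial read-evidence model
  (alt ~ Binomial(depth, HF)) that reproduces the coverage-dependent
  detection of low-level heteroplasmy, planted filter-rule violations, and
  a truth ledger sufficient to audit every stage.
* **Pipeline** (`run_pipeline`) and a CLI front-end
  (`inst/cli/mitovar.R`, subcommands `simulate` / `run-all`).

## Worked example

Reproduce a published enrichment statistic from its printed counts — the
deep-cohort CR vs coding-region 2×2 table (74/247 cases, 54/270 controls):

```r
library(mitovar)
ref <- reference_cohorts()
fisher_exact_2x2(ref$wgs$tables$region)$p
#> [1] 0.04822487
```

i.e. *p* = 0.0482: a significant CR excess in cases. Then run the whole
pipeline on a synthetic deep cohort (8 cases vs 4 controls, ~54 variants
per sample, CR odds 1.5, planted copy numbers 450 vs 362):

```r
cfg <- cohort_config(seed = 42)
b <- generate_mt_cohort(cfg)
r <- run_pipeline(b, depths = generate_depth_table(cfg))
head(r$summary, 4)
#>   block        stratum          case       control      p           method
#>  ploidy            Het 214/412 (52%)  97/211 (46%) 0.1757 fisher_exact_2x2
#>  ploidy            Hom 198/412 (48%) 114/211 (54%)
#>  region Control Region  55/412 (13%)   13/211 (6%) 0.0064 fisher_exact_2x2
#>  region  Coding Region 357/412 (87%) 198/211 (94%)
r$cn$test
#> <t_pooled> statistic = 2856.8 df = 10 p = < 2.2e-16
r$manifest$n_retained; r$manifest$n_distinct_sites
#> [1] 623
#> [1] 617
```

Rows read `n/N (%)` with the observation (sample × site) as counting unit:
here the planted CR enrichment surfaces as 13% vs 6% (*p* = 0.0064), about
half the retained calls are heteroplasmic (the deep-coverage regime), and
the planted copy-number difference is recovered essentially exactly
because the simulated depths carry almost no sampling noise.

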