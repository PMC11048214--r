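nv <- function(sample_id = "S1", chrom = "chr1", position = 100L, ref = "A",
               alt = "G", impact = "MODERATE", maf = 0.001, cadd = 20,
               caller_filter = "PASS") {
  data.frame(sample_id = sample_id, chrom = chrom, position = position,
             ref = ref, alt = alt, impact = impact, maf = maf, cadd = cadd,
             caller_filter = caller_filter, stringsAsFactors = FALSE)
}
design64 <- data.frame(
  sample_id = c(paste0("CASE_", 1:8), paste0("CTRL_", 1:4)),
  group = rep(c("case", "control"), c(8, 4)), stringsAsFactors = FALSE)

test_that("gene windows tag by padded span with exact boundaries", {
  w <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                  start = c(20000L, 26000L), end = c(30000L, 45000L))
  v <- rbind(nv(position = 15000L),   # 5,000 bases upstream: tagged
             nv(position = 9999L),    # 10,001 bases upstream: not tagged
             nv(position = 10000L),   # exactly at the padded edge: tagged
             nv(position = 28000L))   # inside both padded windows
  tagged <- assign_gene_windows(v, w)
  expect_equal(tagged$genes[[1]], "G1")
  expect_length(tagged$genes[[2]], 0)
  expect_equal(tagged$genes[[3]], "G1")
  expect_setequal(tagged$genes[[4]], c("G1", "G2"))
  expect_error(assign_gene_windows(nv(chrom = "1"), w), "mismatch.*: 1")
})

test_that("nuclear cascade drops exactly one variant per violated stage", {
  v <- rbind(
    nv(sample_id = "CASE_1", position = 1L, impact = "LOW"),
    nv(sample_id = "CASE_1", position = 2L),          # shared w/ control
    nv(sample_id = "CTRL_1", position = 2L),
    nv(sample_id = "CASE_2", position = 3L, maf = 0.5),
    nv(sample_id = "CASE_2", position = 4L, cadd = 5),
    nv(sample_id = "CASE_3", position = 5L, caller_filter = "VQSR"),
    nv(sample_id = "CASE_3", position = 6L))          # the survivor
  rep <- prioritize_nuclear(v, design64)
  expect_equal(rep$n_observations, 1L)
  expect_equal(rep$retained$position, 6L)
  expect_true(all(diff(rep$attrition$n_after) <= 0))
  expect_equal(rep$attrition$n_before[1], 7L)

  # brute-force oracle: independent re-application of the five predicates
  grp <- design64$group[match(v$sample_id, design64$sample_id)]
  key <- paste(v$chrom, v$position, v$ref, v$alt)
  oracle <- v$impact != "LOW" &
    !(key %in% key[grp == "control"]) &
    (is.na(v$maf) | v$maf < 0.01) &
    (!is.na(v$cadd) & v$cadd >= 10) &
    v$caller_filter == "PASS"
  expect_equal(rep$n_observations, sum(oracle))
})

test_that("missing annotations follow the documented asymmetry", {
  no_maf <- nv(sample_id = "CASE_1", maf = NA)       # private variant: passes
  no_cadd <- nv(sample_id = "CASE_1", cadd = NA)     # unscored: fails
  expect_equal(prioritize_nuclear(no_maf, design64)$n_observations, 1L)
  expect_equal(prioritize_nuclear(no_cadd, design64)$n_observations, 0L)
  expect_equal(prioritize_nuclear(no_cadd, design64,
                                  missing_cadd_passes = TRUE)$n_observations,
               1L)
  expect_error(prioritize_nuclear(nv(sample_id = "GHOST"), design64),
               "missing from design")
})

test_that("final retained set is invariant to stage order", {
  set.seed(31)
  cfg <- cohort_config(seed = 31, mean_variants_per_sample = 40)
  gw <- data.frame(gene = paste0("G", 1:6), chrom = "chr1",
                   start = seq(1e5, 6e5, 1e5), end = seq(1e5, 6e5, 1e5) + 2e4)
  nb <- generate_nuclear_cohort(cfg, gw)
  v <- nb$variants
  grp <- nb$design$group[match(v$sample_id, nb$design$sample_id)]
  key <- paste(v$chrom, v$position, v$ref, v$alt)
  preds <- list(
    function(v) v$impact != "LOW",
    function(v) !(key %in% key[grp == "control"]),
    function(v) is.na(v$maf) | v$maf < 0.01,
    function(v) !is.na(v$cadd) & v$cadd >= 10,
    function(v) v$caller_filter == "PASS")
  ref_keep <- Reduce(`&`, lapply(preds, function(f) f(v)))
  for (ord in list(5:1, c(3, 1, 5, 2, 4), c(2, 4, 1, 5, 3))) {
    keep <- Reduce(`&`, lapply(preds[ord], function(f) f(v)))
    expect_equal(keep, ref_keep)
  }
  rep <- prioritize_nuclear(v, nb$design)
  expect_equal(rep$n_observations, sum(ref_keep))
  expect_equal(rep$n_observations, sum(nb$truth$survivors))
  expect_lte(rep$n_distinct_sites, rep$n_observations)
})

test_that("tightening thresholds never grows the retained set", {
  set.seed(32)
  cfg <- cohort_config(seed = 32, mean_variants_per_sample = 40)
  gw <- data.frame(gene = "G1", chrom = "chr1", start = 1e5, end = 2e5)
  v <- generate_nuclear_cohort(cfg, gw)$variants
  d <- sample_designs <- generate_nuclear_cohort(cfg, gw)$design
  loose <- prioritize_nuclear(v, d, maf_max = 0.05, cadd_min = 5)
  mid <- prioritize_nuclear(v, d)
  tight <- prioritize_nuclear(v, d, maf_max = 0.001, cadd_min = 25)
  expect_gte(loose$n_observations, mid$n_observations)
  expect_gte(mid$n_observations, tight$n_observations)
})

test_that("mtDNA cascade: LOW impact, control-shared and common are dropped", {
  mt <- function(sample_id, position, impact = "MODIFIER", maf = 1e-4, ...) {
    cbind(make_call(sample_id = sample_id, position = position, ...),
          impact = impact, maf = maf, stringsAsFactors = FALSE)
  }
  v <- rbind(mt("CASE_1", 150L, maf = 0.3),             # common homoplasmic
             mt("CASE_1", 152L),                        # rare case-only: kept
             mt("CASE_2", 7028L, impact = "LOW"),
             mt("CASE_2", 200L), mt("CTRL_1", 200L))    # shared rare site
  rep <- prioritize_mito(v, design64)
  expect_equal(rep$retained$position, 152L)
  expect_equal(rep$n_distinct_sites, 1L)
})

test_that("gene burden counts case samples once per gene", {
  mk <- function(sample_id, gene) data.frame(sample_id = sample_id,
                                             gene = gene,
                                             stringsAsFactors = FALSE)
  rep1 <- list(retained = rbind(mk("CASE_1", "SLC25A21"),
                                mk("CASE_1", "SLC25A21"),
                                mk("CASE_1", "SLC25A21")))
  b1 <- gene_burden(rep1, design64)
  expect_equal(b1$n_case_samples, 1L)
  expect_equal(b1$n_case_total, 8L)

  rep7 <- list(retained = do.call(rbind, lapply(1:7, function(i)
    mk(paste0("CASE_", i), "SLC25A21"))))
  expect_equal(gene_burden(rep7, design64)$n_case_samples, 7L)

  expect_equal(nrow(gene_burden(list(retained = mk("x", "y")[0, ]),
                                design64)), 0L)
  # control-sample variants never contribute
  repc <- list(retained = mk("CTRL_1", "OPA1"))
  expect_equal(nrow(gene_burden(repc, design64)), 0L)
})
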