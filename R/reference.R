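#' Reference contingency tables and group summaries (ALS spinal cord)
#'
#' Printed descriptive-statistics counts and group summaries from a
#' case-control study of mtDNA variants in human ALS spinal cord tissue
#' (a 3 vs 3 whole-exome cohort and an 8 vs 4 whole-genome cohort). These are
#' inputs, not results: the package's test panel recomputes every p-value
#' from these counts, which is how the statistical layer is validated without
#' access to the controlled sequencing data.
#'
#' Counts are authoritative; a few printed percentages in the source tables
#' are internally inconsistent with their own counts.
#'
#' @return A list with elements `wes` and `wgs`. Each cohort holds `tables`
#'   (named list of counts matrices, columns `case`/`control`), `summaries`
#'   (named list of per-group `n`/`mean`/`sd` pairs for the variant-burden and
#'   copy-number t-tests), and `design` (group sizes).
#' @export
reference_cohorts <- function() {
  m <- function(labels, case, control) {
    matrix(c(case, control), ncol = 2,
           dimnames = list(labels, c("case", "control")))
  }
  wes <- list(
    design = c(case = 3L, control = 3L),
    tables = list(
      ploidy = m(c("Het", "Hom"), c(17, 34), c(2, 68)),
      region = m(c("Control Region", "Coding Region"), c(18, 33), c(17, 53)),
      cr_sites = m(c("HV1", "HV2", "HV3", "no-HV"),
                   c(6, 9, 1, 2), c(5, 7, 1, 4)),
      cr_domains = m(c("CENTRAL_DOMAIN", "CSB", "ETAS", "LSP"),
                     c(3, 0, 4, 0), c(6, 0, 0, 0)),
      coding_genes = m(c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP6",
                         "MT-CO3", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB"),
                       c(2, 3, 4, 2, 4, 0, 0, 1, 0, 4),
                       c(2, 7, 3, 2, 3, 2, 4, 5, 1, 7)),
      rrna_trna = m(c("12S rRNA", "16S rRNA", "tRNA", "Non-coding nt"),
                    c(9, 1, 3, 0), c(8, 7, 1, 1)),
      substitution = m(c("A>G", "C>T", "G>A", "T>C"),
                       c(21, 6, 4, 20), c(34, 13, 10, 12))
    ),
    summaries = list(
      variant_burden = list(case = list(n = 3, mean = 17.0, sd = 5.92),
                            control = list(n = 3, mean = 20.0, sd = 7.55)),
      mtdna_cn = list(case = list(n = 3, mean = 18.1, sd = 4.5),
                      control = list(n = 3, mean = 26.6, sd = 15.51))
    )
  )
  wgs <- list(
    design = c(case = 8L, control = 4L),
    tables = list(
      ploidy = m(c("Het", "Hom"), c(154, 167), c(178, 146)),
      region = m(c("Control Region", "Coding Region"),
                 c(74, 247), c(54, 270)),
      cr_sites = m(c("HV1", "HV2", "HV3", "no-HV"),
                   c(18, 32, 8, 16), c(17, 23, 6, 8)),
      cr_domains = m(c("CENTRAL_DOMAIN", "CSB", "ETAS", "LSP"),
                     c(16, 1, 5, 7), c(10, 1, 10, 5)),
      coding_genes = m(c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8",
                         "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
                         "MT-ND5", "MT-ND6", "MT-CYB"),
                       c(15, 19, 12, 9, 2, 16, 8, 4, 6, 25, 28, 6, 40),
                       c(14, 27, 21, 6, 1, 19, 11, 7, 8, 29, 33, 9, 26)),
      rrna_trna = m(c("12S rRNA", "16S rRNA", "tRNA", "Non-coding nt"),
                    c(24, 22, 9, 2), c(21, 28, 5, 5)),
      substitution = m(c("A>G", "C>T", "G>A", "T>C"),
                       c(92, 46, 129, 36), c(54, 64, 144, 46)),
      substitution_het = m(c("A>G", "C>T", "G>A", "T>C"),
                           c(8, 21, 105, 5), c(8, 33, 121, 4)),
      substitution_hom = m(c("A>G", "C>T", "G>A", "T>C"),
                           c(84, 25, 24, 31), c(46, 31, 23, 42))
    ),
    summaries = list(
      variant_burden = list(case = list(n = 8, mean = 40.13, sd = 28.75),
                            control = list(n = 4, mean = 81.0, sd = 70.16)),
      mtdna_cn = list(case = list(n = 8, mean = 450.3, sd = 71.85),
                      control = list(n = 4, mean = 362.0, sd = 7.20))
    )
  )
  list(wes = wes, wgs = wgs)
}
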