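# Cohort fixture whose observation counts encode the shallow-cohort (3 vs 3)
# descriptive table: 51 case and 70 control observations with the printed
# ploidy, region, CR-site, per-gene, rRNA/tRNA and substitution strata.
# Positions are drawn deterministically from the atlas pools so the region
# strata are correct by construction.
wes_fixture <- function(atlas) {
  hp <- atlas_positions(atlas, "homopolymer")
  pool <- function(category, label = NULL) {
    setdiff(atlas_positions(atlas, category, label), hp)
  }
  cr <- pool("CR")
  hv1 <- pool("HV", "HV1"); hv2 <- pool("HV", "HV2"); hv3 <- pool("HV", "HV3")
  nohv <- setdiff(cr, c(hv1, hv2, hv3))
  genes10 <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP6", "MT-CO3",
               "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB")
  gpool <- lapply(genes10, function(g) pool("gene", g))
  names(gpool) <- genes10
  r12 <- pool("rRNA", "MT-RNR1"); r16 <- pool("rRNA", "MT-RNR2")
  trna <- pool("tRNA"); ncnt <- pool("non_coding")

  take <- function(pool, n) if (n == 0) integer(0) else pool[seq_len(n)]
  positions_for <- function(hv_n, gene_n, rr_n) {
    c(take(hv1, hv_n[1]), take(hv2, hv_n[2]), take(hv3, hv_n[3]),
      take(nohv, hv_n[4]),
      unlist(lapply(genes10, function(g) take(gpool[[g]], gene_n[g]))),
      take(r12, rr_n[1]), take(r16, rr_n[2]), take(trna, rr_n[3]),
      take(ncnt, rr_n[4]))
  }
  case_gene <- stats::setNames(c(2, 3, 4, 2, 4, 0, 0, 1, 0, 4), genes10)
  ctrl_gene <- stats::setNames(c(2, 7, 3, 2, 3, 2, 4, 5, 1, 7), genes10)
  case_pos <- positions_for(c(6, 9, 1, 2), case_gene, c(9, 1, 3, 0))
  ctrl_pos <- positions_for(c(5, 7, 1, 4), ctrl_gene, c(8, 7, 1, 1))
  stopifnot(length(case_pos) == 51, length(ctrl_pos) == 70)

  subst <- function(n_ag, n_ct, n_ga, n_tc) {
    rbind(matrix(c("A", "G"), n_ag, 2, byrow = TRUE),
          matrix(c("C", "T"), n_ct, 2, byrow = TRUE),
          matrix(c("G", "A"), n_ga, 2, byrow = TRUE),
          matrix(c("T", "C"), n_tc, 2, byrow = TRUE))
  }
  case_ra <- subst(21, 6, 4, 20)
  ctrl_ra <- rbind(subst(34, 13, 10, 12), c("A", "AC"))   # 70th is an indel

  mkcalls <- function(pos, ra, n_het, samples) {
    n <- length(pos)
    data.frame(
      sample_id = rep_len(samples, n), position = pos,
      ref = ra[, 1], alt = ra[, 2],
      variant_class = ifelse(nchar(ra[, 1]) == 1 & nchar(ra[, 2]) == 1,
                             "SNP", "indel"),
      hf = c(rep(0.5, n_het), rep(1, n - n_het)),
      hf_ci_lower = 0, hf_ci_upper = 1, depth = 1000L,
      alt_fwd = 400L, alt_rev = 400L, quality = 40,
      stringsAsFactors = FALSE)
  }
  calls <- rbind(mkcalls(case_pos, case_ra, 17, paste0("ALS_", 1:3)),
                 mkcalls(ctrl_pos, ctrl_ra, 2, paste0("CNTR_", 1:3)))
  design <- data.frame(sample_id = c(paste0("ALS_", 1:3),
                                     paste0("CNTR_", 1:3)),
                       group = rep(c("case", "control"), each = 3),
                       stringsAsFactors = FALSE)
  list(calls = calls, design = design)
}
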