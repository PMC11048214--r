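#' Synthetic cohort configuration
#'
#' Fully specifies a synthetic case-control cohort: mtDNA variant calls with
#' heteroplasmy and strand support, annotated nuclear calls, and per-contig
#' depth tables. The seed fully determines the output. Defaults describe a
#' WGS-like spinal-cord cohort (8 cases vs 4 controls, ~54 variant
#' observations per sample, ultra-deep 25,725x mtDNA coverage); see
#' `wes_like_config()` for the shallow 107x counterpart.
#'
#' The heteroplasmic-fraction prior `het_fraction_beta = c(25, 2300)`
#' (mean HF ~1.1%, truncated to \[0.01, 0.95)) together with
#' `p_heteroplasmic = 0.52` encodes the observation that at ultra-deep
#' coverage about half of retained calls are sub-homoplasmic while shallow
#' ~100x coverage detects only the upper tail of the same distribution; see
#' the package vignette for the calibration.
#'
#' @param seed Integer RNG seed.
#' @param n_cases,n_controls Group sizes.
#' @param mean_variants_per_sample Poisson mean of generated variants.
#' @param cr_enrichment_odds Odds multiplier for a *case* variant landing in
#'   the control region (controls use odds 1). Default 1.5 matches the
#'   observed WGS-scale CR contrast (23% vs 17%).
#' @param het_fraction_beta Beta shape `c(alpha, beta)` of the true HF
#'   distribution, truncated to \[0.01, 0.95).
#' @param p_heteroplasmic Probability a generated variant is sub-homoplasmic
#'   (otherwise true HF = 1).
#' @param transition_probs Named probabilities over
#'   `A>G, C>T, G>A, T>C, transversion` (default: pooled WGS-scale spectrum,
#'   no transversions).
#' @param coverage_depth Mean reads per mtDNA position.
#' @param strand_bias_rate,homopolymer_rate,low_hf_rate Contamination
#'   probabilities for planted filter-rule violations.
#' @param maf_absent_rate Probability a variant has no population-frequency
#'   record.
#' @param true_cn_case,true_cn_control Planted mtDNA copy numbers.
#' @param autosome_coverage Mean autosomal depth for the depth table.
#' @return A validated list of class `mv_cohort_config`.
#' @export
cohort_config <- function(seed = 1L, n_cases = 8L, n_controls = 4L,
                          mean_variants_per_sample = 54,
                          cr_enrichment_odds = 1.5,
                          het_fraction_beta = c(25, 2300),
                          p_heteroplasmic = 0.52,
                          transition_probs = c("A>G" = 0.24, "C>T" = 0.18,
                                               "G>A" = 0.45, "T>C" = 0.13,
                                               "transversion" = 0),
                          coverage_depth = 25725,
                          strand_bias_rate = 0.02, homopolymer_rate = 0.02,
                          low_hf_rate = 0.02, maf_absent_rate = 0.15,
                          true_cn_case = 450, true_cn_control = 362,
                          autosome_coverage = 30) {
  cfg <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              mean_variants_per_sample = mean_variants_per_sample,
              cr_enrichment_odds = cr_enrichment_odds,
              het_fraction_beta = het_fraction_beta,
              p_heteroplasmic = p_heteroplasmic,
              transition_probs = transition_probs,
              coverage_depth = coverage_depth,
              strand_bias_rate = strand_bias_rate,
              homopolymer_rate = homopolymer_rate,
              low_hf_rate = low_hf_rate,
              maf_absent_rate = maf_absent_rate,
              true_cn_case = true_cn_case,
              true_cn_control = true_cn_control,
              autosome_coverage = autosome_coverage)
  probs <- c(cfg$p_heteroplasmic, cfg$strand_bias_rate, cfg$homopolymer_rate,
             cfg$low_hf_rate, cfg$maf_absent_rate, cfg$transition_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$transition_probs) - 1) > 1e-8) {
    stop("transition_probs must sum to 1")
  }
  if (cfg$cr_enrichment_odds <= 0) stop("cr_enrichment_odds must be > 0")
  if (cfg$mean_variants_per_sample <= 0 || cfg$coverage_depth <= 0) {
    stop("mean_variants_per_sample and coverage_depth must be positive")
  }
  if (cfg$n_cases < 1 || cfg$n_controls < 1) stop("need >= 1 sample per group")
  if (length(cfg$het_fraction_beta) != 2 || any(cfg$het_fraction_beta <= 0)) {
    stop("het_fraction_beta must be two positive shapes")
  }
  structure(cfg, class = "mv_cohort_config")
}

#' WES-like configuration (shallow off-target mtDNA coverage)
#'
#' 3 cases vs 3 controls, ~20 variant observations per sample, 107x mtDNA
#' coverage, planted copy numbers near the shallow-cohort estimates. All
#' other parameters inherit [cohort_config()] defaults.
#'
#' @param seed Integer RNG seed.
#' @param ... Overrides forwarded to [cohort_config()].
#' @export
wes_like_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_cases = 3L, n_controls = 3L,
               mean_variants_per_sample = 20, coverage_depth = 107,
               true_cn_case = 18.1, true_cn_control = 26.6)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

rtrunc_beta <- function(n, shape, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, shape[1], shape[2]),
                    stats::pbeta(hi, shape[1], shape[2]))
  stats::qbeta(u, shape[1], shape[2])
}

sample_design <- function(cfg) {
  data.frame(
    sample_id = c(sprintf("CASE_%d", seq_len(cfg$n_cases)),
                  sprintf("CTRL_%d", seq_len(cfg$n_controls))),
    group = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic mtDNA cohort
#'
#' Per sample, draws a Poisson variant count; positions land in the control
#' region vs elsewhere according to atlas span lengths scaled by the
#' group-specific CR odds; each variant gets a substitution class, a true HF
#' (1 with probability `1 - p_heteroplasmic`, otherwise a truncated Beta
#' draw), and observed evidence via a binomial read model: alt reads ~
#' Binomial(depth, HF) with depth ~ Poisson(`coverage_depth`), strands split
#' Binomial(alt, 0.5). A call is emitted only when at least one alt read is
#' observed, which is what makes heteroplasmy detection coverage-dependent.
#' Planted contaminants (homopolymer-tract positions, single-strand support,
#' true HF < 0.01) are recorded in the truth ledger together with the
#' retention-rule verdict expected from the observed evidence, computed here
#' by direct arithmetic, independent of [filter_calls()].
#'
#' @param config An [cohort_config()] object.
#' @param atlas A `mito_atlas` (bundled default if omitted).
#' @return List of class `mv_cohort` with `calls` (emitted call table,
#'   annotated with `impact` and `maf`), `design`, `truth` (per-call planted
#'   state and expected filter reasons, plus generation parameters), and
#'   `config`.
#' @export
generate_mt_cohort <- function(config, atlas = load_atlas()) {
  stopifnot(inherits(config, "mv_cohort_config"))
  set.seed(config$seed)
  design <- sample_design(config)

  hp_pos <- atlas_positions(atlas, "homopolymer")
  cr_pos <- setdiff(atlas_positions(atlas, "CR"), hp_pos)
  noncr_pos <- setdiff(seq_len(atlas$genome_length),
                       c(atlas_positions(atlas, "CR"), hp_pos))
  len_cr <- length(cr_pos); len_non <- length(noncr_pos)

  n_per <- stats::rpois(nrow(design), config$mean_variants_per_sample)
  n <- sum(n_per)
  if (n == 0L) stop("no variants generated; increase mean_variants_per_sample")
  sample_id <- rep(design$sample_id, n_per)
  group <- rep(design$group, n_per)

  planted <- sample(c("clean", "homopolymer", "single_strand", "low_hf"), n,
                    replace = TRUE,
                    prob = c(1 - config$homopolymer_rate -
                               config$strand_bias_rate - config$low_hf_rate,
                             config$homopolymer_rate,
                             config$strand_bias_rate, config$low_hf_rate))

  odds <- ifelse(group == "case", config$cr_enrichment_odds, 1)
  p_cr <- (len_cr * odds) / (len_cr * odds + len_non)
  in_cr <- stats::runif(n) < p_cr
  position <- integer(n)
  hp <- planted == "homopolymer"
  position[hp] <- sample(hp_pos, sum(hp), replace = TRUE)
  position[!hp & in_cr] <- sample(cr_pos, sum(!hp & in_cr), replace = TRUE)
  position[!hp & !in_cr] <- sample(noncr_pos, sum(!hp & !in_cr),
                                   replace = TRUE)

  cls <- sample(names(config$transition_probs), n, replace = TRUE,
                prob = config$transition_probs)
  tv <- cls == "transversion"
  ref <- substr(cls, 1, 1); alt_base <- substr(cls, 3, 3)
  if (any(tv)) {                       # pick a random transversion pair
    tv_ref <- sample(c("A", "C", "G", "T"), sum(tv), replace = TRUE)
    tv_alt <- vapply(tv_ref, function(r) {
      sample(setdiff(switch(r, A = c("C", "T"), G = c("C", "T"),
                            C = c("A", "G"), T = c("A", "G")), r), 1)
    }, character(1))
    ref[tv] <- tv_ref; alt_base[tv] <- tv_alt
  }

  is_het <- stats::runif(n) < config$p_heteroplasmic
  true_hf <- ifelse(is_het,
                    rtrunc_beta(n, config$het_fraction_beta, 0.01, 0.95), 1)
  low <- planted == "low_hf"
  true_hf[low] <- stats::runif(sum(low), 0.002, 0.009)

  depth <- pmax(stats::rpois(n, config$coverage_depth), 1L)
  alt_reads <- stats::rbinom(n, depth, true_hf)
  fwd <- stats::rbinom(n, alt_reads, 0.5)
  ss <- planted == "single_strand"
  fwd[ss] <- ifelse(stats::runif(sum(ss)) < 0.5, alt_reads[ss], 0L)
  rev <- alt_reads - fwd
  hf <- alt_reads / depth
  se <- sqrt(pmax(hf * (1 - hf), 0) / depth)
  quality <- round(stats::runif(n, 35, 45), 1)

  reg <- assign_region(atlas, position)
  pc_genes <- atlas$top$label[atlas$top$category == "gene"]
  in_pc <- !is.na(reg$gene) & reg$gene %in% pc_genes
  impact <- rep("MODIFIER", n)
  impact[in_pc] <- sample(c("LOW", "MODERATE", "HIGH"), sum(in_pc),
                          replace = TRUE, prob = c(0.40, 0.55, 0.05))
  maf <- 10^stats::runif(n, -6, -0.3)
  maf[stats::runif(n) < config$maf_absent_rate] <- NA_real_

  emitted <- alt_reads >= 1L
  calls <- data.frame(
    sample_id = sample_id, position = position, ref = ref, alt = alt_base,
    variant_class = "SNP", hf = hf,
    hf_ci_lower = pmax(hf - 1.96 * se, 0), hf_ci_upper = pmin(hf + 1.96 * se, 1),
    depth = depth, alt_fwd = fwd, alt_rev = rev, quality = quality,
    impact = impact, maf = maf, stringsAsFactors = FALSE)[emitted, ]
  rownames(calls) <- NULL

  # expected retention verdict from the observed evidence, by plain arithmetic
  exp_fail <- cbind(
    low_depth = depth < 5, low_quality = quality < 25,
    homopolymer = position %in% hp_pos,
    single_strand = fwd < 1 | rev < 1, low_hf = hf < 0.01)
  expected_reasons <- apply(exp_fail, 1L,
                            function(r) paste(colnames(exp_fail)[r],
                                              collapse = ","))
  truth <- list(
    calls = data.frame(sample_id = sample_id, position = position, ref = ref,
                       alt = alt_base, group = group, true_hf = true_hf,
                       planted = planted, emitted = emitted,
                       expected_reasons = expected_reasons,
                       stringsAsFactors = FALSE),
    params = list(n_generated = n, p_cr_case = p_cr[match("case", group)],
                  p_cr_control = (len_cr) / (len_cr + len_non)))

  structure(list(calls = calls, design = design, truth = truth,
                 config = config),
            class = "mv_cohort")
}

#' @export
print.mv_cohort <- function(x, ...) {
  cat("<mv_cohort>", nrow(x$calls), "emitted calls across",
      nrow(x$design), "samples (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Generate a synthetic annotated nuclear cohort
#'
#' Places variants inside (or, with probability `1 - in_window_rate`, outside)
#' padded nuclear-mitochondrial gene windows, draws impact class, population
#' frequency (with an absent-record point mass), CADD score, caller filter
#' status, and a panel of categorical pathogenicity-predictor labels. A
#' fraction of variants is drawn from a shared population pool so that
#' control-shared sites exist. The truth ledger records, for every
#' observation, whether it should survive the prioritisation cascade —
#' computed by direct arithmetic, independent of [prioritize_nuclear()].
#'
#' @param config An [cohort_config()] object.
#' @param gene_windows Data frame `gene`, `chrom`, `start`, `end`.
#' @param pad Window padding (bases).
#' @param in_window_rate Probability a variant falls inside a padded window.
#' @param shared_rate Probability a variant is drawn from the shared
#'   population pool (recurring sites).
#' @return List with `variants`, `design`, `truth`, `config`.
#' @export
generate_nuclear_cohort <- function(config, gene_windows, pad = 10000,
                                    in_window_rate = 0.8, shared_rate = 0.25) {
  stopifnot(inherits(config, "mv_cohort_config"))
  set.seed(config$seed + 1L)
  design <- sample_design(config)
  gw <- gene_windows
  n_per <- stats::rpois(nrow(design), config$mean_variants_per_sample)
  n <- sum(n_per)
  if (n == 0L) stop("no variants generated")

  draw_annot <- function(k) {
    lex <- predictor_lexicons()
    latent <- sample(c("D", "B", "none"), k, replace = TRUE,
                     prob = c(0.3, 0.3, 0.4))
    panel <- replicate(6, {
      lab <- character(k)
      noisy <- stats::runif(k) < 0.2
      lab[latent == "D"] <- sample(lex$deleterious, sum(latent == "D"), TRUE)
      lab[latent == "B"] <- sample(lex$benign, sum(latent == "B"), TRUE)
      lab[latent == "none" | noisy] <- sample(c("unknown", "", "VUS"),
                                              sum(latent == "none" | noisy),
                                              TRUE)
      lab
    })
    inw <- stats::runif(k) < in_window_rate
    idx <- sample(nrow(gw), k, replace = TRUE)
    span_lo <- pmax(gw$start[idx] - pad, 1)
    span_hi <- gw$end[idx] + pad
    pos <- integer(k)
    pos[inw] <- floor(stats::runif(sum(inw), span_lo[inw], span_hi[inw] + 1))
    pos[!inw] <- span_hi[!inw] + floor(stats::runif(sum(!inw), pad + 1, 1e6))
    ra <- matrix(replicate(k, sample(c("A", "C", "G", "T"), 2)), nrow = 2)
    data.frame(chrom = gw$chrom[idx], position = pos,
               ref = ra[1, ], alt = ra[2, ],
               impact = sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), k,
                               TRUE, prob = c(0.05, 0.25, 0.40, 0.30)),
               maf = ifelse(stats::runif(k) < config$maf_absent_rate,
                            NA_real_, 10^stats::runif(k, -6, -0.3)),
               cadd = ifelse(stats::runif(k) < 0.05, NA_real_,
                             stats::runif(k, 0, 40)),
               caller_filter = sample(c("PASS", "VQSRTranche"), k, TRUE,
                                      prob = c(0.9, 0.1)),
               predictor_1 = panel[, 1], predictor_2 = panel[, 2],
               predictor_3 = panel[, 3], predictor_4 = panel[, 4],
               predictor_5 = panel[, 5], predictor_6 = panel[, 6],
               stringsAsFactors = FALSE)
  }

  pool <- draw_annot(max(5L, ceiling(config$mean_variants_per_sample / 3)))
  fresh <- draw_annot(n)
  from_pool <- stats::runif(n) < shared_rate
  pick <- sample(nrow(pool), n, replace = TRUE)
  variants <- fresh
  variants[from_pool, ] <- pool[pick[from_pool], ]
  variants <- cbind(sample_id = rep(design$sample_id, n_per), variants,
                    stringsAsFactors = FALSE)
  rownames(variants) <- NULL

  # expected cascade survivors, by plain arithmetic
  grp <- rep(design$group, n_per)
  key <- paste(variants$chrom, variants$position, variants$ref, variants$alt,
               sep = "\r")
  in_control <- key %in% unique(key[grp == "control"])
  survive <- variants$impact != "LOW" & !in_control &
    (is.na(variants$maf) | variants$maf < 0.01) &
    (!is.na(variants$cadd) & variants$cadd >= 10) &
    variants$caller_filter == "PASS"

  truth <- list(survivors = survive, group = grp)
  list(variants = variants, design = design, truth = truth, config = config)
}

# approximate per-autosome sampled segment length used for the depth table;
# mirrors depth tools that estimate autosomal coverage on a sampled subset
.autosome_segment <- 1e6

#' Generate a synthetic per-contig depth table
#'
#' Autosomal mean depths are Poisson draws around `autosome_coverage` over a
#' sampled 1-Mb segment per autosome; the mitochondrial contig's depth is a
#' Poisson draw around `autosome_coverage * cn / 2` over the 16,569-bp
#' genome, so the planted copy number is recoverable as twice the depth
#' ratio.
#'
#' @param config An [cohort_config()] object.
#' @param mito_name Mitochondrial contig name.
#' @return List with `coverage` (sample_id, contig, length, mean_depth),
#'   `truth` (sample_id, true_cn), and `design`.
#' @export
generate_depth_table <- function(config, mito_name = "chrM") {
  stopifnot(inherits(config, "mv_cohort_config"))
  set.seed(config$seed + 2L)
  design <- sample_design(config)
  cov <- config$autosome_coverage
  out <- lapply(seq_len(nrow(design)), function(i) {
    cn <- if (design$group[i] == "case") config$true_cn_case
          else config$true_cn_control
    auto <- data.frame(
      sample_id = design$sample_id[i], contig = paste0("chr", 1:22),
      length = .autosome_segment,
      mean_depth = stats::rpois(22, cov * .autosome_segment) /
        .autosome_segment,
      stringsAsFactors = FALSE)
    mt <- data.frame(sample_id = design$sample_id[i], contig = mito_name,
                     length = 16569,
                     mean_depth = stats::rpois(1, cov * cn / 2 * 16569) / 16569,
                     stringsAsFactors = FALSE)
    rbind(auto, mt)
  })
  truth <- data.frame(
    sample_id = design$sample_id,
    true_cn = ifelse(design$group == "case", config$true_cn_case,
                     config$true_cn_control),
    stringsAsFactors = FALSE)
  list(coverage = do.call(rbind, out), truth = truth, design = design)
}
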