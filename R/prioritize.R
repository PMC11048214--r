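#' Tag variants with padded gene windows
#'
#' A variant is tagged with every gene whose padded span
#' `[start - pad, end + pad]` (floored at 1) contains its position; windows
#' may overlap and a variant may carry several genes. The default 10-kb pad
#' matches the convention of counting variants within 10 kbp upstream and
#' downstream of nuclear-encoded mitochondrial genes.
#'
#' @param variants Data frame with columns `chrom` and `position` (1-based).
#' @param windows Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @param pad Window padding in bases (default 10,000).
#' @return `variants` with a list-column `genes` (character(0) when no window
#'   contains the variant).
#' @export
assign_gene_windows <- function(variants, windows, pad = 10000) {
  bad <- setdiff(unique(variants$chrom), unique(windows$chrom))
  if (length(bad)) {
    stop("chromosome naming mismatch; variant chroms absent from windows: ",
         paste(bad, collapse = ", "))
  }
  ws <- pmax(windows$start - pad, 1)
  we <- windows$end + pad
  genes <- lapply(seq_len(nrow(variants)), function(i) {
    hit <- windows$chrom == variants$chrom[i] &
      ws <= variants$position[i] & we >= variants$position[i]
    windows$gene[hit]
  })
  variants$genes <- genes
  variants
}

site_key <- function(v) paste(if (!is.null(v$chrom)) v$chrom else "chrM",
                              v$position, v$ref, v$alt, sep = "\r")

check_design <- function(variants, design) {
  grp <- design$group[match(variants$sample_id, design$sample_id)]
  if (any(is.na(grp))) {
    stop("samples missing from design: ",
         paste(unique(variants$sample_id[is.na(grp)]), collapse = ", "))
  }
  grp
}

run_cascade <- function(variants, design, stages) {
  grp <- check_design(variants, design)
  attrition <- data.frame(stage = names(stages),
                          n_before = NA_integer_, n_after = NA_integer_)
  keep <- rep(TRUE, nrow(variants))
  for (i in seq_along(stages)) {
    attrition$n_before[i] <- sum(keep)
    keep <- keep & stages[[i]](variants, grp)
    attrition$n_after[i] <- sum(keep)
  }
  retained <- variants[keep, , drop = FALSE]
  rownames(retained) <- NULL
  counts <- count_sites_and_observations(retained)
  structure(list(retained = retained,
                 n_observations = counts$n_observations,
                 n_distinct_sites = counts$n_distinct_sites,
                 attrition = attrition),
            class = "mv_prioritization")
}

#' @export
print.mv_prioritization <- function(x, ...) {
  cat("<mv_prioritization>", x$n_observations, "observations at",
      x$n_distinct_sites, "distinct sites retained\n")
  print(x$attrition)
  invisible(x)
}

# stage predicates shared by both cascades
stage_not_low <- function(v, grp) v$impact != "LOW"
stage_case_only <- function(v, grp) {
  control_sites <- unique(site_key(v)[grp == "control"])
  !(site_key(v) %in% control_sites)
}
stage_rare <- function(maf_max) {
  function(v, grp) is.na(v$maf) | v$maf < maf_max
}

#' Rare-variant prioritisation cascade for nuclear variants
#'
#' Applies, in order: (1) drop LOW-impact variants; (2) drop any site
#' (chrom, position, ref, alt) observed in at least one control sample;
#' (3) keep variants rarer than `maf_max` in the population, or with no
#' recorded frequency (private variants pass); (4) keep CADD deleteriousness
#' scores of at least `cadd_min` (missing CADD fails by default — rarity
#' without evidence of deleteriousness is not certified); (5) keep calls with
#' a PASS caller filter. The five predicates commute, so the retained set is
#' order-independent; the per-stage attrition counts are not.
#'
#' @param variants Data frame with columns `sample_id`, `chrom`, `position`,
#'   `ref`, `alt`, `impact` (`HIGH`/`MODERATE`/`LOW`/`MODIFIER`), `maf`
#'   (`NA` = unreported), `cadd` (`NA` = unscored), `caller_filter`.
#' @param design Data frame with `sample_id`, `group` labelling every sample.
#' @param maf_max Population-frequency rarity cutoff (exclusive).
#' @param cadd_min Minimum phred-scaled CADD score (inclusive).
#' @param missing_cadd_passes Set `TRUE` to let unscored variants through
#'   stage 4.
#' @return An `mv_prioritization` with the retained observations,
#'   observation/distinct-site counts and per-stage attrition.
#' @export
prioritize_nuclear <- function(variants, design, maf_max = 0.01,
                               cadd_min = 10, missing_cadd_passes = FALSE) {
  stages <- list(
    drop_low_impact = stage_not_low,
    drop_control_shared = stage_case_only,
    rare = stage_rare(maf_max),
    deleterious = function(v, grp) {
      if (missing_cadd_passes) is.na(v$cadd) | v$cadd >= cadd_min
      else !is.na(v$cadd) & v$cadd >= cadd_min
    },
    caller_pass = function(v, grp) v$caller_filter == "PASS"
  )
  run_cascade(variants, design, stages)
}

#' Rare-variant prioritisation cascade for mtDNA variants
#'
#' The mtDNA cascade mirrors the nuclear one without the CADD and caller-PASS
#' stages: drop LOW impact, drop control-shared sites, keep rare or
#' never-reported variants.
#'
#' @inheritParams prioritize_nuclear
#' @export
prioritize_mito <- function(variants, design, maf_max = 0.01) {
  stages <- list(
    drop_low_impact = stage_not_low,
    drop_control_shared = stage_case_only,
    rare = stage_rare(maf_max)
  )
  run_cascade(variants, design, stages)
}

#' Per-gene burden among case samples
#'
#' For each gene, counts the case samples carrying at least one retained
#' prioritised variant in (or within the padded window of) that gene; a
#' sample counts once per gene regardless of how many variants it carries.
#'
#' @param report An `mv_prioritization`. Retained variants must carry either
#'   a `genes` list-column (nuclear, from [assign_gene_windows()]) or a
#'   `gene` column (mtDNA).
#' @param design Data frame with `sample_id`, `group`.
#' @return Data frame `gene`, `n_case_samples`, `n_case_total`, sorted by
#'   decreasing burden.
#' @export
gene_burden <- function(report, design) {
  v <- report$retained
  n_case_total <- sum(design$group == "case")
  empty <- data.frame(gene = character(0), n_case_samples = integer(0),
                      n_case_total = integer(0))
  if (nrow(v) == 0L) return(empty)
  grp <- check_design(v, design)
  v <- v[grp == "case", , drop = FALSE]
  if (nrow(v) == 0L) return(empty)
  if (!is.null(v$genes)) {
    long <- data.frame(
      sample_id = rep(v$sample_id, lengths(v$genes)),
      gene = unlist(v$genes), stringsAsFactors = FALSE)
  } else if (!is.null(v$gene)) {
    long <- data.frame(sample_id = v$sample_id, gene = v$gene,
                       stringsAsFactors = FALSE)
    long <- long[!is.na(long$gene), ]
  } else {
    stop("retained variants carry neither 'genes' nor 'gene'")
  }
  if (nrow(long) == 0L) return(empty)
  long <- unique(long)
  agg <- stats::aggregate(sample_id ~ gene, long, length)
  out <- data.frame(gene = agg$gene, n_case_samples = agg$sample_id,
                    n_case_total = n_case_total, stringsAsFactors = FALSE)
  out[order(-out$n_case_samples, out$gene), , drop = FALSE]
}
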