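#' Mitochondrial DNA copy number from depth ratio
#'
#' The per-cell mtDNA copy number is estimated as twice the ratio of mean
#' mitochondrial to mean autosomal sequencing depth: a diploid cell carries
#' two autosomal genome copies, so depth parity (mt = autosomal) corresponds
#' to two mtDNA copies.
#'
#' @param depths Data frame with columns `sample_id`, `mt_mean_depth`,
#'   `auto_mean_depth`.
#' @return Data frame `sample_id`, `cn`.
#' @examples
#' estimate_cn(data.frame(sample_id = "s1", mt_mean_depth = 6750,
#'                        auto_mean_depth = 30))
#' @export
estimate_cn <- function(depths) {
  if (any(depths$auto_mean_depth <= 0)) {
    stop("auto_mean_depth must be positive")
  }
  if (any(depths$mt_mean_depth < 0)) stop("mt_mean_depth must be >= 0")
  if (any(depths$mt_mean_depth == 0)) {
    warning("mt_mean_depth of 0: copy number estimated as 0")
  }
  data.frame(sample_id = depths$sample_id,
             cn = 2 * depths$mt_mean_depth / depths$auto_mean_depth,
             stringsAsFactors = FALSE)
}

#' Collapse a per-contig coverage table to depth summaries
#'
#' Computes the length-weighted mean autosomal depth over a configurable
#' autosome set (all 22 autosomes by default; sex chromosomes are always
#' excluded as a copy-number confound) and pairs it with the mitochondrial
#' contig's mean depth.
#'
#' @param coverage Data frame with columns `sample_id`, `contig`, `length`,
#'   `mean_depth`.
#' @param mito_name Mitochondrial contig name (`"chrM"` or `"MT"`).
#' @param autosomes Autosomal contig names to include.
#' @return Data frame `sample_id`, `mt_mean_depth`, `auto_mean_depth`.
#' @export
depth_from_coverage_table <- function(coverage, mito_name = "chrM",
                                      autosomes = paste0("chr", 1:22)) {
  out <- lapply(split(coverage, coverage$sample_id), function(cv) {
    mt <- cv[cv$contig == mito_name, ]
    if (nrow(mt) != 1L) {
      stop("coverage table lacks mitochondrial contig '", mito_name,
           "' for sample ", cv$sample_id[1])
    }
    au <- cv[cv$contig %in% autosomes, ]
    if (nrow(au) == 0L) stop("no autosomal contigs in coverage table")
    data.frame(sample_id = cv$sample_id[1],
               mt_mean_depth = mt$mean_depth,
               auto_mean_depth = sum(au$mean_depth * au$length) /
                 sum(au$length),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare copy-number estimates between groups
#'
#' Summarises per-group estimates as (n, mean, sample SD) and delegates to
#' the pooled two-tailed t-test.
#'
#' @param estimates Data frame `sample_id`, `cn` from [estimate_cn()].
#' @param design Data frame `sample_id`, `group` (`"case"`/`"control"`).
#' @return List with `summary` (per-group n/mean/sd) and `test`
#'   (`mv_test_result`).
#' @export
compare_cn_groups <- function(estimates, design) {
  grp <- design$group[match(estimates$sample_id, design$sample_id)]
  if (any(is.na(grp))) stop("samples missing from design")
  summ <- lapply(split(estimates$cn, grp), function(x) {
    if (length(x) < 2L) stop("each group needs at least 2 samples")
    list(n = length(x), mean = mean(x), sd = stats::sd(x))
  })
  list(summary = summ,
       test = t_test_from_summary(summ$case, summ$control))
}
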