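#' Run the full mtDNA case-control pipeline on a cohort bundle
#'
#' Orchestrates the stages end to end on an in-memory synthetic cohort (or a
#' cohort read from disk): retention filtering, deduplication, ploidy
#' classification, region assignment, contingency-table construction, the
#' enrichment test panel, mtDNA prioritisation, and copy-number comparison.
#' When `out_dir` is given, writes the summary TSV, a JSON of test results,
#' the prioritised-variant TSV, and a machine-readable run manifest
#' (package version, thresholds, input digests) so that re-runs on identical
#' inputs are verifiably identical.
#'
#' @param cohort An `mv_cohort` from [generate_mt_cohort()], or a list with
#'   elements `calls` and `design`.
#' @param depths Optional depth bundle from [generate_depth_table()] (or a
#'   list with `coverage`).
#' @param atlas A `mito_atlas`.
#' @param thresholds An [mt_thresholds()] object.
#' @param maf_max Rarity cutoff for mtDNA prioritisation.
#' @param out_dir Optional output directory for report artifacts.
#' @return List with `filtered` (all calls + verdicts), `retained`, `tables`,
#'   `results`, `summary` (rendered table), `prioritized`, `burden`, `cn`
#'   (estimates and group test, when `depths` given), and `manifest`.
#' @export
run_pipeline <- function(cohort, depths = NULL, atlas = load_atlas(),
                         thresholds = mt_thresholds(), maf_max = 0.01,
                         out_dir = NULL) {
  if (is.null(cohort$design)) stop("stage 'design': cohort lacks a design table")
  if (is.null(cohort$calls)) stop("stage 'input': cohort lacks a call table")
  filtered <- filter_calls(dedupe_calls(cohort$calls), atlas, thresholds)
  retained <- filtered[filtered$retained, , drop = FALSE]
  tables <- build_tables(retained, cohort$design, atlas,
                         hom_threshold = thresholds$hom_threshold)
  results <- run_panel(tables)
  summary <- render_summary(tables, results)

  prioritized <- NULL
  burden <- NULL
  if (!is.null(retained$impact)) {
    pr_in <- retained
    pr_in$gene <- assign_region(atlas, pr_in$position)$gene
    prioritized <- prioritize_mito(pr_in, cohort$design, maf_max = maf_max)
    burden <- gene_burden(prioritized, cohort$design)
  }

  cn <- NULL
  if (!is.null(depths)) {
    est <- estimate_cn(depth_from_coverage_table(depths$coverage))
    cmp <- compare_cn_groups(est, cohort$design)
    cn <- list(estimates = est, summary = cmp$summary, test = cmp$test)
  }

  counts <- count_sites_and_observations(retained)
  manifest <- list(
    package = as.character(utils::packageVersion("mitovar")),
    thresholds = unclass(thresholds), maf_max = maf_max,
    n_input_calls = nrow(cohort$calls),
    n_retained = counts$n_observations,
    n_distinct_sites = counts$n_distinct_sites)

  out <- list(filtered = filtered, retained = retained, tables = tables,
              results = results, summary = summary,
              prioritized = prioritized, burden = burden, cn = cn,
              manifest = manifest)
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res <- lapply(report$results, function(r) {
    list(method = r$method,
         statistic = if (is.na(r$statistic)) NULL else r$statistic,
         df = if (is.na(r$df)) NULL else r$df, p = r$p, note = r$note)
  })
  jsonlite::write_json(res, file.path(out_dir, "test_results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$prioritized)) {
    utils::write.table(report$prioritized$retained,
                       file.path(out_dir, "prioritized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$cn)) {
    utils::write.table(report$cn$estimates, file.path(out_dir, "mtdna_cn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  man <- report$manifest
  art <- list.files(out_dir, full.names = TRUE)
  art <- art[basename(art) != "manifest.json"]
  man$artifact_md5 <- as.list(tools::md5sum(art))
  names(man$artifact_md5) <- basename(art)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
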