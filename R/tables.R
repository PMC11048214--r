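#' Build the stratified case-control contingency tables
#'
#' Constructs the descriptive-statistics table blocks used for mtDNA
#' enrichment testing: ploidy class, control-region vs coding distribution,
#' CR hypervariable sites, CR functional domains, per-gene coding counts,
#' rRNA/tRNA/non-coding counts, and the substitution spectrum (overall, and
#' split by ploidy). The counting unit is the variant observation (one sample
#' carrying one site), so column sums match per-group retained counts.
#'
#' @param calls Data frame of retained, deduplicated mtDNA calls with columns
#'   `sample_id`, `position`, `ref`, `alt`, `variant_class` (`"SNP"` or
#'   `"indel"`) and `hf`.
#' @param design Data frame with columns `sample_id` and `group`
#'   (`"case"`/`"control"`); every sample in `calls` must be labelled.
#' @param atlas A `mito_atlas`.
#' @param hom_threshold Homoplasmy boundary passed to [classify_ploidy()].
#' @return Named list of `mv_table` objects (`ploidy`, `region`, `cr_sites`,
#'   `cr_domains`, `coding_genes`, `rrna_trna`, `substitution`,
#'   `substitution_het`, `substitution_hom`), each holding a counts matrix
#'   with rows = strata and columns = `case`, `control`.
#' @export
build_tables <- function(calls, design, atlas, hom_threshold = 0.95) {
  grp <- design$group[match(calls$sample_id, design$sample_id)]
  if (any(is.na(grp))) {
    stop("samples missing from design: ",
         paste(unique(calls$sample_id[is.na(grp)]), collapse = ", "))
  }
  if (!all(grp %in% c("case", "control"))) {
    stop("design group must be 'case' or 'control'")
  }
  grp <- factor(grp, levels = c("case", "control"))
  reg <- assign_region(atlas, calls$position)
  ploidy <- classify_ploidy(calls$hf, hom_threshold)
  is_snv <- if ("variant_class" %in% names(calls)) {
    calls$variant_class == "SNP"
  } else nchar(calls$ref) == 1L & nchar(calls$alt) == 1L

  tab <- function(rows, labels, mask = rep(TRUE, length(grp))) {
    rows <- factor(rows[mask], levels = labels)
    m <- table(rows, grp[mask])
    m <- matrix(as.integer(m), nrow = length(labels),
                dimnames = list(labels, c("case", "control")))
    m
  }
  mk <- function(name, counts) {
    structure(list(name = name, counts = counts), class = "mv_table")
  }

  out <- list()
  out$ploidy <- mk("ploidy", tab(ifelse(ploidy == "heteroplasmic",
                                        "Het", "Hom"), c("Het", "Hom")))
  in_cr <- reg$top_level == "CR"
  out$region <- mk("region", tab(ifelse(in_cr, "Control Region",
                                        "Coding Region"),
                                 c("Control Region", "Coding Region")))
  out$cr_sites <- mk("cr_sites",
                     tab(reg$hv, c("HV1", "HV2", "HV3", "no-HV"), in_cr))
  dom_levels <- c("CENTRAL_DOMAIN", "CSB", "ETAS", "LSP")
  out$cr_domains <- mk("cr_domains",
                       tab(reg$functional_domain, dom_levels,
                           in_cr & reg$functional_domain %in% dom_levels))
  pc <- atlas$top$label[atlas$top$category == "gene"]    # genomic order
  is_pc <- !is.na(reg$gene) & reg$gene %in% pc
  seen <- pc[pc %in% reg$gene[is_pc]]
  out$coding_genes <- mk("coding_genes", tab(reg$gene, seen, is_pc))
  rt <- rep(NA_character_, nrow(calls))
  rt[!in_cr & !is_pc] <- "Non-coding nt"
  rt[!is.na(reg$gene) & reg$gene == "MT-RNR1"] <- "12S rRNA"
  rt[!is.na(reg$gene) & reg$gene == "MT-RNR2"] <- "16S rRNA"
  trna <- !is.na(reg$gene) &
    reg$gene %in% atlas$top$label[atlas$top$category == "tRNA"]
  rt[trna] <- "tRNA"
  out$rrna_trna <- mk("rrna_trna",
                      tab(rt, c("12S rRNA", "16S rRNA", "tRNA",
                                "Non-coding nt"), !in_cr & !is_pc))

  spec_tab <- function(mask, name) {
    cls <- rep(NA_character_, nrow(calls))
    cls[mask] <- classify_substitution(calls$ref[mask], calls$alt[mask])
    m <- tab(cls, c("A>G", "C>T", "G>A", "T>C"),
             mask & cls %in% c("A>G", "C>T", "G>A", "T>C"))
    res <- mk(name, m)
    res$transversions <- tab(cls, "transversion",
                             mask & !is.na(cls) & cls == "transversion")
    res
  }
  out$substitution <- spec_tab(is_snv, "substitution")
  out$substitution_het <- spec_tab(is_snv & ploidy == "heteroplasmic",
                                   "substitution_het")
  out$substitution_hom <- spec_tab(is_snv & ploidy == "homoplasmic",
                                   "substitution_hom")
  out
}

#' @export
print.mv_table <- function(x, ...) {
  cat("<mv_table>", x$name, "\n")
  print(x$counts)
  invisible(x)
}

#' Run the test panel over built tables
#'
#' Applies the table-shape convention of the descriptive panels: 2-row tables
#' are tested with the Fisher exact test, tables with 3 or more rows with the
#' uncorrected chi-square test (all-zero rows are pruned first, with a note).
#' Tables that are untestable after pruning (fewer than two non-empty rows or
#' an empty group column) are skipped with a note.
#'
#' @param tables Named list of `mv_table` objects from [build_tables()], or
#'   plain counts matrices.
#' @return Named list of `mv_test_result` objects (skipped tables carry
#'   `method = "skipped"` and `p = NA`).
#' @export
run_panel <- function(tables) {
  lapply(tables, function(tb) {
    m <- if (inherits(tb, "mv_table")) tb$counts else as.matrix(tb)
    keep <- rowSums(m) > 0
    pruned <- m[keep, , drop = FALSE]
    note <- if (!all(keep)) {
      paste("pruned empty strata:", paste(rownames(m)[!keep], collapse = ", "))
    }
    if (nrow(pruned) < 2L || any(colSums(pruned) == 0)) {
      return(test_result("skipped", NA, NA, NA_real_,
                         note = paste(c(note, "untestable table"),
                                      collapse = "; ")))
    }
    if (nrow(m) == 2L) {
      res <- fisher_exact_2x2(m)
    } else {
      res <- suppressWarnings(chi_square(pruned))
      res$note <- paste(c(note, res$note), collapse = "; ")
      if (res$note == "") res$note <- NULL
    }
    res
  })
}

#' Format the enrichment panel as a descriptive summary table
#'
#' Rows are rendered as `n/N (%)` with whole-number percentages recomputed
#' from counts (never trusted from input); each block's first row carries its
#' p-value (4 decimals, or `<0.0001`) and test method. Empty strata render as
#' `0/0 (-)`.
#'
#' @param tables Named list from [build_tables()].
#' @param results Named list from [run_panel()] (optional).
#' @return Data frame with columns `block`, `stratum`, `case`, `control`,
#'   `p`, `method`.
#' @export
render_summary <- function(tables, results = NULL) {
  fmt_cell <- function(n, N) {
    if (N == 0) return("0/0 (-)")
    sprintf("%d/%d (%d%%)", n, N, round(100 * n / N))
  }
  fmt_p <- function(p) {
    if (is.null(p) || is.na(p)) return("")
    if (p < 1e-4) "<0.0001" else sprintf("%.4f", p)
  }
  blocks <- lapply(names(tables), function(nm) {
    m <- tables[[nm]]$counts
    N <- colSums(m)
    res <- results[[nm]]
    data.frame(
      block = nm, stratum = rownames(m),
      case = vapply(seq_len(nrow(m)), function(i) fmt_cell(m[i, 1], N[1]), ""),
      control = vapply(seq_len(nrow(m)), function(i) fmt_cell(m[i, 2], N[2]), ""),
      p = c(if (is.null(res)) "" else fmt_p(res$p),
            rep("", nrow(m) - 1L)),
      method = c(if (is.null(res)) "" else res$method, rep("", nrow(m) - 1L)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
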