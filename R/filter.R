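#' mtDNA variant retention thresholds
#'
#' Bundles the rule parameters of the retention filter. Defaults follow the
#' published post-calling conventions: sites must be covered by at least 5
#' independent reads, have an aggregate mapping quality of at least 25, lie
#' outside homopolymeric tracts, be supported by at least one read on each
#' strand, and carry a heteroplasmy fraction (HF) of at least 0.01. Variants
#' with HF in \[0.95, 1\] are classified homoplasmic.
#'
#' @param min_depth Minimum read depth at the site (`depth >= min_depth`).
#' @param min_quality Minimum aggregate mapping quality retained.
#' @param min_hf Minimum heteroplasmy fraction retained.
#' @param hom_threshold HF at or above which a call is homoplasmic.
#' @param min_strand_reads Minimum alt-supporting reads required on *each*
#'   strand.
#' @return A named list of class `mt_thresholds`.
#' @export
mt_thresholds <- function(min_depth = 5, min_quality = 25, min_hf = 0.01,
                          hom_threshold = 0.95, min_strand_reads = 1) {
  stopifnot(min_depth >= 0, min_quality >= 0, min_hf >= 0, min_hf <= 1,
            hom_threshold > 0, hom_threshold <= 1, min_strand_reads >= 0)
  structure(list(min_depth = min_depth, min_quality = min_quality,
                 min_hf = min_hf, hom_threshold = hom_threshold,
                 min_strand_reads = min_strand_reads),
            class = "mt_thresholds")
}

#' Apply the mtDNA retention rules
#'
#' Evaluates every rule on every call and reports all failing reasons, in the
#' fixed order `low_depth`, `low_quality`, `homopolymer`, `single_strand`,
#' `low_hf`. The verdict is total: no call errors out.
#'
#' @param calls Data frame of mtDNA calls with columns `sample_id`,
#'   `position`, `ref`, `alt`, `hf`, `depth`, `alt_fwd`, `alt_rev`, `quality`.
#' @param atlas A `mito_atlas` used for homopolymer lookup.
#' @param thresholds An [mt_thresholds()] object.
#' @return `calls` with added columns `retained` (logical) and `reasons`
#'   (comma-separated failed rules, `""` when retained).
#' @export
filter_calls <- function(calls, atlas, thresholds = mt_thresholds()) {
  stopifnot(inherits(thresholds, "mt_thresholds"))
  need <- c("sample_id", "position", "hf", "depth", "alt_fwd", "alt_rev",
            "quality")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("calls lack columns: ", paste(miss, collapse = ", "))
  n <- nrow(calls)
  fail <- cbind(
    low_depth = calls$depth < thresholds$min_depth,
    low_quality = calls$quality < thresholds$min_quality,
    homopolymer = if (n) is_homopolymer(atlas, calls$position) else logical(0),
    single_strand = calls$alt_fwd < thresholds$min_strand_reads |
      calls$alt_rev < thresholds$min_strand_reads,
    low_hf = calls$hf < thresholds$min_hf
  )
  if (n == 0L) {
    calls$retained <- logical(0)
    calls$reasons <- character(0)
    return(calls)
  }
  reasons <- apply(fail, 1L, function(r) paste(colnames(fail)[r], collapse = ","))
  calls$retained <- !apply(fail, 1L, any)
  calls$reasons <- reasons
  calls
}

#' Classify heteroplasmy fraction into ploidy class
#'
#' A variant present in essentially all mtDNA copies (HF in
#' \[`hom_threshold`, 1\]) is homoplasmic; anything below the threshold is
#' heteroplasmic.
#'
#' @param hf Numeric vector of heteroplasmy fractions in \[0, 1\].
#' @param hom_threshold Homoplasmy boundary (default 0.95, closed).
#' @return Character vector, `"homoplasmic"` or `"heteroplasmic"`.
#' @export
classify_ploidy <- function(hf, hom_threshold = 0.95) {
  if (any(is.na(hf)) || any(hf < 0) || any(hf > 1)) {
    stop("hf must lie in [0, 1]")
  }
  ifelse(hf >= hom_threshold, "homoplasmic", "heteroplasmic")
}

#' Drop duplicated mtDNA calls and normalise ordering
#'
#' One record is kept per (sample, position, ref, alt) key. Exact duplicates
#' keep the first-seen record; records with conflicting HF for the same key
#' keep the maximum-HF record (conservative toward detection) and a warning is
#' emitted. Output is sorted by sample then position.
#'
#' @param calls Data frame of mtDNA calls (see [filter_calls()]).
#' @return Deduplicated, sorted data frame.
#' @export
dedupe_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  key <- paste(calls$sample_id, calls$position, calls$ref, calls$alt,
               sep = "\r")
  conflicting <- vapply(split(calls$hf, key),
                        function(h) length(unique(h)) > 1L, logical(1))
  if (any(conflicting)) {
    warning(sum(conflicting),
            " duplicated call key(s) had conflicting HF; keeping max-HF record")
  }
  # stable order so that among equal-HF duplicates the first-seen record wins
  ord <- order(key, -calls$hf, seq_len(nrow(calls)))
  calls <- calls[ord, ]
  calls <- calls[!duplicated(paste(calls$sample_id, calls$position, calls$ref,
                                   calls$alt, sep = "\r")), ]
  calls <- calls[order(calls$sample_id, calls$position), ]
  rownames(calls) <- NULL
  calls
}

#' Observation and distinct-site counts
#'
#' The counting unit throughout the enrichment tables is the variant
#' *observation* (one sample carrying one site); the distinct-site count
#' collapses observations over samples by (position, ref, alt).
#'
#' @param calls Deduplicated data frame of calls.
#' @return List with `n_observations` and `n_distinct_sites`.
#' @export
count_sites_and_observations <- function(calls) {
  list(n_observations = nrow(calls),
       n_distinct_sites = length(unique(paste(calls$position, calls$ref,
                                              calls$alt, sep = "\r"))))
}
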