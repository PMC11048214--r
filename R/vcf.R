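#' Write mtDNA calls to a VCF 4.2 file
#'
#' One file per cohort, one sample column per sample, contig `chrM`. Per-call
#' evidence is stored in FORMAT fields: `GT` (placeholder `0/1`), `HF`
#' (heteroplasmy fraction), `CILOW`/`CIUP` (HF confidence bounds), `DP`
#' (depth), `SF` (alt forward,reverse strand counts) and `MQ` (aggregate
#' mapping quality). Positions absent from a sample are `.`-filled.
#'
#' @param calls Data frame of mtDNA calls (see [filter_calls()]).
#' @param path Output file path.
#' @param contig Contig name written to the header and CHROM column.
#' @return `path`, invisibly.
#' @export
write_mt_vcf <- function(calls, path, contig = "chrM") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=16569>", contig),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=HF,Number=1,Type=Float,Description=\"Heteroplasmy fraction\">",
    "##FORMAT=<ID=CILOW,Number=1,Type=Float,Description=\"HF CI lower bound\">",
    "##FORMAT=<ID=CIUP,Number=1,Type=Float,Description=\"HF CI upper bound\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=SF,Number=2,Type=Integer,Description=\"Alt reads fwd,rev\">",
    "##FORMAT=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">")
  samples <- sort(unique(calls$sample_id))
  sites <- unique(calls[, c("position", "ref", "alt")])
  sites <- sites[order(sites$position, sites$ref, sites$alt), , drop = FALSE]
  key <- paste(calls$position, calls$ref, calls$alt, calls$sample_id)
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    cells <- vapply(samples, function(s) {
      j <- match(paste(sites$position[i], sites$ref[i], sites$alt[i], s), key)
      if (is.na(j)) return("./.:.:.:.:.:.:.")
      sprintf("0/1:%.6g:%.6g:%.6g:%d:%d,%d:%.6g",
              calls$hf[j], calls$hf_ci_lower[j], calls$hf_ci_upper[j],
              calls$depth[j], calls$alt_fwd[j], calls$alt_rev[j],
              calls$quality[j])
    }, character(1))
    paste(c(contig, sites$position[i], ".", sites$ref[i], sites$alt[i], ".",
            ".", ".", "GT:HF:CILOW:CIUP:DP:SF:MQ", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               rows), path)
  invisible(path)
}

#' Read mtDNA calls from a VCF written by [write_mt_vcf()]
#'
#' Narrow reader for the package's own VCF dialect (HF and strand evidence in
#' FORMAT). Returns the long call table consumed by [filter_calls()].
#'
#' @param path VCF file path.
#' @return Data frame of calls.
#' @export
read_mt_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (!length(body) || !startsWith(body[1], "#CHROM")) {
    stop("not a VCF file: ", path)
  }
  cols <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  samples <- cols[-(1:9)]
  if (length(body) == 1L) {
    return(data.frame(sample_id = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      variant_class = character(0), hf = numeric(0),
                      hf_ci_lower = numeric(0), hf_ci_upper = numeric(0),
                      depth = integer(0), alt_fwd = integer(0),
                      alt_rev = integer(0), quality = numeric(0)))
  }
  rec <- do.call(rbind, strsplit(body[-1], "\t"))
  out <- lapply(seq_along(samples), function(si) {
    cell <- rec[, 9 + si]
    keep <- cell != "./.:.:.:.:.:.:."
    if (!any(keep)) return(NULL)
    f <- do.call(rbind, strsplit(cell[keep], ":"))
    sf <- do.call(rbind, strsplit(f[, 6], ","))
    data.frame(sample_id = samples[si],
               position = as.integer(rec[keep, 2]),
               ref = rec[keep, 4], alt = rec[keep, 5],
               variant_class = ifelse(nchar(rec[keep, 4]) == 1L &
                                        nchar(rec[keep, 5]) == 1L,
                                      "SNP", "indel"),
               hf = as.numeric(f[, 2]),
               hf_ci_lower = as.numeric(f[, 3]),
               hf_ci_upper = as.numeric(f[, 4]),
               depth = as.integer(f[, 5]),
               alt_fwd = as.integer(sf[, 1]), alt_rev = as.integer(sf[, 2]),
               quality = as.numeric(f[, 7]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$position), ]
  rownames(res) <- NULL
  res
}
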