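#' Contingency-table and summary-statistic tests
#'
#' The enrichment panel compares case and control variant counts with the
#' classical tests used for sparse cohort tables: the two-sided Fisher exact
#' test for 2-row tables and the uncorrected chi-square test for larger
#' tables, plus a pooled-variance two-tailed Student t-test recomputed from
#' published group summaries (n, mean, SD).
#'
#' @name enrichment-tests
NULL

test_result <- function(method, statistic, df, p, note = NULL) {
  structure(list(method = method, statistic = statistic, df = df, p = p,
                 note = note),
            class = "mv_test_result")
}

#' @export
print.mv_test_result <- function(x, ...) {
  cat("<", x$method, "> ", sep = "")
  if (!is.na(x$statistic)) cat("statistic =", signif(x$statistic, 5), "")
  if (!is.na(x$df)) cat("df =", x$df, "")
  cat("p =", format.pval(x$p, digits = 4), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

check_count_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("contingency table must contain non-negative integers")
  }
  storage.mode(m) <- "double"
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the exact two-sided p-value by summing, over all tables with the
#' observed margins, the hypergeometric point probabilities that do not exceed
#' the observed table's point probability (ties admitted within a relative
#' tolerance of 1e-7 — the convention of mainstream statistics packages).
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return An `mv_test_result` with `method = "fisher_exact_2x2"`.
#' @examples
#' fisher_exact_2x2(matrix(c(74, 247, 54, 270), nrow = 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(m) {
  m <- check_count_matrix(m)
  if (!all(dim(m) == c(2L, 2L))) stop("fisher_exact_2x2 requires a 2x2 table")
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(test_result("fisher_exact_2x2", NA, NA, 1))
  k <- max(0, r1 + c1 - n):min(r1, c1)      # support of the [1,1] cell
  logp <- stats::dhyper(k, c1, n - c1, r1, log = TRUE)
  obs <- stats::dhyper(m[1, 1], c1, n - c1, r1, log = TRUE)
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  test_result("fisher_exact_2x2", NA, NA, min(p, 1))
}

#' Uncorrected chi-square test of independence
#'
#' Pearson statistic without continuity correction, with expected counts from
#' the table margins and df = (r-1)(c-1). Rows or columns with zero margins
#' are rejected (prune them upstream); small expected counts produce a
#' warning but no correction, mirroring the uncorrected practice the panel
#' reproduces.
#'
#' @param m r x c matrix of non-negative integer counts (r, c >= 2).
#' @return An `mv_test_result` with `method = "chi_square"`.
#' @export
chi_square <- function(m) {
  m <- check_count_matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("chi_square requires at least 2x2")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero-margin row/column; prune empty strata before testing")
  }
  expd <- outer(rs, cs) / sum(m)
  stat <- sum((m - expd)^2 / expd)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  note <- NULL
  if (any(expd < 5)) {
    note <- "expected count < 5 in at least one cell"
    warning("chi-square approximation may be poor: ", note)
  }
  test_result("chi_square", stat, df,
              stats::pchisq(stat, df, lower.tail = FALSE), note)
}

#' Pooled two-tailed Student t-test from group summaries
#'
#' Recomputes the classical equal-variance t-test from per-group sample size,
#' mean and sample SD, with df = n_a + n_b - 2. When both SDs are zero and the
#' means are equal, p = 1 by convention.
#'
#' @param a,b Lists (or named vectors) with elements `n`, `mean`, `sd`.
#' @return An `mv_test_result` with `method = "t_pooled"`.
#' @examples
#' t_test_from_summary(list(n = 8, mean = 450.3, sd = 71.85),
#'                     list(n = 4, mean = 362.0, sd = 7.20))
#' @export
t_test_from_summary <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  if (a$n < 2 || b$n < 2) stop("each group needs n >= 2")
  if (a$sd < 0 || b$sd < 0) stop("sd must be non-negative")
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) {
    if (a$mean == b$mean) return(test_result("t_pooled", 0, df, 1))
    return(test_result("t_pooled", Inf * sign(a$mean - b$mean), df, 0))
  }
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  test_result("t_pooled", t, df, 2 * stats::pt(-abs(t), df))
}

#' Classify a single-nucleotide substitution
#'
#' Substitutions are reported on the rCRS light-strand reference (the
#' "m.16298T>C" convention) and fall into the four transition classes that
#' dominate mammalian mtDNA, or a pooled transversion bucket. Indels are
#' rejected: they are excluded from the substitution spectrum.
#'
#' @param ref,alt Single-base reference and alternate alleles (vectorised).
#' @return Character vector in `c("A>G", "C>T", "G>A", "T>C", "transversion")`.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L)) {
    stop("indels are excluded from the substitution spectrum")
  }
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (any(!ok)) stop("ref/alt must be distinct single bases")
  cls <- paste0(ref, ">", alt)
  ifelse(cls %in% c("A>G", "C>T", "G>A", "T>C"), cls, "transversion")
}
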