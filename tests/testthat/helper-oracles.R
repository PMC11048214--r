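# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Fisher oracle enumerates all tables with the
# observed margins using choose(); the chi-square oracle is the literal hand
# formula; the concordance oracle is the written-out rule table.

# Two-sided Fisher exact p by exhaustive enumeration over margin-fixed tables.
fisher_enum_oracle <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(ks, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, numeric(1))
  p_obs <- prob[ks == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

chi_square_oracle <- function(m) {
  expd <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expd)^2 / expd)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# Rule table for the five-level concordance score (unanimity reading).
concordance_oracle <- function(n_D, n_B) {
  if (n_D >= 1 && n_B >= 1) return(0L)
  if (n_D >= 4) return(2L)
  if (n_D >= 1) return(1L)
  if (n_B >= 4) return(-2L)
  if (n_B >= 1) return(-1L)
  0L
}

random_2x2 <- function(max_n = 60) {
  repeat {
    m <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(m) >= 1 && sum(m) <= max_n) return(m)
  }
}

# Minimal well-formed mtDNA call record with overridable fields.
make_call <- function(sample_id = "S1", position = 7410L, ref = "C",
                      alt = "T", hf = 0.5, depth = 100L, alt_fwd = 25L,
                      alt_rev = 25L, quality = 40, variant_class = "SNP") {
  data.frame(sample_id = sample_id, position = position, ref = ref,
             alt = alt, variant_class = variant_class, hf = hf,
             hf_ci_lower = max(hf - 0.05, 0), hf_ci_upper = min(hf + 0.05, 1),
             depth = depth, alt_fwd = alt_fwd, alt_rev = alt_rev,
             quality = quality, stringsAsFactors = FALSE)
}

test_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- mitovar::load_atlas()
    cache
  }
})
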