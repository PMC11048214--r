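atlas <- test_atlas()

test_that("each retention rule fires with its documented reason", {
  calls <- rbind(
    make_call(position = 303L, hf = 0.50),                       # homopolymer
    make_call(position = 1007L, hf = 0.005),                     # low_hf
    make_call(position = 2000L, alt_fwd = 10L, alt_rev = 0L),    # single strand
    make_call(position = 2500L, depth = 3L, alt_fwd = 2L, alt_rev = 1L),
    make_call(position = 3000L, quality = 20),
    make_call(position = 7410L, hf = 0.30, depth = 50L, quality = 40))
  v <- filter_calls(calls, atlas)
  expect_equal(v$retained,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(v$reasons,
               c("homopolymer", "low_hf", "single_strand", "low_depth",
                 "low_quality", ""))
})

test_that("all failing reasons are reported in rule order", {
  bad <- make_call(position = 303L, hf = 0.005, depth = 2L,
                   alt_fwd = 2L, alt_rev = 0L, quality = 10)
  v <- filter_calls(bad, atlas)
  expect_equal(v$reasons,
               "low_depth,low_quality,homopolymer,single_strand,low_hf")
})

test_that("boundary semantics are closed as documented", {
  at <- function(...) filter_calls(make_call(...), atlas)$retained
  expect_true(at(depth = 5L, alt_fwd = 3L, alt_rev = 2L))
  expect_false(at(depth = 4L, alt_fwd = 2L, alt_rev = 2L))
  expect_true(at(quality = 25))
  expect_false(at(quality = 24.9))
  expect_true(at(hf = 0.01))
  expect_false(at(hf = 0.0099))
})

test_that("ploidy classification uses the closed 0.95 boundary", {
  expect_equal(classify_ploidy(c(1, 0.96, 0.95, 0.94, 0.01)),
               c("homoplasmic", "homoplasmic", "homoplasmic",
                 "heteroplasmic", "heteroplasmic"))
  expect_error(classify_ploidy(1.2), "\\[0, 1\\]")
  expect_error(classify_ploidy(-0.1), "\\[0, 1\\]")
})

test_that("deduplication keeps one record per key, preferring max HF", {
  a <- make_call(hf = 0.3)
  b <- make_call(hf = 0.3)
  expect_equal(nrow(dedupe_calls(rbind(a, b))), 1L)

  two_samples <- rbind(make_call(sample_id = "S1"), make_call(sample_id = "S2"))
  expect_equal(nrow(dedupe_calls(two_samples)), 2L)

  conflict <- rbind(make_call(hf = 0.3), make_call(hf = 0.5))
  expect_warning(d <- dedupe_calls(conflict), "conflicting HF")
  expect_equal(d$hf, 0.5)

  shuffled <- rbind(make_call(sample_id = "S2", position = 5L),
                    make_call(sample_id = "S1", position = 9L),
                    make_call(sample_id = "S1", position = 2L))
  d <- dedupe_calls(shuffled)
  expect_equal(d$sample_id, c("S1", "S1", "S2"))
  expect_equal(d$position, c(2L, 9L, 5L))
})

test_that("observation and distinct-site counting", {
  one_site_three_samples <- do.call(rbind, lapply(c("A", "B", "C"), function(s)
    make_call(sample_id = s)))
  cnt <- count_sites_and_observations(one_site_three_samples)
  expect_equal(cnt$n_observations, 3L)
  expect_equal(cnt$n_distinct_sites, 1L)
  empty <- count_sites_and_observations(make_call()[0, ])
  expect_equal(unlist(empty), c(n_observations = 0L, n_distinct_sites = 0L))

  # brute-force oracle on a random fixture
  set.seed(11)
  fx <- do.call(rbind, lapply(1:60, function(i)
    make_call(sample_id = sample(LETTERS[1:4], 1),
              position = sample(c(100L, 200L, 300L), 1),
              alt = sample(c("T", "G"), 1), ref = "C")))
  fx <- dedupe_calls(fx)
  cnt <- count_sites_and_observations(fx)
  expect_equal(cnt$n_observations, nrow(fx))
  expect_equal(cnt$n_distinct_sites,
               nrow(unique(fx[, c("position", "ref", "alt")])))
})

test_that("filtering is idempotent and rule removal is monotone", {
  set.seed(21)
  cohort <- generate_mt_cohort(cohort_config(seed = 21, n_cases = 3,
                                             n_controls = 3,
                                             mean_variants_per_sample = 60))
  v1 <- filter_calls(cohort$calls, atlas)
  kept <- v1[v1$retained, names(cohort$calls)]
  v2 <- filter_calls(kept, atlas)
  expect_true(all(v2$retained))

  # disabling any single rule can only grow the retained set
  base <- sum(v1$retained)
  relaxed <- list(mt_thresholds(min_depth = 0),
                  mt_thresholds(min_quality = 0),
                  mt_thresholds(min_hf = 0),
                  mt_thresholds(min_strand_reads = 0))
  for (th in relaxed) {
    expect_gte(sum(filter_calls(cohort$calls, atlas, th)$retained), base)
  }

  # ploidy classes partition the retained calls
  pl <- classify_ploidy(kept$hf)
  expect_equal(sum(pl == "homoplasmic") + sum(pl == "heteroplasmic"),
               nrow(kept))
})
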