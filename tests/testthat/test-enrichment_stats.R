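atlas <- test_atlas()

test_that("fisher_exact_2x2 reproduces documented p-values", {
  expect_lt(fisher_exact_2x2(rbind(c(17, 34), c(2, 68)))$p, 1e-4)
  expect_equal(round(fisher_exact_2x2(rbind(c(74, 247), c(54, 270)))$p, 4),
               0.0482)
  expect_equal(fisher_exact_2x2(rbind(c(0, 10), c(0, 10)))$p, 1)
  expect_error(fisher_exact_2x2(matrix(1, 3, 2)), "2x2")
  expect_error(fisher_exact_2x2(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("fisher_exact_2x2 equals the enumeration oracle and base R", {
  set.seed(41)
  for (i in 1:200) {
    m <- random_2x2()
    p <- fisher_exact_2x2(m)$p
    expect_lt(abs(p - fisher_enum_oracle(m)), 1e-9)
    expect_lt(abs(p - stats::fisher.test(m)$p.value), 1e-7)
  }
})

test_that("chi_square matches the hand formula and documented p-values", {
  expect_equal(round(chi_square(cbind(c(21, 6, 4, 20),
                                      c(34, 13, 10, 12)))$p, 4), 0.0527)
  expect_equal(round(chi_square(cbind(c(92, 46, 129, 36),
                                      c(54, 64, 144, 46)))$p, 3), 0.002)
  uni <- chi_square(rbind(c(5, 5), c(5, 5)))
  expect_equal(uni$statistic, 0)
  expect_equal(uni$p, 1)

  set.seed(42)
  for (i in 1:200) {
    m <- matrix(rpois(sample(2:4, 1) * 2, 8) + 1, ncol = 2)
    got <- suppressWarnings(chi_square(m))   # small-count warnings expected
    want <- chi_square_oracle(m)
    expect_equal(got$statistic, want$stat)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p)
  }
  expect_error(chi_square(rbind(c(0, 0), c(3, 4))), "zero-margin")
  expect_warning(chi_square(rbind(c(1, 2), c(2, 1))), "expected count")
})

test_that("pooled t-test reproduces documented p-values", {
  p4 <- function(a, b) round(t_test_from_summary(a, b)$p, 4)
  expect_equal(p4(list(n = 8, mean = 450.3, sd = 71.85),
                  list(n = 4, mean = 362.0, sd = 7.20)), 0.0377)
  expect_equal(round(t_test_from_summary(
    list(n = 8, mean = 40.13, sd = 28.75),
    list(n = 4, mean = 81.0, sd = 70.16))$p, 2), 0.17)
  same <- list(n = 5, mean = 3, sd = 1)
  res <- t_test_from_summary(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 8)
  # degenerate zero-variance convention
  expect_equal(t_test_from_summary(list(n = 3, mean = 1, sd = 0),
                                   list(n = 3, mean = 1, sd = 0))$p, 1)
  expect_error(t_test_from_summary(list(n = 1, mean = 1, sd = 0), same),
               "n >= 2")
})

test_that("substitution classification covers transitions and transversions", {
  expect_equal(classify_substitution(c("T", "G", "A"), c("C", "A", "C")),
               c("T>C", "G>A", "transversion"))
  expect_error(classify_substitution("A", "AC"), "indel")
  expect_error(classify_substitution("A", "A"), "distinct")
})

test_that("build_tables reproduces the encoded descriptive table", {
  fx <- wes_fixture(atlas)
  tb <- build_tables(fx$calls, fx$design, atlas)
  expect_equal(unname(tb$ploidy$counts), rbind(c(17, 2), c(34, 68)))
  expect_equal(unname(tb$region$counts), rbind(c(18, 17), c(33, 53)))
  expect_equal(unname(tb$cr_sites$counts),
               cbind(c(6, 9, 1, 2), c(5, 7, 1, 4)))
  expect_equal(unname(tb$coding_genes$counts),
               cbind(c(2, 3, 4, 2, 4, 0, 0, 1, 0, 4),
                     c(2, 7, 3, 2, 3, 2, 4, 5, 1, 7)))
  expect_equal(rownames(tb$coding_genes$counts),
               c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP6", "MT-CO3",
                 "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB"))
  expect_equal(unname(tb$rrna_trna$counts),
               cbind(c(9, 1, 3, 0), c(8, 7, 1, 1)))
  expect_equal(unname(tb$substitution$counts),
               cbind(c(21, 6, 4, 20), c(34, 13, 10, 12)))
  # margins conserve: column sums equal per-group retained counts
  expect_equal(unname(colSums(tb$ploidy$counts)), c(51, 70))
  expect_equal(unname(colSums(tb$region$counts)), c(51, 70))
  expect_equal(unname(colSums(tb$substitution$counts)), c(51, 69)) # indel out
  # CR functional domains agree with a direct assignment oracle
  reg <- assign_region(atlas, fx$calls$position)
  grp <- fx$design$group[match(fx$calls$sample_id, fx$design$sample_id)]
  for (dom in c("CENTRAL_DOMAIN", "CSB", "ETAS", "LSP")) {
    expect_equal(unname(tb$cr_domains$counts[dom, ]),
                 c(sum(reg$functional_domain == dom & grp == "case"),
                   sum(reg$functional_domain == dom & grp == "control")))
  }
  expect_error(build_tables(fx$calls,
                            fx$design[-1, , drop = FALSE], atlas),
               "missing from design")
})

test_that("the panel reproduces every printed p-value through the full path", {
  fx <- wes_fixture(atlas)
  tb <- build_tables(fx$calls, fx$design, atlas)
  res <- run_panel(tb)
  expect_equal(res$ploidy$method, "fisher_exact_2x2")
  expect_lt(res$ploidy$p, 1e-4)
  expect_equal(round(res$region$p, 4), 0.2250)
  expect_equal(res$cr_sites$method, "chi_square")
  expect_equal(round(res$cr_sites$p, 4), 0.8061)
  expect_equal(round(res$coding_genes$p, 4), 0.4854)
  expect_equal(round(res$rrna_trna$p, 4), 0.1052)
  expect_equal(round(res$substitution$p, 4), 0.0527)
  # het/hom spectra are tested separately
  expect_true(all(c("substitution_het", "substitution_hom") %in% names(res)))
})

test_that("untestable tables are skipped with a note, zero rows pruned", {
  single <- list(
    empty = structure(list(name = "empty",
                           counts = matrix(0, 2, 2,
                                           dimnames = list(c("a", "b"),
                                                           c("case", "control")))),
                      class = "mv_table"),
    pruned = structure(list(name = "pruned",
                            counts = matrix(c(5, 0, 3, 6, 0, 4), ncol = 2,
                                            dimnames = list(c("a", "b", "c"),
                                                            c("case", "control")))),
                       class = "mv_table"))
  res <- run_panel(single)
  expect_equal(res$empty$method, "skipped")
  expect_true(is.na(res$empty$p))
  expect_equal(res$pruned$method, "chi_square")
  expect_match(res$pruned$note, "pruned empty strata: b")
  expect_equal(res$pruned$df, 1)
})

test_that("render_summary formats n/N (%) rows with recomputed percentages", {
  fx <- wes_fixture(atlas)
  tb <- build_tables(fx$calls, fx$design, atlas)
  res <- run_panel(tb)
  s <- render_summary(tb, res)
  het <- s[s$block == "ploidy" & s$stratum == "Het", ]
  expect_equal(het$case, "17/51 (33%)")
  expect_equal(het$control, "2/70 (3%)")
  expect_equal(het$p, "<0.0001")
  cr <- s[s$block == "region" & s$stratum == "Control Region", ]
  expect_equal(cr$case, "18/51 (35%)")
  expect_equal(cr$p, "0.2250")
  empty <- render_summary(list(z = structure(
    list(name = "z", counts = matrix(0, 1, 2,
                                     dimnames = list("r", c("case", "control")))),
    class = "mv_table")))
  expect_equal(empty$case, "0/0 (-)")
})
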