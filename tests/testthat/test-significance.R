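test_that("contingency cells follow the selected convention", {
  counts <- data.frame(n_both = 142, n_cd = 220, n_idx = 1066,
                       n_total = 125924)
  direct <- assemble_table(counts, convention = "direct")
  expect_equal(unlist(direct[c("a", "b", "c", "d")]),
               c(a = 142, b = 220, c = 1066, d = 125924))
  remainder <- assemble_table(counts, convention = "remainder")
  expect_equal(remainder$d, 125924 - 142 - 220 - 1066)
  margins <- assemble_table(counts, convention = "margins")
  expect_equal(unlist(margins[c("a", "b", "c", "d")]),
               c(a = 142, b = 78, c = 924, d = 124780))
  expect_error(
    assemble_table(data.frame(n_both = 1, n_cd = 0, n_idx = 0, n_total = 0),
                   convention = "remainder"),
    "negative cell")
  expect_error(
    assemble_table(data.frame(n_both = 1, n_cd = 0, n_idx = 0, n_total = 9),
                   convention = "margins"),
    "negative cell")
})

test_that("log-space Fisher reproduces small enumerable cases", {
  expect_equal(fisher_exact_pvalue(2, 0, 0, 2, "greater"), 1 / 6,
               tolerance = 1e-12)
  expect_equal(fisher_exact_pvalue(0, 3, 5, 7, "greater"), 1)
  expect_equal(fisher_exact_pvalue(1, 1, 1, 1, "two_sided"), 1)
  expect_error(fisher_exact_pvalue(0, 0, 0, 0), "all-zero")
})

test_that("tail identities and monotonicity hold on random tables", {
  withr::local_seed(7)
  for (i in 1:50) {
    tab <- random_table(100L)
    a <- tab["a"]; b <- tab["b"]; c <- tab["c"]; d <- tab["d"]
    point <- unname(exp(comormine:::log_hyper_pmf(a, sum(tab), a + b, a + c)))
    expect_equal(
      fisher_exact_pvalue(a, b, c, d, "greater") +
        fisher_exact_pvalue(a, b, c, d, "less"),
      1 + point, tolerance = 1e-9)
    # greater-tail p strictly decreases as the a-cell grows at fixed
    # margins (strictness is only representable when the removed point
    # mass survives double rounding against a tail near 1)
    if (b > 0 && c > 0) {
      p_hi <- fisher_exact_pvalue(a + 1, b - 1, c - 1, d + 1, "greater")
      p_lo <- fisher_exact_pvalue(a, b, c, d, "greater")
      if (point > 1e-12) expect_lt(p_hi, p_lo) else expect_lte(p_hi, p_lo)
    }
  }
})

test_that("log-space path agrees with linear-space hypergeometric sums", {
  # stats::phyper computes the same tail by a different route
  withr::local_seed(11)
  for (i in 1:50) {
    tab <- random_table(100L)
    p_log <- fisher_exact_pvalue(tab["a"], tab["b"], tab["c"], tab["d"],
                                 "greater")
    p_lin <- stats::phyper(tab["a"] - 1, tab["a"] + tab["b"],
                           tab["c"] + tab["d"], tab["a"] + tab["c"],
                           lower.tail = FALSE)
    if (p_log > 1e-10) {
      expect_equal(p_log, unname(p_lin), tolerance = 1e-9)
    }
  }
  # and with fisher.test on a fixed asymmetric table, both sidednesses
  tab <- matrix(c(12, 3, 5, 40), 2, byrow = TRUE)
  expect_equal(fisher_exact_pvalue(12, 3, 5, 40, "greater"),
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-9)
  expect_equal(fisher_exact_pvalue(12, 3, 5, 40, "two_sided"),
               stats::fisher.test(tab)$p.value, tolerance = 1e-9)
})

test_that("extreme tails are returned without underflow", {
  p <- fisher_exact_pvalue(142, 78, 924, 124780, "greater")
  expect_gt(p, 0)
  expect_lt(p, 1e-230)
  expect_equal(log10(p), -237.885, tolerance = 1e-3)
})

test_that("significance classification thresholds and sorts correctly", {
  res <- comorbidity_significance(ad_counts(), alpha = 1 - 1e-12)
  expect_true(all(res$significant))
  expect_identical(res$p_value, sort(res$p_value))

  empty <- comorbidity_significance(ad_counts()[0, ])
  expect_identical(nrow(empty), 0L)

  res_bh <- comorbidity_significance(ad_counts(), p_adjust = "BH")
  raw <- comorbidity_significance(ad_counts())
  expect_true(all(res_bh$p_value >= raw$p_value))
  expect_error(comorbidity_significance(ad_counts(), alpha = 0), "alpha")
})

test_that("brute-force oracle matches enumerable values and bounds", {
  expect_equal(fisher_bruteforce_oracle(2, 0, 0, 2, "greater"), 1 / 6,
               tolerance = 1e-15)
  expect_equal(fisher_bruteforce_oracle(1, 1, 1, 1, "two_sided"), 1,
               tolerance = 1e-15)
  expect_error(fisher_bruteforce_oracle(100, 50, 40, 30), "N <= 200")
  # spot agreement with stats::fisher.test (a third route)
  expect_equal(fisher_bruteforce_oracle(12, 3, 5, 40, "two_sided"),
               stats::fisher.test(matrix(c(12, 3, 5, 40), 2, byrow = TRUE))$p.value,
               tolerance = 1e-10)
})
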