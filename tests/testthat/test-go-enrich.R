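# Binomial test, multiple-testing adjustment, group enrichment, top report.

test_that("binomial_test matches hand-computed tail sums", {
  expect_equal(binomial_test(0, 10, 0.5, "greater"), 1.0)
  expect_equal(binomial_test(8, 10, 0.5, "greater"), 56 / 1024)
  expect_equal(binomial_test(8, 10, 0.5, "two_sided"), 112 / 1024)
  # degenerate nulls
  expect_equal(binomial_test(1, 10, 0), 0)
  expect_equal(binomial_test(0, 10, 0), 1)
  expect_equal(binomial_test(3, 10, 1, "greater"), 1)
  expect_error(binomial_test(11, 10, 0.5), "0 <= k <= n")
  expect_error(binomial_test(2, 10, 1.5), "p0")
})

test_that("binomial_test agrees with brute-force enumeration and stats::binom.test", {
  for (n in c(1, 5, 12)) {
    for (p0 in c(0.1, 0.5, 0.9)) {
      for (k in 0:n) {
        expect_equal(binomial_test(k, n, p0, "greater"),
                     brute_binom_greater(k, n, p0), tolerance = 1e-12)
        expect_equal(binomial_test(k, n, p0, "two_sided"),
                     brute_binom_two_sided(k, n, p0), tolerance = 1e-12)
      }
    }
  }
  # independent reference implementation
  expect_equal(binomial_test(40, 100, 0.3, "greater"),
               stats::binom.test(40, 100, 0.3, "greater")$p.value)
  expect_equal(binomial_test(40, 100, 0.3, "two_sided"),
               stats::binom.test(40, 100, 0.3, "two.sided")$p.value)
})

test_that("upper-tail p is non-increasing in k and stable for large n", {
  for (p0 in c(0.05, 0.5)) {
    p <- vapply(0:50, binomial_test, numeric(1), n = 50, p0 = p0)
    expect_true(all(diff(p) <= 1e-15))
  }
  # log-space path keeps deep tails accurate where naive summation underflows
  p <- binomial_test(150, 1000, 0.05)
  expect_equal(log(p), pbinom(149, 1000, 0.05, lower.tail = FALSE,
                              log.p = TRUE), tolerance = 1e-10)
})

test_that("Holm and BH adjustments match the step definitions and p.adjust", {
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(0.02), 0.02)          # single p unchanged
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  set.seed(17)
  p <- runif(40)
  expect_equal(adjust_pvalues(p, "holm"), stats::p.adjust(p, "holm"))
  expect_equal(adjust_pvalues(p, "BH"), stats::p.adjust(p, "BH"))
  expect_true(all(adjust_pvalues(p, "holm") >= p))
  expect_true(all(adjust_pvalues(p, "BH") >= p))
  expect_true(all(adjust_pvalues(p, "holm") >= adjust_pvalues(p, "BH")))
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("count_terms restricts to the requested GO level", {
  dag <- parse_obo_text(make_obo(6, 2))
  lvl6 <- dag$terms$term_id[dag$terms$level == 6]
  lvl5 <- dag$terms$term_id[dag$terms$level == 5]
  ann <- list(p1 = c(lvl6[1], lvl5[1]), p2 = lvl6[1], p3 = lvl5[1])
  ct <- count_terms(ann, c("p1", "p2", "p3", "p4"), dag, level = 6)
  expect_equal(ct$n, 3L)                       # p4 unannotated
  expect_equal(unname(ct$k[lvl6[1]]), 2L)
  expect_false(lvl5[1] %in% names(ct$k))       # level-5 term excluded
  expect_equal(count_terms(list(), "p1", dag)$n, 0L)
})

test_that("enrich_group applies the direction filter and flags degenerate nulls", {
  tested <- list(n = 100L, k = c(T1 = 30L, T2 = 5L, T3 = 4L))
  control <- list(n = 200L, k = c(T1 = 10L, T2 = 40L))
  res <- enrich_group(tested, control)
  expect_equal(res$p0[res$term_id == "T1"], 0.05)
  expect_true(res$significant[res$term_id == "T1"])
  # T2 is depleted: even a tiny p must not be reported as enriched
  expect_equal(res$direction[res$term_id == "T2"], "under")
  expect_false(res$significant[res$term_id == "T2"])
  # T3 absent from control: k_C = 0, degenerate, still computed
  expect_true(res$degenerate[res$term_id == "T3"])
  expect_equal(res$p0[res$term_id == "T3"], 0)
  expect_error(enrich_group(tested, list(n = 0L, k = integer())),
               "control")
  # tested identical to control fractions -> nothing significant
  same <- enrich_group(list(n = 200L, k = c(T1 = 10L, T2 = 40L)), control)
  expect_false(any(same$significant))
  expect_true(all(same$p_raw >= 0.5))
  # Holm/Bonferroni guarantee: adjusted >= raw
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("top_report sorts by adjusted p with deterministic tie-breaks", {
  res <- data.frame(term_id = c("T3", "T1", "T2", "T4"),
                    k_T = c(10L, 20L, 10L, 1L), n_T = 100L,
                    k_C = 0L, n_C = 100L, p0 = 0,
                    p_raw = c(1e-4, 1e-6, 1e-6, 0.2),
                    p_adj = c(1e-3, 1e-5, 1e-5, 0.6),
                    direction = c("over", "over", "over", "over"),
                    significant = c(TRUE, TRUE, TRUE, FALSE),
                    degenerate = FALSE)
  top <- top_report(res, top_n = 2)
  expect_equal(top$term_id, c("T1", "T2"))   # tie broken by larger fraction
  expect_equal(top$neg_log10_padj, c(5, 5))
  expect_equal(nrow(top_report(res[res$p_adj > 0.5, , drop = FALSE])), 0L)
  expect_equal(nrow(top_report(res, top_n = 10)), 3L)
})
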