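test_that("exact Mann-Whitney matches hand-enumerated cases", {
  res <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1)  # 2 of the 20 assignments are as extreme
  # all ties: every assignment equivalent
  res_tie <- mann_whitney_exact(c(1, 1, 1), c(1, 1, 1))
  expect_equal(res_tie$u, 4.5)
  expect_equal(res_tie$p, 1)
})

test_that("enumeration agrees with an independent brute-force oracle", {
  withr::with_seed(71, {
    for (i in 1:25) {
      n1 <- sample(1:7, 1)
      n2 <- sample(1:7, 1)
      # half the draws from a small integer support to force ties
      pool <- if (i %% 2 == 0) sample(1:4, n1 + n2, replace = TRUE) else stats::rnorm(n1 + n2)
      x <- pool[seq_len(n1)]
      y <- pool[-seq_len(n1)]
      got <- mann_whitney_exact(x, y)
      oracle <- mwu_enumeration_oracle(x, y)
      expect_equal(got$u, oracle$u)
      expect_equal(got$p, oracle$p, tolerance = 1e-12)
    }
  })
})

test_that("the no-ties large-sample path matches enumeration and wilcox.test", {
  withr::with_seed(72, {
    x <- stats::rnorm(9)
    y <- stats::rnorm(8) + 0.8
    enum <- mann_whitney_exact(x, y)                     # C(17,9) small enough
    shifted <- mann_whitney_exact(x, y, enum_limit = 10) # force dwilcox path
    expect_equal(shifted$method, "exact_no_ties")
    expect_equal(shifted$u, enum$u)
    expect_equal(shifted$p, enum$p, tolerance = 1e-12)
    wt <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(unname(wt$statistic), enum$u)
    expect_equal(unname(wt$p.value), enum$p, tolerance = 1e-12)
  })
})

test_that("the Monte Carlo fallback approximates enumeration under ties", {
  withr::with_seed(73, {
    x <- sample(1:3, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    enum <- mann_whitney_exact(x, y)
    mc <- mann_whitney_exact(x, y, enum_limit = 10, seed = 4)
    expect_equal(mc$method, "monte_carlo")
    expect_equal(mc$p, enum$p, tolerance = 0.02)
    # deterministic under its seed
    expect_equal(mann_whitney_exact(x, y, enum_limit = 10, seed = 4)$p, mc$p)
  })
})

test_that("Bonferroni is min(1, N p), order preserving, and validated", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(0.9, n = 2), 1)
  expect_equal(bonferroni(0.001, n = 59), 0.059)
  withr::with_seed(74, {
    p <- stats::runif(30)
    adj <- bonferroni(p, n = 40)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  })
  expect_error(bonferroni(c(0.1, 0.2), n = 1), class = "rscuflow_error_config")
  expect_error(bonferroni(c(-0.1)), class = "rscuflow_error_config")
})

test_that("Cohen's d uses the quadratic-mean denominator and is equivariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(0, 2, 4)), 0)
  x <- c(1, 2, 3); y <- c(0, 1, 2)  # means 2 vs 1, unit sds -> d = 1.0
  expect_equal(cohens_d(x, y), 1)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_equal(cohens_d(x + 10, y + 10), cohens_d(x, y))
  expect_equal(cohens_d(3 * x, 3 * y), cohens_d(x, y))
  expect_error(cohens_d(c(1, 1), c(2, 2)), class = "rscuflow_error_undefined_effect")
  # consistency: d estimates the standardized shift
  withr::with_seed(75, {
    d <- cohens_d(stats::rnorm(4000, 0.5), stats::rnorm(4000))
    expect_equal(d, 0.5, tolerance = 0.1)
  })
  # pooled variant agrees when group sizes and variances match
  withr::with_seed(76, {
    a <- stats::rnorm(50); b <- stats::rnorm(50, 1)
    expect_equal(cohens_d(a, b, pooled = TRUE), cohens_d(a, b), tolerance = 0.02)
  })
})

test_that("effect bins reproduce the printed classifications", {
  expect_equal(effect_bin(c(0.21, 0.38, 0.70)), c("small", "medium", "large"))
  expect_equal(effect_bin(c(0.05, -0.25, 1.2)), c("very small", "small", "very large"))
  # contiguous boundaries
  expect_equal(effect_bin(c(0.2, 0.36, 0.66, 1, 1.0001)),
               c("small", "medium", "large", "large", "very large"))
})

test_that("compare_groups handles null, planted, and stratified cases", {
  profiles <- random_usage_profiles(6, seed = 77)
  r <- rscu(profiles)
  r2 <- r
  r2$sample_id <- paste0(r2$sample_id, "_b")
  null_cmp <- compare_groups(r, r2)
  expect_equal(attr(null_cmp, "fraction_significant_codons"), 0)
  expect_equal(nrow(null_cmp), 59)

  # planted shift in the Phe family, clean separation
  withr::with_seed(78, {
    a <- dplyr::bind_rows(lapply(1:8, function(i)
      usage_profile(c(TTT = 3 + stats::rnorm(1, 0, 0.05)), sample_id = paste0("a", i))))
    b <- dplyr::bind_rows(lapply(1:8, function(i)
      usage_profile(c(TTT = 1 + stats::rnorm(1, 0, 0.05)), sample_id = paste0("b", i))))
  })
  cmp <- compare_groups(rscu(a), rscu(b))
  expect_true(all(cmp$significant[cmp$codon %in% c("TTT", "TTC")]))
  # bookkeeping identity on the output table
  expect_equal(attr(cmp, "fraction_significant_tests"),
               sum(cmp$significant) / nrow(cmp))
  expect_equal(attr(cmp, "bonferroni_n"), nrow(cmp))
  expect_equal(cmp$p_adj, pmin(1, nrow(cmp) * cmp$p_raw))

  # strata: contributions over strata sum to one
  strata2 <- stats::setNames(c(rep("E10", 6), rep("E11", 2), rep("E10", 6), rep("E11", 2)),
                             c(paste0("a", 1:8), paste0("b", 1:8)))
  cmp_s <- compare_groups(rscu(a), rscu(b), strata = strata2)
  contrib <- stratum_contribution(cmp_s)
  expect_setequal(contrib$stratum, c("E10", "E11"))
  if (sum(cmp_s$significant) > 0) {
    expect_equal(sum(contrib$contribution), 1)
  }
  # a glance row summarizes the comparison
  g <- glance(cmp)
  expect_equal(g$n_tests, nrow(cmp))
  expect_true(g$fraction_significant_codons > 0)
})
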