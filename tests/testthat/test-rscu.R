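test_that("rscu follows the defining formula on small families", {
  # uniform four-fold family (Ala): all 1
  p <- usage_profile(fill = 1)
  r <- rscu(p)
  expect_equal(as.numeric(r[1, c("GCA", "GCC", "GCG", "GCT")]), rep(1, 4))
  # 3:1 two-fold family (Phe) -> 1.5 / 0.5
  p2 <- usage_profile(c(TTT = 3, TTC = 1))
  r2 <- rscu(p2)
  expect_equal(as.numeric(r2[1, c("TTT", "TTC")]), c(1.5, 0.5))
  # zero-total family undefined
  p3 <- usage_profile(c(TTT = 0, TTC = 0))
  r3 <- rscu(p3)
  expect_true(all(is.na(r3[1, c("TTT", "TTC")])))
  # stop codons never appear
  expect_false(any(c("TGA", "TAG", "TAA") %in% names(r)))
  # degeneracy-1 codons are identically 1 when expressed
  expect_equal(as.numeric(r[1, c("ATG", "TGG")]), c(1, 1))
})

test_that("family sums equal degeneracy and rscu is scale invariant", {
  profiles <- random_usage_profiles(200, seed = 21)
  r <- rscu(profiles)
  code <- standard_genetic_code()
  fams <- split(code$codon[code$aa != "*"], code$aa[code$aa != "*"])
  for (codons in fams) {
    sums <- rowSums(r[, codons, drop = FALSE])
    expect_equal(sums, rep(length(codons), nrow(r)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  scaled <- profiles
  scaled[all_codons()] <- scaled[all_codons()] * 37.5
  expect_equal(rscu(scaled), r)
})

test_that("representation classification uses inclusive thresholds", {
  p <- usage_profile(c(TTT = 3, TTC = 1,          # exactly 1.5 / 0.5
                       CAA = 0, CAG = 0))         # undefined
  cls <- classify_representation(rscu(p))
  expect_equal(cls$TTT, "over")
  expect_equal(cls$TTC, "under")
  expect_equal(cls$GCA, "neutral")
  expect_equal(cls$CAA, "undefined")
  expect_error(classify_representation(rscu(p), hi = 0.4, lo = 0.5),
               class = "rscuflow_error_config")
  # in a two-fold family, rscu 1.5 forces the partner to 0.5
  r <- rscu(p)
  expect_equal(r$TTT + r$TTC, 2)
})

test_that("group summaries report mean and n-1 SD", {
  p1 <- usage_profile(c(TTT = 1, TTC = 1))
  p2 <- usage_profile(c(TTT = 3, TTC = 1), sample_id = "s2")
  r <- rscu(dplyr::bind_rows(p1, p2))
  gs <- summarize_group(r, label = "demo")
  row <- gs[gs$codon == "TTT", ]
  expect_equal(row$mean, mean(c(1, 1.5)))
  expect_equal(row$sd, stats::sd(c(1, 1.5)))
  expect_equal(row$n, 2)
  expect_equal(row$label, "Phe-TTT")
  # identical profiles -> SD 0; single profile -> SD 0 with flag
  gs_same <- summarize_group(rscu(dplyr::bind_rows(p1, p1)))
  expect_true(all(gs_same$sd == 0))
  gs1 <- summarize_group(rscu(p1))
  expect_true(all(gs1$sd_degenerate))
  # hand check of the n-1 formula on values 1.0 and 2.0
  expect_equal(stats::sd(c(1, 2)), 0.7071, tolerance = 1e-4)
  expect_error(summarize_group(r[0, ]), class = "rscuflow_error_empty_selection")
})

test_that("planted family bias is recovered by mean-profile classification", {
  # 9:1 preference in every two-fold family -> rscu 1.8 / 0.2
  withr::with_seed(9, {
    code <- standard_genetic_code()
    two_fold <- split(code$codon[!is.na(code$degeneracy) & code$degeneracy == 2],
                      code$aa[!is.na(code$degeneracy) & code$degeneracy == 2])
    vals <- c()
    for (fam in two_fold) {
      vals[fam[1]] <- 9
      vals[fam[2]] <- 1
    }
    profiles <- dplyr::bind_rows(lapply(1:5, function(i) {
      jitter <- stats::rnorm(length(vals), 0, 0.01)
      usage_profile(vals + jitter, sample_id = paste0("s", i))
    }))
    gs <- summarize_group(rscu(profiles))
    mean_profile <- usage_profile(stats::setNames(gs$mean, gs$codon))
    cls <- classify_representation(mean_profile[c("sample_id", sense_codons())])
    for (fam in two_fold) {
      expect_equal(cls[[fam[1]]], "over")
      expect_equal(cls[[fam[2]]], "under")
    }
  })
})

test_that("external usage tables classify through the same path", {
  uniform <- stats::setNames(rep(5, 64), all_codons())
  cls <- classify_external_usage(uniform)
  expect_equal(nrow(cls), 61)
  expect_true(all(cls$class == "neutral"))
  # dominant codon per two-fold family: 9:1 -> over/under
  biased <- uniform
  biased["TTT"] <- 9; biased["TTC"] <- 1
  cls2 <- classify_external_usage(biased)
  expect_equal(cls2$rscu[cls2$codon == "TTT"], 1.8)
  expect_equal(cls2$class[cls2$codon == "TTT"], "over")
  expect_equal(cls2$class[cls2$codon == "TTC"], "under")
  # strictly positive table: nothing undefined
  withr::with_seed(2, {
    tab <- stats::setNames(stats::runif(61, 0.5, 4), sense_codons())
    cls3 <- classify_external_usage(tab)
    expect_false(any(cls3$class == "undefined"))
  })
  expect_error(classify_external_usage(stats::setNames(1:10, sense_codons()[1:10])),
               class = "rscuflow_error_missing_codons")
})
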