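test_that("feature selection keeps exactly the 59 PCA codons", {
  profiles <- random_usage_profiles(4, seed = 1)
  fm <- select_codon_features(profiles)
  expect_equal(ncol(fm), 60)  # sample_id + 59 codons
  expect_false(any(c("ATG", "TGG", "TGA", "TAG", "TAA") %in% names(fm)))
  expect_equal(select_codon_features(fm), fm)  # idempotent
  expect_error(select_codon_features(fm[, 1:10]),
               class = "rscuflow_error_missing_codons")
})

test_that("standardization uses the population denominator", {
  f <- tibble::tibble(sample_id = c("a", "b"), f1 = c(1, 3), f2 = c(5, 5))
  z <- standardize_features(f)
  expect_equal(z$f1, c(-1, 1))  # population sd of (1,3) is 1
  expect_equal(z$f2, c(0, 0))
  expect_true(attr(z, "constant")[["f2"]])
  z2 <- standardize_features(z[, 1:3])
  expect_equal(z2$f1, z$f1)  # idempotent
  expect_error(standardize_features(f[1, ]), class = "rscuflow_error_config")
})

make_feature_tbl <- function(x) {
  out <- tibble::as_tibble(x, .name_repair = ~paste0("f", seq_len(ncol(x))))
  tibble::add_column(out, sample_id = paste0("s", seq_len(nrow(x))), .before = 1)
}

test_that("component count follows the variance threshold and cap", {
  withr::with_seed(31, {
    # rank-1 structure + tiny noise -> K = 1
    u <- stats::rnorm(30)
    x1 <- outer(u, stats::rnorm(10)) + matrix(stats::rnorm(300, sd = 1e-3), 30)
    m1 <- fit_codon_pca(make_feature_tbl(x1))
    expect_equal(m1$k, 1)
    # isotropic noise in many dimensions -> the cap of 5 binds
    x2 <- matrix(stats::rnorm(100 * 59), 100, 59)
    m2 <- fit_codon_pca(make_feature_tbl(x2))
    expect_equal(m2$k, 5)
    expect_gt(m2$k80, 5)
    # K-selection equals a brute-force scan of cumulative ratios
    for (m in list(m1, m2)) {
      evr <- m$explained_variance_ratio
      brute <- min(which(vapply(seq_along(evr),
                                function(k) sum(evr[1:k]) >= 0.8, logical(1))))
      expect_equal(m$k80, brute)
      expect_equal(m$k, min(5, brute))
    }
    expect_error(fit_codon_pca(make_feature_tbl(x2), var_threshold = 1.2),
                 class = "rscuflow_error_config")
  })
})

test_that("the PCA model is a faithful orthonormal decomposition", {
  withr::with_seed(32, {
    x <- matrix(stats::rnorm(25 * 8), 25, 8)
    m <- fit_codon_pca(make_feature_tbl(x))
    v <- m$loadings_full
    expect_equal(crossprod(v), diag(ncol(v)), tolerance = 1e-8, ignore_attr = TRUE)
    evr <- m$explained_variance_ratio
    expect_true(all(diff(evr) <= 1e-12))
    expect_true(all(evr >= 0 & evr <= 1) && sum(evr) <= 1 + 1e-9)
    # reconstruction from the full basis returns the standardized data
    z <- standardize_features(make_feature_tbl(x))
    zm <- as.matrix(z[, -1])
    scores_full <- zm %*% v
    expect_equal(scores_full %*% t(v), zm, tolerance = 1e-8, ignore_attr = TRUE)
    # sign convention: largest-|loading| entry of each retained component positive
    for (j in seq_len(m$k)) {
      expect_gt(v[which.max(abs(v[, j])), j], 0)
    }
    # score covariance is diagonal
    cov_s <- stats::cov(scores_full)
    expect_equal(cov_s, diag(diag(cov_s)), tolerance = 1e-8, ignore_attr = TRUE)
  })
})

fake_pca <- function(loadings, scores = NULL, k = ncol(loadings)) {
  colnames(loadings) <- NULL
  n <- if (is.null(scores)) 4 else nrow(scores)
  if (is.null(scores)) {
    scores <- matrix(0, n, k)
  }
  sc <- tibble::as_tibble(scores, .name_repair = ~paste0("PC", seq_len(k)))
  sc <- tibble::add_column(sc, sample_id = paste0("s", seq_len(n)), .before = 1)
  structure(list(loadings = loadings, loadings_full = loadings,
                 explained_variance_ratio = rep(1 / k, k), k = k, k80 = k,
                 cap = 5, var_threshold = 0.8, scores = sc, n_samples = n),
            class = "codon_pca")
}

test_that("loading reports highlight amino acids with two passing codons", {
  codons <- pca_feature_codons()
  l <- matrix(0, length(codons), 1, dimnames = list(codons, NULL))
  l[c("GCT", "GCC"), 1] <- c(0.25, 0.30)  # Ala: two passing codons
  l["GTG", 1] <- 0.4                      # Val: single codon
  l["AAT", 1] <- 0.21; l["AAC", 1] <- -0.5 # Asn: mixed signs, pooled rule
  rep <- loading_report(fake_pca(l))
  ala <- rep$codons[rep$codons$aa == "A", ]
  expect_true(all(ala$highlighted))
  expect_false(any(rep$codons$highlighted[rep$codons$aa == "V"]))
  expect_true(all(rep$codons$highlighted[rep$codons$aa == "N"]))
  # per-sign counting drops the mixed-sign pair
  rep2 <- loading_report(fake_pca(l), per_sign = TRUE)
  expect_false(any(rep2$codons$highlighted[rep2$codons$aa == "N"]))
  # sub-threshold loadings: empty highlight
  rep3 <- loading_report(fake_pca(l * 0.1))
  expect_equal(nrow(rep3$codons), 0)
  # the raw listing keeps single-codon entries
  expect_true("GTG" %in% rep$codons$codon)
})

test_that("sample descriptors use a strict score threshold", {
  codons <- pca_feature_codons()
  l <- matrix(0, length(codons), 2, dimnames = list(codons, NULL))
  l[c("GCT", "GCC"), 2] <- 0.3
  l[c("TTA", "TTG"), 2] <- -0.3
  scores <- cbind(c(0, 5, 0, 1), c(0, 0, 6.2, -7))
  model <- fake_pca(l, scores = scores, k = 2)
  d <- describe_samples(model, score_threshold = 5)
  expect_equal(d$sample_id, "s3")   # 5.0 exactly is excluded, -7 is not > 5
  expect_equal(d$pc, 2)
  expect_setequal(d$pos_codons[[1]], c("GCT", "GCC"))
  expect_setequal(d$neg_codons[[1]], c("TTA", "TTG"))
  d_abs <- describe_samples(model, score_threshold = 5, absolute = TRUE)
  expect_setequal(d_abs$sample_id, c("s3", "s4"))
  expect_equal(nrow(describe_samples(model, score_threshold = 10)), 0)
})

test_that("nucleotide preference ranks wobble-position composition", {
  expect_equal(nucleotide_preference(c("GCC", "GGC", "CTC")), "C>A=G=T")
  expect_equal(nucleotide_preference(c("GCA", "GCT")), "A=T>C=G")
  withr::with_seed(33, {
    for (i in 1:10) {
      set <- sample(sense_codons(), sample(1:10, 1))
      ranking <- nucleotide_preference(set)
      letters_only <- strsplit(gsub("[>=]", "", ranking), "")[[1]]
      expect_setequal(letters_only, c("A", "C", "G", "T"))
    }
  })
  expect_error(nucleotide_preference(character()), class = "rscuflow_error_config")
})
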