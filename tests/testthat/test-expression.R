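make_meta <- function(n = 10, tissue = rep(c("liver", "heart"), length.out = n)) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    strain = rep(c("C57BL/6", "CD-1"), length.out = n),
    tissue = tissue,
    stage = rep(10:14, length.out = n),
    library_id = paste0("SRR", 1000 + seq_len(n))
  )
}

test_that("filter_samples applies tissue and strain predicates", {
  meta <- make_meta(10, tissue = c(rep("liver", 4), rep("heart", 6)))
  expect_equal(filter_samples(meta, "liver"), paste0("s", 1:4))
  expect_equal(filter_samples(meta, "liver", strains = c("C57BL/6", "CD-1")),
               filter_samples(meta, "liver"))
  expect_equal(filter_samples(meta, "liver", strains = "C57BL/6"), c("s1", "s3"))
  expect_error(filter_samples(meta, "eye"), class = "rscuflow_error_empty_selection")
})

test_that("restrict_to_gene_set is a three-way intersection", {
  expr <- tibble::tibble(gene_id = paste0("g", 1:5), s1 = 1:5, s2 = 5:1)
  out <- restrict_to_gene_set(expr, c("g2", "g3", "g9"), paste0("g", 1:5))
  expect_equal(out$gene_id, c("g2", "g3"))
  expect_equal(out$s1, c(2, 3))
  expect_error(restrict_to_gene_set(expr, c("g9"), paste0("g", 1:5)),
               class = "rscuflow_error_empty_intersection")
  expect_error(restrict_to_gene_set(expr, c("g9"), paste0("g", 1:5)), "\\(5\\).*\\(1\\)")

  # randomized instances against a brute-force set oracle
  withr::with_seed(5, {
    for (i in 1:20) {
      genes <- paste0("g", sample(1:30, 15))
      expr_i <- tibble::tibble(gene_id = genes, s1 = stats::runif(15))
      gs <- paste0("g", sample(1:30, 10))
      cds <- paste0("g", sample(1:30, 20))
      expected <- genes[genes %in% intersect(intersect(genes, gs), cds)]
      if (length(expected) == 0) {
        expect_error(restrict_to_gene_set(expr_i, gs, cds),
                     class = "rscuflow_error_empty_intersection")
      } else {
        expect_equal(restrict_to_gene_set(expr_i, gs, cds)$gene_id, expected)
      }
    }
  })
})

two_gene_counts <- function() {
  # gene A: two GCT codons; gene B: two GCC codons
  dplyr::bind_rows(
    tibble::add_column(usage_profile(c(GCT = 2), fill = 0)[,-1], gene_id = "A", n_codons = 2, .before = 1),
    tibble::add_column(usage_profile(c(GCC = 2), fill = 0)[,-1], gene_id = "B", n_codons = 2, .before = 1)
  )
}

test_that("weighted usage matches hand arithmetic and is scale invariant", {
  counts <- two_gene_counts()
  w <- weighted_codon_usage(c(A = 10, B = 30), counts)
  expect_equal(unname(w["GCT"]), 250)
  expect_equal(unname(w["GCC"]), 750)
  expect_equal(sum(w), 1000)
  # global TPM rescaling leaves the normalized profile unchanged
  expect_equal(weighted_codon_usage(c(A = 100, B = 300), counts), w)
  # single gene: profile proportional to its codon counts
  w1 <- weighted_codon_usage(c(A = 7), counts)
  expect_equal(unname(w1["GCT"]), 1000)
  # raw weights are linear in TPM
  r1 <- weighted_codon_usage(c(A = 1, B = 2), counts, normalize = FALSE)
  r2 <- weighted_codon_usage(c(A = 5, B = 1), counts, normalize = FALSE)
  r12 <- weighted_codon_usage(c(A = 6, B = 3), counts, normalize = FALSE)
  expect_equal(r1 + r2, r12)
  expect_error(weighted_codon_usage(c(A = 0, B = 0), counts),
               class = "rscuflow_error_degenerate_sample")
})

test_that("weighted usage equals per-gene brute-force accumulation", {
  withr::with_seed(11, {
    n_genes <- 50
    seqs <- vapply(seq_len(n_genes), function(i) random_cds(sample(20:80, 1)), character(1))
    ids <- paste0("g", seq_len(n_genes))
    counts <- dplyr::bind_rows(lapply(seq_len(n_genes), function(i) {
      cc <- naive_codon_scan(seqs[i])
      tibble::add_column(tibble::as_tibble(as.list(cc)), gene_id = ids[i],
                         n_codons = sum(cc), .before = 1)
    }))
    for (rep in 1:5) {
      tpm <- stats::setNames(stats::runif(n_genes, 0, 50), ids)
      oracle <- stats::setNames(rep(0, 64), all_codons())
      for (g in ids) oracle <- oracle + tpm[[g]] * naive_codon_scan(seqs[which(ids == g)])
      expect_equal(weighted_codon_usage(tpm, counts, normalize = FALSE), oracle)
      norm <- weighted_codon_usage(tpm, counts)
      expect_equal(sum(norm), 1000, tolerance = 1e-9)
      expect_equal(norm, 1000 * oracle / sum(oracle))
    }
  })
})

test_that("weighted_usage_profiles matches the single-column operation", {
  counts <- two_gene_counts()
  expr <- tibble::tibble(gene_id = c("A", "B"), s1 = c(10, 30), s2 = c(1, 0))
  prof <- weighted_usage_profiles(expr, counts)
  expect_equal(prof$sample_id, c("s1", "s2"))
  expect_equal(as.numeric(prof[1, all_codons()]),
               unname(weighted_codon_usage(c(A = 10, B = 30), counts)))
  expect_equal(rowSums(prof[, all_codons()]), c(1000, 1000), ignore_attr = TRUE)
})

test_that("expression and metadata readers validate input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 2)), path)
  expect_equal(read_expression_matrix(path)$gene_id, c("a", "b"))
  readr::write_tsv(tibble::tibble(gene_id = c("a", "a"), s1 = c(1, 2)), path)
  expect_error(read_expression_matrix(path), class = "rscuflow_error_expression")

  mpath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(make_meta(4), mpath)
  expect_equal(nrow(read_sample_metadata(mpath)), 4)
  bad <- make_meta(4)
  bad$stage[1] <- 30
  readr::write_tsv(bad, mpath)
  expect_error(read_sample_metadata(mpath), class = "rscuflow_error_metadata")
})
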