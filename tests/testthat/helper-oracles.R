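# Independent oracles and fixture builders shared across the suite. The
# oracles deliberately use naive, brute-force implementations so they never
# share code paths with the package.

# naive triplet tally by substring scanning
naive_codon_scan <- function(sequence) {
  sequence <- toupper(sequence)
  out <- stats::setNames(rep(0, 64), all_codons())
  for (i in seq(1, nchar(sequence), by = 3)) {
    codon <- substr(sequence, i, i + 2)
    out[codon] <- out[codon] + 1
  }
  out
}

# random DNA CDS of the given codon count
random_cds <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE), collapse = "")
}

# wide usage tibble with given values for some codons, `fill` elsewhere
usage_profile <- function(values = c(), fill = 1, sample_id = "s1") {
  u <- stats::setNames(rep(fill, 64), all_codons())
  u[names(values)] <- values
  out <- tibble::as_tibble(as.list(u))
  tibble::add_column(out, sample_id = sample_id, .before = 1)
}

# n samples of strictly positive random usage
random_usage_profiles <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * 64, 0.1, 10), nrow = n,
                dimnames = list(NULL, all_codons()))
    out <- tibble::as_tibble(m)
    tibble::add_column(out, sample_id = paste0("s", seq_len(n)), .before = 1)
  })
}

# isotropic Gaussian clouds around the given centers (rows)
gaussian_clouds <- function(n_per, centers, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(stats::rnorm(n_per * ncol(centers), sd = sd), nrow = n_per) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
    rownames(x) <- paste0("s", seq_len(nrow(x)))
    list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# dense, evenly spaced clouds: jittered square grids around the centers.
# Bounded support and near-constant spacing keep the k-distance curve free
# of stragglers, the regime where the knee-based eps rule is well posed.
grid_clouds <- function(n_side, centers, spacing = 1, seed = 1) {
  withr::with_seed(seed, {
    g <- as.matrix(expand.grid(seq_len(n_side), seq_len(n_side))) * spacing
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      g + matrix(centers[i, ], nrow(g), 2, byrow = TRUE) +
        matrix(stats::runif(2 * nrow(g), -0.2, 0.2) * spacing, nrow(g))
    }))
    rownames(x) <- paste0("s", seq_len(nrow(x)))
    list(x = x, labels = rep(seq_len(nrow(centers)), each = nrow(g)))
  })
}

# brute-force pair-count Mann-Whitney oracle: enumerates every group
# assignment and counts ties with weight 1/2
mwu_enumeration_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(a, b) {
    s <- 0
    for (xi in a) for (yj in b) s <- s + (xi > yj) + 0.5 * (xi == yj)
    s
  }
  u_obs <- u_of(x, y)
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(u = u_obs, p = p)
}

# independent restatement of the consensus rule for k candidates
consensus_oracle <- function(b) {
  counts <- table(b)
  m <- max(counts)
  if (m >= 2) {
    unname(min(as.integer(names(counts)[counts == m])))
  } else {
    unname(sort(b)[2])  # lower median of four distinct values
  }
}

# healthy- and disease-weighted RSCU profiles of a generated study
study_group_rscu <- function(study) {
  expr <- study$expression
  h <- weighted_usage_profiles(
    expr[expr$gene_id %in% study$gene_sets$healthy, ], study$cds_counts)
  d <- weighted_usage_profiles(
    expr[expr$gene_id %in% study$gene_sets$disease, ], study$cds_counts)
  d$sample_id <- paste0(d$sample_id, ".disease")
  list(healthy = rscu(h), disease = rscu(d))
}
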