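#' Exact two-sided Mann-Whitney U test
#'
#' The statistic is `U = sum over pairs of [x_i > y_j] + 0.5 * [x_i = y_j]`.
#' The two-sided p-value is `P(|U' - n1*n2/2| >= |U - n1*n2/2|)` under the
#' permutation null that reassigns the pooled values to the two groups. The
#' null distribution is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments when that count is at most
#' `enum_limit`; otherwise by the exact no-ties distribution
#' ([stats::dwilcox]) when the pooled data are tie-free, and by fixed-seed
#' Monte Carlo permutation (`n_mc` draws) for large tied inputs.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param enum_limit Maximum number of assignments for full enumeration.
#' @param n_mc Monte Carlo permutations for the large-tied fallback.
#' @param seed Seed for the Monte Carlo fallback.
#' @return A list with `u`, `p`, and `method` (`"enumeration"`,
#'   `"exact_no_ties"`, or `"monte_carlo"`).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))  # u = 0, p = 0.1
#' @export
mann_whitney_exact <- function(x, y, enum_limit = 2e6, n_mc = 1e5, seed = 1L) {
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty", class = "rscuflow_error_config")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)  # midranks; U = R1 - n1(n1+1)/2 matches the pair count
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  dev_obs <- abs(u_obs - mu) - 1e-9
  n <- n1 + n2
  if (choose(n, n1) <= enum_limit) {
    idx <- utils::combn(n, n1)
    rank_sums <- colSums(matrix(ranks[idx], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= dev_obs)
    method <- "enumeration"
  } else if (!anyDuplicated(pooled)) {
    u_vals <- 0:(n1 * n2)
    dens <- stats::dwilcox(u_vals, n1, n2)
    p <- sum(dens[abs(u_vals - mu) >= dev_obs])
    method <- "exact_no_ties"
  } else {
    p <- with_seed_if(seed, {
      hits <- sum(vapply(seq_len(n_mc), function(i) {
        r <- sum(ranks[sample.int(n, n1)]) - n1 * (n1 + 1) / 2
        abs(r - mu) >= dev_obs
      }, logical(1)))
      (hits + 1) / (n_mc + 1)
    })
    method <- "monte_carlo"
  }
  list(u = u_obs, p = min(1, p), method = method)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, N * p)`. `N` defaults to the number of p-values but may
#' be larger (a wider declared family); smaller values are an error.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param n Number of comparisons in the family.
#' @return Adjusted p-values, order-preserving, each `>= p` and `<= 1`.
#' @export
bonferroni <- function(p, n = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "rscuflow_error_config")
  }
  if (n < length(p)) {
    abort("family size N cannot be smaller than the number of tests",
          class = "rscuflow_error_config")
  }
  pmin(1, n * p)
}

#' Cohen's d (unequal-variance form)
#'
#' `d = (mean(x) - mean(y)) / sqrt((s1^2 + s2^2) / 2)` with n-1 denominator
#' variances — the standard unequal-variance variant. `pooled = TRUE` uses
#' the classical pooled (n-weighted) standard deviation instead.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param pooled Use the pooled-SD form? Default `FALSE`.
#' @return The signed effect size; `d(x, y) == -d(y, x)`.
#' @export
cohens_d <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("both groups need at least 2 values", class = "rscuflow_error_config")
  }
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  denom <- if (pooled) {
    sqrt(((length(x) - 1) * v1 + (length(y) - 1) * v2) / (length(x) + length(y) - 2))
  } else {
    sqrt((v1 + v2) / 2)
  }
  if (denom == 0) {
    abort("both groups are constant: effect size undefined",
          class = "rscuflow_error_undefined_effect")
  }
  (mean(x) - mean(y)) / denom
}

#' Bin an effect size
#'
#' Contiguous bins on `|d|`: \[0, 0.2) very small, \[0.2, 0.36) small,
#' \[0.36, 0.66) medium, \[0.66, 1\] large, above 1 very large. The
#' boundaries honor the conventional printed bin edges (0.2/0.35,
#' 0.36/0.65, 0.66/0.9, >1) while leaving no gaps.
#'
#' @param d Numeric vector of effect sizes.
#' @return Character vector of bin labels.
#' @examples
#' effect_bin(c(0.21, 0.38, 0.70, 9.01))
#' @export
effect_bin <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    a < 0.2 ~ "very small",
    a < 0.36 ~ "small",
    a < 0.66 ~ "medium",
    a <= 1 ~ "large",
    TRUE ~ "very large"
  )
}

#' Codon-wise two-group comparison
#'
#' For every synonymous codon — the 59 sense codons of families with two or
#' more members; ATG and TGG have RSCU identically 1 and are untestable —
#' (optionally within strata such as embryonic
#' stages), runs the exact two-sided Mann-Whitney U test on RSCU values of
#' group A versus group B, applies the Bonferroni correction over the
#' family of tests actually performed, and annotates Cohen's d with its
#' effect bin. Codons whose RSCU is undefined (NA) anywhere in either group
#' for a stratum are skipped and reported. Significance means adjusted
#' p <= `alpha`.
#'
#' @param profiles_a,profiles_b RSCU tibbles from [rscu()] for the two
#'   groups (e.g. healthy- and disease-weighted samples).
#' @param strata Optional named vector `sample_id -> stratum` (e.g.
#'   embryonic stage). When given, tests run per (codon, stratum) with at
#'   least `min_n` samples per group in the stratum.
#' @param alpha Significance level on adjusted p-values. Default 0.05.
#' @param bonferroni_n Family size override (`NULL`: number of tests run).
#' @param min_n Minimum samples per group per stratum. Default 2.
#' @param seed Seed forwarded to the Monte Carlo fallback of
#'   [mann_whitney_exact()].
#' @return An object of class `codon_comparison`: the per-test tibble
#'   (`codon`, `aa`, `stratum`, `n1`, `n2`, `u`, `p_raw`, `p_adj`, `d`,
#'   `bin`, `significant`, `method`) with summary attributes; see
#'   [glance.codon_comparison()].
#' @export
compare_groups <- function(profiles_a, profiles_b, strata = NULL,
                           alpha = 0.05, bonferroni_n = NULL, min_n = 2,
                           seed = 1L) {
  xa <- profile_matrix(profiles_a, sense_codons())
  xb <- profile_matrix(profiles_b, sense_codons())
  aa <- codon_aa_map(sense = TRUE)
  strata_a <- if (is.null(strata)) rep("all", nrow(xa)) else as.character(strata[profiles_a$sample_id])
  strata_b <- if (is.null(strata)) rep("all", nrow(xb)) else as.character(strata[profiles_b$sample_id])
  levels_s <- sort(unique(c(strata_a, strata_b)))
  skipped <- list()
  rows <- list()
  for (s in levels_s) {
    ia <- which(strata_a == s)
    ib <- which(strata_b == s)
    if (length(ia) < min_n || length(ib) < min_n) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        codon = NA_character_, stratum = s, reason = "insufficient samples")
      next
    }
    for (codon in pca_feature_codons()) {
      va <- xa[ia, codon]
      vb <- xb[ib, codon]
      if (anyNA(va) || anyNA(vb)) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(
          codon = codon, stratum = s, reason = "undefined RSCU")
        next
      }
      mw <- mann_whitney_exact(va, vb, seed = seed)
      d <- tryCatch(cohens_d(va, vb), rscuflow_error_undefined_effect = function(e) NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        codon = codon, aa = unname(aa[codon]), stratum = s,
        n1 = length(va), n2 = length(vb),
        u = mw$u, p_raw = mw$p, d = d, method = mw$method
      )
    }
  }
  if (length(rows) == 0) {
    abort("insufficient samples in every stratum", class = "rscuflow_error_config")
  }
  res <- dplyr::bind_rows(rows)
  n_family <- bonferroni_n %||% nrow(res)
  res$p_adj <- bonferroni(res$p_raw, n_family)
  res$bin <- ifelse(is.na(res$d), NA_character_, effect_bin(res$d))
  res$significant <- res$p_adj <= alpha
  res <- res[, c("codon", "aa", "stratum", "n1", "n2", "u", "p_raw", "p_adj",
                 "d", "bin", "significant", "method")]
  codon_sig <- dplyr::summarise(dplyr::group_by(res, .data$codon),
                                any_sig = any(.data$significant), .groups = "drop")
  n_sig <- sum(res$significant)
  contribution <- dplyr::summarise(
    dplyr::group_by(res, .data$stratum),
    n_tests = dplyr::n(),
    n_significant = sum(.data$significant),
    contribution = if (n_sig > 0) sum(.data$significant) / n_sig else 0,
    .groups = "drop"
  )
  structure(
    res,
    class = c("codon_comparison", class(res)),
    alpha = alpha,
    bonferroni_n = n_family,
    fraction_significant_codons = mean(codon_sig$any_sig),
    fraction_significant_tests = mean(res$significant),
    stratum_contribution = contribution,
    skipped = if (length(skipped) > 0) dplyr::bind_rows(skipped) else NULL
  )
}

#' @export
print.codon_comparison <- function(x, ...) {
  cat(sprintf(
    "<codon_comparison> %d tests (Bonferroni N = %d, alpha = %g): %.1f%% of tests, %.1f%% of codons significant\n",
    nrow(x), attr(x, "bonferroni_n"), attr(x, "alpha"),
    100 * attr(x, "fraction_significant_tests"),
    100 * attr(x, "fraction_significant_codons")
  ))
  NextMethod()
}

#' @describeIn compare_groups The per-test results as a plain tibble.
#' @param x A `codon_comparison`.
#' @param ... Unused.
#' @export
tidy.codon_comparison <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attributes(out)[setdiff(names(attributes(out)), c("names", "row.names", "class"))] <- NULL
  out
}

#' One-row summary of a codon comparison
#'
#' Reports the significant fractions (per test and per codon), the family
#' size, and the top-decile absolute effect size.
#'
#' @param x A `codon_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.codon_comparison <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    bonferroni_n = attr(x, "bonferroni_n"),
    alpha = attr(x, "alpha"),
    fraction_significant_tests = attr(x, "fraction_significant_tests"),
    fraction_significant_codons = attr(x, "fraction_significant_codons"),
    top_decile_abs_d = stats::quantile(abs(x$d), 0.9, na.rm = TRUE, names = FALSE)
  )
}

#' @describeIn compare_groups Per-stratum share of the significant results.
#' @export
stratum_contribution <- function(x) {
  attr(x, "stratum_contribution")
}
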