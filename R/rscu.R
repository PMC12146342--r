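#' Relative synonymous codon usage
#'
#' For codon c encoding amino acid a with degeneracy k, RSCU(c) is the
#' usage of c divided by the mean usage of a's synonymous family:
#' `rscu(c) = usage(c) * k / sum(usage over family)`. A value of 1 means no
#' bias. Stop codons are excluded; codons of a family whose total usage is
#' zero are undefined (`NA`). RSCU is invariant to rescaling the usage
#' vector, so raw and per-1,000 profiles give identical results.
#'
#' @param profiles Wide usage tibble (`sample_id` + at least the 61 sense
#'   codon columns), e.g. from [weighted_usage_profiles()].
#' @return A tibble with `sample_id` and the 61 sense-codon columns holding
#'   RSCU values (`NA` where undefined).
#' @examples
#' u <- tibble::tibble(sample_id = "s1", TTT = 3, TTC = 1)
#' full <- tibble::as_tibble(as.list(stats::setNames(rep(1, 64), all_codons())))
#' full[c("TTT", "TTC")] <- list(3, 1)
#' rscu(dplyr::bind_cols(tibble::tibble(sample_id = "s1"), full))[, c("TTT", "TTC")]
#' @export
rscu <- function(profiles) {
  usage <- profile_matrix(profiles, sense_codons())
  if (any(usage < 0, na.rm = TRUE)) {
    abort("usage values must be non-negative", class = "rscuflow_error_rscu")
  }
  fams <- synonymous_families()
  out <- usage
  for (codons in fams) {
    fam_total <- rowSums(usage[, codons, drop = FALSE])
    k <- length(codons)
    vals <- usage[, codons, drop = FALSE] * k / fam_total
    vals[fam_total == 0, ] <- NA_real_
    out[, codons] <- vals
  }
  matrix_profile(out, sample_id = profiles$sample_id)
}

#' Classify codon representation
#'
#' Calls a codon overrepresented when RSCU is at least `hi` (default 1.5)
#' and underrepresented when at most `lo` (default 0.5); both thresholds
#' are inclusive. Undefined RSCU values stay `"undefined"`.
#'
#' @param rscu_profiles RSCU tibble from [rscu()] (or any tibble of RSCU
#'   columns plus `sample_id`).
#' @param hi,lo Over-/under-representation thresholds, `hi > lo > 0`.
#' @return Tibble of the same shape with character classes `"over"`,
#'   `"under"`, `"neutral"`, `"undefined"`.
#' @export
classify_representation <- function(rscu_profiles, hi = 1.5, lo = 0.5) {
  stopifnot_scalar_number(hi, "hi")
  stopifnot_scalar_number(lo, "lo")
  if (!(hi > lo && lo > 0)) {
    abort("thresholds must satisfy hi > lo > 0", class = "rscuflow_error_config")
  }
  vals <- profile_matrix(rscu_profiles)
  cls <- matrix("neutral", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  cls[vals >= hi] <- "over"
  cls[vals <= lo] <- "under"
  cls[is.na(vals)] <- "undefined"
  out <- tibble::as_tibble(cls)
  tibble::add_column(out, sample_id = rscu_profiles$sample_id, .before = 1)
}

#' Summarize RSCU over a sample group
#'
#' Per-codon sample mean and standard deviation (n - 1 denominator) over
#' defined values. With a single defined value the SD is reported as 0 and
#' flagged.
#'
#' @param rscu_profiles RSCU tibble from [rscu()].
#' @param label Group label to attach.
#' @return A tibble with columns `group`, `codon`, `aa`, `label`
#'   (AA-codon), `mean`, `sd`, `n`, `sd_degenerate`.
#' @export
summarize_group <- function(rscu_profiles, label = "group") {
  if (nrow(rscu_profiles) == 0) {
    abort("empty profile list", class = "rscuflow_error_empty_selection")
  }
  vals <- profile_matrix(rscu_profiles)
  aa <- codon_aa_map(sense = TRUE)
  n <- colSums(!is.na(vals))
  mu <- colMeans(vals, na.rm = TRUE)
  sd <- apply(vals, 2, stats::sd, na.rm = TRUE)
  sd[n <= 1] <- 0
  mu[n == 0] <- NA_real_
  tibble::tibble(
    group = label,
    codon = colnames(vals),
    aa = unname(aa[colnames(vals)]),
    label = codon_label(colnames(vals)),
    mean = unname(mu),
    sd = unname(sd),
    n = unname(n),
    sd_degenerate = unname(n <= 1)
  )
}

#' Classify an external codon-usage table
#'
#' Converts a genomic or tissue codon-usage table (64 or 61 codon
#' frequencies) to RSCU and classifies representation with the same code
#' path and thresholds as internal profiles.
#'
#' @param usage Named numeric vector of codon usage (61 or 64 codons), or a
#'   single-row wide tibble.
#' @inheritParams classify_representation
#' @return A tibble with `codon`, `aa`, `label`, `rscu`, `class`.
#' @export
classify_external_usage <- function(usage, hi = 1.5, lo = 0.5) {
  if (is.data.frame(usage)) {
    tbl <- usage
    if (!"sample_id" %in% names(tbl)) {
      tbl <- tibble::add_column(tbl, sample_id = "external", .before = 1)
    }
  } else {
    missing <- setdiff(sense_codons(), names(usage))
    if (length(missing) > 0) {
      abort(paste0("usage table missing codons: ", paste(utils::head(missing, 10), collapse = ", ")),
            class = "rscuflow_error_missing_codons")
    }
    tbl <- matrix_profile(matrix(usage[sense_codons()], nrow = 1,
                                 dimnames = list(NULL, sense_codons())),
                          sample_id = "external")
  }
  r <- rscu(tbl)
  cls <- classify_representation(r, hi = hi, lo = lo)
  aa <- codon_aa_map(sense = TRUE)
  tibble::tibble(
    codon = sense_codons(),
    aa = unname(aa[sense_codons()]),
    label = codon_label(sense_codons()),
    rscu = as.numeric(r[1, sense_codons()]),
    class = as.character(cls[1, sense_codons()])
  )
}
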