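# Contingency-table agreement metrics between a clustering and a reference
# labeling. Definitions follow the standard information-theoretic forms:
# ARI via the pair-counting formula; AMI with the hypergeometric expected
# mutual information and arithmetic-mean normalization; V-measure as the
# harmonic mean of homogeneity and completeness.

contingency <- function(labels, reference) {
  table(factor(labels), factor(reference))
}

adjusted_rand_index <- function(labels, reference) {
  tab <- contingency(labels, reference)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both labelings trivial
  (sum_ij - expected) / (max_index - expected)
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

mutual_information <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + (nij / n) * log(nij * n / (a[i] * b[j]))
    }
  }
  mi
}

# expected MI under the permutation (hypergeometric) model
expected_mutual_information <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      # P(N_ij = nij) hypergeometric
      logp <- stats::dhyper(nij, bj, n - bj, ai, log = TRUE)
      term <- (nij / n) * log(nij * n / (ai * bj))
      emi <- emi + sum(exp(logp) * term)
    }
  }
  emi
}

adjusted_mutual_information <- function(labels, reference) {
  tab <- contingency(labels, reference)
  h_u <- entropy_counts(rowSums(tab))
  h_v <- entropy_counts(colSums(tab))
  if (h_u == 0 && h_v == 0) return(1)
  mi <- mutual_information(tab)
  emi <- expected_mutual_information(tab)
  denom <- (h_u + h_v) / 2 - emi
  if (denom == 0) return(0)
  unname((mi - emi) / denom)
}

homogeneity_completeness <- function(labels, reference) {
  tab <- contingency(labels, reference)
  h_c <- entropy_counts(colSums(tab))  # reference classes
  h_k <- entropy_counts(rowSums(tab))  # clusters
  mi <- mutual_information(tab)
  homogeneity <- if (h_c == 0) 1 else mi / h_c
  completeness <- if (h_k == 0) 1 else mi / h_k
  v <- if (homogeneity + completeness == 0) 0 else {
    2 * homogeneity * completeness / (homogeneity + completeness)
  }
  c(homogeneity = unname(homogeneity), completeness = unname(completeness),
    v_measure = unname(v))
}

#' Validate a clustering against reference labels
#'
#' Computes the adjusted Rand index, adjusted mutual information, V-measure,
#' homogeneity and completeness of a cluster assignment versus an external
#' reference labeling (tissue state or embryonic day). Noise points (label
#' -1 from the density-based method) are kept as their own singleton-style
#' category by default; `drop_noise = TRUE` excludes them instead.
#'
#' @param assignment A `cluster_assignment` (or tibble with `sample_id`,
#'   `cluster`).
#' @param reference Named vector `sample_id -> label`, or a tibble with
#'   `sample_id` and a label column.
#' @param reference_name Name recorded for the reference labeling.
#' @param drop_noise Exclude noise points from the metrics? Default `FALSE`.
#' @return A one-row tibble: `method`, `reference`, `ari`, `ami`,
#'   `v_measure`, `homogeneity`, `completeness`, `n`.
#' @export
evaluate_clustering <- function(assignment, reference,
                                reference_name = "reference",
                                drop_noise = FALSE) {
  if (is.data.frame(reference)) {
    lab_col <- setdiff(names(reference), "sample_id")[1]
    reference <- stats::setNames(reference[[lab_col]], reference$sample_id)
  }
  if (!setequal(assignment$sample_id, names(reference))) {
    abort("assignment and reference cover different sample sets",
          class = "rscuflow_error_sample_mismatch")
  }
  ref <- reference[assignment$sample_id]
  labels <- assignment$cluster
  if (drop_noise) {
    keep <- labels != -1L
    labels <- labels[keep]
    ref <- ref[keep]
  }
  hc <- homogeneity_completeness(labels, ref)
  tibble::tibble(
    method = attr(assignment, "method") %||% "unknown",
    reference = reference_name,
    ari = adjusted_rand_index(labels, ref),
    ami = adjusted_mutual_information(labels, ref),
    v_measure = unname(hc["v_measure"]),
    homogeneity = unname(hc["homogeneity"]),
    completeness = unname(hc["completeness"]),
    n = length(labels)
  )
}

#' Select the best clustering method
#'
#' Scores each method by the mean of the five validation metrics averaged
#' over the reference labelings (tissue state and embryonic day in the
#' standard pipeline) and returns the arg-max. Ties are broken by ARI on
#' the tissue-state reference, then by the fixed order agglomerative,
#' kmeans, spectral, dbscan.
#'
#' @param evaluations Tibble of rows from [evaluate_clustering()] covering
#'   one or more methods and references.
#' @param tie_reference Reference name used for the ARI tie-break.
#' @return The winning method name (the full ranking is attached as
#'   attribute `ranking`).
#' @export
select_best_method <- function(evaluations, tie_reference = "tissue_state") {
  if (nrow(evaluations) == 0) {
    abort("no evaluations to select from", class = "rscuflow_error_config")
  }
  metric_cols <- c("ari", "ami", "v_measure", "homogeneity", "completeness")
  per_ref <- dplyr::summarise(
    dplyr::group_by(evaluations, .data$method, .data$reference),
    score = mean(unlist(dplyr::pick(dplyr::all_of(metric_cols)))),
    .groups = "drop"
  )
  ranking <- dplyr::summarise(
    dplyr::group_by(per_ref, .data$method),
    score = mean(.data$score),
    .groups = "drop"
  )
  tie_ari <- dplyr::filter(evaluations, .data$reference == tie_reference)
  tie_ari <- dplyr::summarise(dplyr::group_by(tie_ari, .data$method),
                              tie_ari = mean(.data$ari), .groups = "drop")
  ranking <- dplyr::left_join(ranking, tie_ari, by = "method")
  ranking$tie_ari[is.na(ranking$tie_ari)] <- -Inf
  order_fixed <- c("agglomerative", "kmeans", "spectral", "dbscan")
  ranking$order_rank <- match(ranking$method, order_fixed)
  ranking$order_rank[is.na(ranking$order_rank)] <- length(order_fixed) + 1
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$score),
                            dplyr::desc(.data$tie_ari), .data$order_rank)
  structure(ranking$method[1], ranking = ranking)
}
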