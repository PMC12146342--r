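#' Select the 59-codon PCA feature set
#'
#' Drops the three stop codons (TGA, TAG, TAA) and the two degeneracy-1
#' codons ATG (Met) and TGG (Trp) — whose RSCU is identically 1 — leaving
#' exactly 59 codon features. Idempotent.
#'
#' @param profiles Wide tibble (`sample_id` + codon columns; 64- or
#'   61-codon input accepted).
#' @return Tibble with `sample_id` and the 59 feature codons.
#' @export
select_codon_features <- function(profiles) {
  feats <- pca_feature_codons()
  missing <- setdiff(feats, names(profiles))
  if (length(missing) > 0) {
    abort(paste0("missing expected codon columns: ", paste(utils::head(missing, 10), collapse = ", ")),
          class = "rscuflow_error_missing_codons")
  }
  dplyr::select(profiles, "sample_id", dplyr::all_of(feats))
}

#' Standardize feature columns
#'
#' Centers each feature to mean 0 and scales to unit standard deviation,
#' using the population (n) denominator. Zero-variance columns are set to 0
#' and flagged.
#'
#' @param features Wide tibble (`sample_id` + numeric feature columns).
#' @return The standardized tibble, with attributes `center`, `scale`
#'   (named numeric) and `constant` (logical per feature).
#' @export
standardize_features <- function(features) {
  x <- profile_matrix(features, setdiff(names(features), "sample_id"))
  if (nrow(x) < 2) {
    abort("standardization needs at least 2 samples", class = "rscuflow_error_config")
  }
  center <- colMeans(x)
  n <- nrow(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))  # population sd
  constant <- scale == 0
  scale_use <- ifelse(constant, 1, scale)
  z <- sweep(sweep(x, 2, center), 2, scale_use, "/")
  z[, constant] <- 0
  out <- matrix_profile(z, sample_id = features$sample_id)
  attr(out, "center") <- center
  attr(out, "scale") <- scale_use
  attr(out, "constant") <- constant
  out
}

#' Fit a PCA on the codon feature space
#'
#' Standardizes the features (population-SD z-scores), runs a principal
#' component analysis, and retains `K = min(cap, k80)` components, where
#' k80 is the smallest number of components whose cumulative explained
#' variance reaches `var_threshold`. Component signs are fixed by forcing
#' each component's largest-magnitude loading positive, so reported
#' positively/negatively correlated codon sets are reproducible.
#'
#' @param features Wide tibble of codon features, e.g. from
#'   [select_codon_features()] (optionally batch-adjusted).
#' @param var_threshold Cumulative explained-variance target in (0, 1].
#'   Default 0.80.
#' @param cap Maximum number of retained components. Default 5.
#' @return An object of class `codon_pca`: a list with `center`, `scale`,
#'   `loadings` (features x K), `loadings_full`, `explained_variance_ratio`
#'   (all components), `k`, and `scores` (tibble `sample_id` + `PC1..PCK`).
#' @export
fit_codon_pca <- function(features, var_threshold = 0.80, cap = 5) {
  stopifnot_scalar_number(var_threshold, "var_threshold")
  if (var_threshold <= 0 || var_threshold > 1) {
    abort("var_threshold must be in (0, 1]", class = "rscuflow_error_config")
  }
  z <- standardize_features(features)
  x <- profile_matrix(z, setdiff(names(z), "sample_id"))
  sv <- svd(x)
  evr <- sv$d^2 / sum(sv$d^2)
  # sign fix: largest-|loading| entry of each component positive
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  v <- sweep(sv$v, 2, flip, "*")
  rownames(v) <- colnames(x)
  k80 <- which(cumsum(evr) >= var_threshold - 1e-12)[1]
  if (is.na(k80)) k80 <- length(evr)
  k <- min(cap, k80)
  scores_full <- x %*% v
  colnames(scores_full) <- paste0("PC", seq_len(ncol(scores_full)))
  scores <- tibble::as_tibble(scores_full[, seq_len(k), drop = FALSE])
  scores <- tibble::add_column(scores, sample_id = features$sample_id, .before = 1)
  structure(
    list(
      center = attr(z, "center"),
      scale = attr(z, "scale"),
      constant = attr(z, "constant"),
      loadings = v[, seq_len(k), drop = FALSE],
      loadings_full = v,
      explained_variance_ratio = evr,
      k = k,
      k80 = k80,
      var_threshold = var_threshold,
      cap = cap,
      scores = scores,
      n_samples = nrow(x)
    ),
    class = "codon_pca"
  )
}

#' @export
print.codon_pca <- function(x, ...) {
  cat(sprintf(
    "<codon_pca> %d samples, %d features; K = %d (k80 = %d, cap = %d); cumulative EVR = %.3f\n",
    x$n_samples, nrow(x$loadings), x$k, x$k80, x$cap,
    sum(x$explained_variance_ratio[seq_len(x$k)])
  ))
  invisible(x)
}

#' @describeIn fit_codon_pca Long tibble of loadings (`pc`, `codon`, `aa`,
#'   `loading`) for the retained components.
#' @param x A `codon_pca` object.
#' @param ... Unused.
#' @export
tidy.codon_pca <- function(x, ...) {
  aa <- codon_aa_map(sense = TRUE)
  tibble::tibble(
    pc = rep(seq_len(x$k), each = nrow(x$loadings)),
    codon = rep(rownames(x$loadings), x$k),
    aa = unname(aa[rep(rownames(x$loadings), x$k)]),
    loading = as.numeric(x$loadings)
  )
}

#' @describeIn fit_codon_pca One-row model summary.
#' @export
glance.codon_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    n_features = nrow(x$loadings_full),
    k = x$k,
    k80 = x$k80,
    cumulative_evr = sum(x$explained_variance_ratio[seq_len(x$k)])
  )
}

#' Third-position nucleotide preference of a codon set
#'
#' Counts wobble-position (or all-position) nucleotides across a codon set
#' and formats a ranking such as `"C>G>T>A"`, using `=` between tied counts
#' (ties displayed alphabetically).
#'
#' @param codon_set Non-empty character vector of codons.
#' @param position `"third"` (default) or `"all"`.
#' @return A ranking string over A, C, G, T.
#' @examples
#' nucleotide_preference(c("GCC", "GGC", "CTC"))
#' @export
nucleotide_preference <- function(codon_set, position = c("third", "all")) {
  position <- match.arg(position)
  if (length(codon_set) == 0) {
    abort("empty codon set", class = "rscuflow_error_config")
  }
  chars <- if (position == "third") {
    substr(codon_set, 3, 3)
  } else {
    unlist(strsplit(codon_set, ""))
  }
  counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
  ord <- order(-as.numeric(counts), names(counts))
  sorted <- counts[ord]
  seps <- ifelse(diff(as.numeric(sorted)) == 0, "=", ">")
  paste0(names(sorted), c(seps, ""), collapse = "")
}

#' Loading-interpretation report
#'
#' For each retained component, lists codons whose loading magnitude passes
#' the cutoff (default 0.2), split into positively (`+corr`) and negatively
#' (`-corr`) correlated sets. An amino acid is *highlighted* only when at
#' least two of its synonymous codons pass the cutoff on that component
#' (by default pooled across signs; set `per_sign = TRUE` to count within
#' each sign). All passing codons stay in the raw listing either way.
#'
#' @param model A `codon_pca` object.
#' @param cutoff Absolute loading cutoff. Default 0.2.
#' @param per_sign Count the two-codon rule within each sign separately?
#'   Default `FALSE`.
#' @return A list with `codons` (tibble: `pc`, `codon`, `aa`, `loading`,
#'   `direction`, `highlighted`) and `preferences` (tibble: `pc`,
#'   `direction`, `n_codons`, `nucleotide_preference`).
#' @export
loading_report <- function(model, cutoff = 0.2, per_sign = FALSE) {
  ld <- tidy(model)
  passing <- dplyr::filter(ld, abs(.data$loading) >= cutoff)
  passing <- dplyr::mutate(
    passing,
    direction = ifelse(.data$loading >= 0, "+corr", "-corr")
  )
  grouping <- if (per_sign) c("pc", "aa", "direction") else c("pc", "aa")
  passing <- dplyr::mutate(
    dplyr::group_by(passing, dplyr::across(dplyr::all_of(grouping))),
    highlighted = dplyr::n() >= 2
  )
  passing <- dplyr::ungroup(passing)
  prefs <- if (nrow(passing) == 0) {
    tibble::tibble(pc = integer(), direction = character(),
                   n_codons = integer(), nucleotide_preference = character())
  } else {
    dplyr::summarise(
      dplyr::group_by(passing, .data$pc, .data$direction),
      n_codons = dplyr::n(),
      nucleotide_preference = nucleotide_preference(.data$codon),
      .groups = "drop"
    )
  }
  list(codons = passing, preferences = prefs)
}

#' Describe high-scoring samples
#'
#' Lists samples whose score on a retained component exceeds the threshold
#' (strictly greater than 5 by default, matching the signed-score rule);
#' `absolute = TRUE` applies the rule to score magnitudes instead. Each
#' descriptor carries the component's positively and negatively correlated
#' codon sets from [loading_report()].
#'
#' @param model A `codon_pca` object.
#' @param score_threshold Score cutoff. Default 5.
#' @param absolute Use `|score| > threshold`? Default `FALSE`.
#' @param cutoff Loading cutoff forwarded to [loading_report()].
#' @return Tibble with `sample_id`, `pc`, `score`, `direction`,
#'   `pos_codons`, `neg_codons` (list columns).
#' @export
describe_samples <- function(model, score_threshold = 5, absolute = FALSE,
                             cutoff = 0.2) {
  rep <- loading_report(model, cutoff = cutoff)
  long <- tidyr::pivot_longer(model$scores, -"sample_id",
                              names_to = "pc", values_to = "score")
  long$pc <- as.integer(sub("^PC", "", long$pc))
  keep <- if (absolute) abs(long$score) > score_threshold else long$score > score_threshold
  long <- long[keep, , drop = FALSE]
  pos <- split(rep$codons$codon[rep$codons$direction == "+corr"],
               rep$codons$pc[rep$codons$direction == "+corr"])
  neg <- split(rep$codons$codon[rep$codons$direction == "-corr"],
               rep$codons$pc[rep$codons$direction == "-corr"])
  tibble::tibble(
    sample_id = long$sample_id,
    pc = long$pc,
    score = long$score,
    direction = ifelse(long$score >= 0, "positive", "negative"),
    pos_codons = unname(lapply(as.character(long$pc), function(p) pos[[p]] %||% character())),
    neg_codons = unname(lapply(as.character(long$pc), function(p) neg[[p]] %||% character()))
  )
}

#' @describeIn fit_codon_pca Score scatter plot of two components.
#' @param object A `codon_pca` object.
#' @param pcs Two component indices to plot.
#' @param colour Optional vector (one value per sample) used to colour
#'   points, e.g. tissue state or cluster labels.
#' @export
autoplot.codon_pca <- function(object, pcs = c(1, 2), colour = NULL, ...) {
  pcs <- pcs[pcs <= object$k]
  if (length(pcs) < 2) pcs <- c(1, min(2, object$k))
  df <- object$scores
  xv <- paste0("PC", pcs[1])
  yv <- if (object$k >= 2) paste0("PC", pcs[2]) else xv
  evr <- object$explained_variance_ratio
  if (!is.null(colour)) df$.colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xv]], y = .data[[yv]])) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xv, 100 * evr[pcs[1]]),
      y = sprintf("%s (%.1f%%)", yv, 100 * evr[min(pcs[2], length(evr))])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$.colour)) +
      ggplot2::labs(colour = NULL)
  }
}
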