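#' Knee/elbow point of a convex curve
#'
#' Kneedle-style detection: x and y are min-max normalized and the elbow is
#' the point of maximum gap below the chord joining the endpoints. The two
#' uses in this package are the inertia-vs-k elbow (`decreasing = TRUE`)
#' and the sorted k-distance plot (`decreasing = FALSE`).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param decreasing Is the curve decreasing in x? Default `TRUE`.
#' @return The x value at the knee, or `NA` if no knee exists.
#' @keywords internal
find_knee <- function(x, y, decreasing = TRUE) {
  n <- length(x)
  if (n < 3 || diff(range(y)) == 0) return(NA_real_)
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  # elbow of a convex curve = point of maximum gap below the chord joining
  # the endpoints: (1 - xn) - yn for decreasing curves, xn - yn for
  # increasing ones (sorted k-distance plots)
  diffc <- if (decreasing) (1 - xn) - yn else xn - yn
  i <- which.max(diffc)
  if (diffc[i] <= 0) return(NA_real_)
  x[i]
}

# inertia (within-cluster sum of squares) of a labeled partition
partition_inertia <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xi <- x[idx, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

# Calinski-Harabasz pseudo-F of a labeled partition
calinski_harabasz <- function(x, labels) {
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  w <- partition_inertia(x, labels)
  b <- sum(vapply(split(seq_len(n), labels), function(idx) {
    length(idx) * sum((colMeans(x[idx, , drop = FALSE]) - grand)^2)
  }, numeric(1)))
  (b / (k - 1)) / (w / (n - k))
}

# Davies-Bouldin index (lower = better separated, less dispersed)
davies_bouldin <- function(x, labels) {
  groups <- split(seq_len(nrow(x)), labels)
  k <- length(groups)
  if (k < 2) return(NA_real_)
  cents <- t(vapply(groups, function(idx) colMeans(x[idx, , drop = FALSE]),
                    numeric(ncol(x))))
  disp <- vapply(seq_along(groups), function(i) {
    xi <- x[groups[[i]], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cents[i, ])^2)))
  }, numeric(1))
  dmat <- as.matrix(stats::dist(cents))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) (disp[i] + disp[j]) / dmat[i, j],
               numeric(1)))
  }, numeric(1))
  mean(r)
}

mean_silhouette <- function(x, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Scan cluster numbers with four heuristics
#'
#' For each candidate k, partitions the score matrix with a centroid-based
#' reference clustering (k-means) and records the silhouette coefficient,
#' Calinski-Harabasz score, inertia, and Davies-Bouldin index. The best k
#' per heuristic is the silhouette maximum, the CH maximum, the knee of the
#' inertia curve, and the DB minimum; the four candidates are combined by
#' [consensus_k()].
#'
#' @param scores Wide tibble (`sample_id` + numeric columns, e.g. PCA
#'   scores) or a numeric matrix.
#' @param k_range Candidate cluster numbers; default `2:min(10, n - 1)`.
#' @param seed Seed for the reference k-means initializations.
#' @return An object of class `heuristic_report`: list with `curves`
#'   (tibble k x heuristic values), `best_k` (named integer vector), and
#'   `consensus_k`.
#' @export
heuristic_scan <- function(scores, k_range = NULL, seed = 1L) {
  x <- as_score_matrix(scores)
  n <- nrow(x)
  if (n < 3) abort("need at least 3 samples", class = "rscuflow_error_config")
  if (is.null(k_range)) k_range <- 2:min(10, n - 1)
  if (any(k_range < 2 | k_range > n - 1)) {
    abort("k_range must lie within [2, n - 1]", class = "rscuflow_error_config")
  }
  curves <- with_seed_if(seed, {
    purrr::map_dfr(k_range, function(k) {
      km <- stats::kmeans(x, centers = k, nstart = 10, iter.max = 50)
      tibble::tibble(
        k = k,
        silhouette = mean_silhouette(x, km$cluster),
        calinski_harabasz = calinski_harabasz(x, km$cluster),
        inertia = km$tot.withinss,
        davies_bouldin = davies_bouldin(x, km$cluster)
      )
    })
  })
  # anchor the elbow scan at k = 1 (total sum of squares) so a true elbow at
  # the smallest candidate k remains detectable; a knee at 1 maps to min(k)
  inertia1 <- sum(sweep(x, 2, colMeans(x))^2)
  knee <- find_knee(c(1L, curves$k), c(inertia1, curves$inertia), decreasing = TRUE)
  if (!is.na(knee) && knee < min(k_range)) knee <- min(k_range)
  best <- c(
    silhouette = curves$k[which.max(curves$silhouette)],
    calinski_harabasz = curves$k[which.max(curves$calinski_harabasz)],
    inertia = if (is.na(knee)) curves$k[1] else as.integer(knee),
    davies_bouldin = curves$k[which.min(curves$davies_bouldin)]
  )
  if (length(k_range) == 1) best[] <- k_range
  structure(
    list(curves = curves, best_k = best, consensus_k = consensus_k(best)),
    class = "heuristic_report"
  )
}

#' Consensus cluster number
#'
#' If two or more heuristics agree on a best k, that modal value wins (two
#' modes tied at multiplicity two: the smaller k, for parsimony). With no
#' agreement, the lower median (second order statistic) of the four values
#' is used, guaranteeing an integer from the candidate set.
#'
#' @param best_k Integer vector of per-heuristic best k values (length 4 in
#'   the standard scan).
#' @return A single integer.
#' @examples
#' consensus_k(c(3, 3, 5, 2))  # 3: two agree
#' consensus_k(c(2, 3, 4, 6))  # 3: lower median
#' @export
consensus_k <- function(best_k) {
  best_k <- as.integer(best_k)
  tab <- table(best_k)
  if (max(tab) >= 2) {
    modes <- as.integer(names(tab)[tab == max(tab)])
    return(min(modes))
  }
  sorted <- sort(best_k)
  sorted[ceiling(length(sorted) / 2)]
}

#' @export
print.heuristic_report <- function(x, ...) {
  cat("<heuristic_report> best k per heuristic:\n")
  print(x$best_k)
  cat("consensus k:", x$consensus_k, "\n")
  invisible(x)
}

#' @describeIn heuristic_scan Heuristic curves, one panel per metric.
#' @param object A `heuristic_report`.
#' @param ... Unused.
#' @export
autoplot.heuristic_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves, -"k",
                              names_to = "heuristic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~heuristic, scales = "free_y") +
    ggplot2::theme_minimal()
}

# accept tibble-with-sample_id or plain matrix
as_score_matrix <- function(scores) {
  if (is.matrix(scores)) {
    if (is.null(rownames(scores))) rownames(scores) <- paste0("s", seq_len(nrow(scores)))
    return(scores)
  }
  profile_matrix(scores, setdiff(names(scores), "sample_id"))
}
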