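# All clustering front-ends return a `cluster_assignment`: a tibble with
# sample_id and an integer cluster column (noise = -1, density-based method
# only), plus attributes method/parameters (and the linkage tree for the
# agglomerative method).

new_cluster_assignment <- function(sample_id, cluster, method, parameters,
                                   tree = NULL) {
  out <- tibble::tibble(sample_id = sample_id, cluster = as.integer(cluster))
  structure(out, method = method, parameters = parameters, tree = tree,
            class = c("cluster_assignment", class(out)))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  pars <- attr(x, "parameters")
  cat(sprintf("<cluster_assignment> method = %s; %d samples, %d cluster(s)%s\n",
              attr(x, "method"), nrow(x),
              length(setdiff(unique(x$cluster), -1L)),
              if (any(x$cluster == -1L)) sprintf(", %d noise", sum(x$cluster == -1L)) else ""))
  cat("parameters:", paste(names(pars), unlist(pars), sep = "=", collapse = ", "), "\n")
  NextMethod()
}

#' K-means with subsample-seeded centers
#'
#' Two-stage protocol: stage one draws 30% of the samples without
#' replacement and runs five random initializations, each capped at three
#' Lloyd iterations, keeping the centers with the lowest subsample inertia;
#' stage two runs full-data Lloyd iterations from those centers to
#' convergence. If the 30% subsample is smaller than k, stage one falls
#' back to the full data (with a message).
#'
#' @param scores Score tibble (`sample_id` + numeric columns) or matrix.
#' @param k Number of clusters.
#' @param seed Seed making the run reproducible.
#' @param subsample_frac,n_attempts,n_iter Stage-one protocol parameters.
#' @return A `cluster_assignment`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1L, subsample_frac = 0.3,
                           n_attempts = 5, n_iter = 3) {
  x <- as_score_matrix(scores)
  n <- nrow(x)
  if (k > n) abort("k exceeds the number of samples", class = "rscuflow_error_config")
  if (k == 1) {
    return(new_cluster_assignment(rownames(x), rep(1L, n), "kmeans",
                                  list(k = 1, seed = seed)))
  }
  with_seed_if(seed, {
    m <- floor(subsample_frac * n)
    if (m < k) {
      inform("30% subsample smaller than k; using full data for stage one")
      sub <- x
    } else {
      sub <- x[sample.int(n, m), , drop = FALSE]
    }
    best <- NULL
    for (i in seq_len(n_attempts)) {
      km <- suppressWarnings(
        stats::kmeans(sub, centers = k, iter.max = n_iter, nstart = 1,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    final <- suppressWarnings(
      stats::kmeans(x, centers = best$centers, iter.max = 100,
                    algorithm = "Lloyd")
    )
    new_cluster_assignment(
      rownames(x), final$cluster, "kmeans",
      list(k = k, seed = seed, subsample_frac = subsample_frac,
           n_attempts = n_attempts, n_iter = n_iter,
           inertia = final$tot.withinss)
    )
  })
}

# symmetric affinity -> spectral embedding -> k-means labels
spectral_labels <- function(a, k, seed) {
  d <- rowSums(a)
  d[d == 0] <- 1e-12
  dhalf <- 1 / sqrt(d)
  m <- a * tcrossprod(dhalf)             # D^-1/2 A D^-1/2
  eig <- eigen(m, symmetric = TRUE)
  u <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  with_seed_if(seed, stats::kmeans(u, centers = k, nstart = 10, iter.max = 50)$cluster)
}

knn_affinity <- function(x, n_neighbors) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:min(n, n_neighbors + 1)]
    a[i, nb] <- 1
  }
  (a + t(a)) > 0  # symmetrized connectivity
}

graph_connected <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(a[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Spectral clustering with dual affinities
#'
#' Rows are L2-normalized before the embedding. Two affinities are fitted —
#' a Gaussian (rbf) kernel and a symmetrized nearest-neighbor connectivity
#' graph with `n_neighbors = max(1, floor(n / 4))` — and the labeling with
#' the higher silhouette score (on the normalized data) is kept. A
#' disconnected neighbor graph falls back to the Gaussian kernel with a
#' warning.
#'
#' @inheritParams kmeans_cluster
#' @param gamma Gaussian kernel width parameter, `exp(-gamma * d^2)`.
#' @return A `cluster_assignment`; `parameters$affinity` records the choice.
#' @export
spectral_cluster <- function(scores, k, seed = 1L, gamma = 1) {
  x <- as_score_matrix(scores)
  n <- nrow(x)
  if (k > n) abort("k exceeds the number of samples", class = "rscuflow_error_config")
  rn <- sqrt(rowSums(x^2))
  rn[rn == 0] <- 1
  xn <- x / rn
  n_neighbors <- max(1, floor(n / 4))
  d2 <- as.matrix(stats::dist(xn))^2
  a_rbf <- exp(-gamma * d2)
  diag(a_rbf) <- 0
  lab_rbf <- spectral_labels(a_rbf, k, seed)
  a_knn <- knn_affinity(xn, n_neighbors)
  if (!graph_connected(a_knn)) {
    warn("nearest-neighbor affinity graph is disconnected; using the Gaussian kernel")
    labels <- lab_rbf
    affinity <- "rbf"
  } else {
    lab_knn <- spectral_labels(a_knn * 1, k, seed)
    sil <- c(rbf = mean_silhouette(xn, lab_rbf), knn = mean_silhouette(xn, lab_knn))
    sil[is.na(sil)] <- -Inf
    if (sil["knn"] > sil["rbf"]) {
      labels <- lab_knn
      affinity <- "nearest_neighbors"
    } else {
      labels <- lab_rbf
      affinity <- "rbf"
    }
  }
  new_cluster_assignment(
    rownames(x), labels, "spectral",
    list(k = k, seed = seed, n_neighbors = n_neighbors, gamma = gamma,
         affinity = affinity)
  )
}

#' Density-based clustering (DBSCAN)
#'
#' `min_samples` is twice the number of retained PCA dimensions; `eps` is
#' taken at the knee of the sorted `min_samples`-th nearest-neighbor
#' distance curve unless given explicitly. Noise points are labeled `-1`.
#' If every point ends up noise the result is flagged degenerate.
#'
#' @inheritParams kmeans_cluster
#' @param dims Number of PCA dimensions K (sets `min_samples = 2 * dims`);
#'   default `ncol(scores)`.
#' @param eps Neighborhood radius; `NULL` (default) uses the knee rule.
#' @return A `cluster_assignment`; `parameters$degenerate` flags an
#'   all-noise result.
#' @export
dbscan_cluster <- function(scores, dims = NULL, eps = NULL) {
  x <- as_score_matrix(scores)
  n <- nrow(x)
  if (is.null(dims)) dims <- ncol(x)
  min_samples <- 2L * as.integer(dims)
  if (n <= min_samples) {
    abort("need more samples than min_samples", class = "rscuflow_error_config")
  }
  d <- as.matrix(stats::dist(x))
  if (is.null(eps)) {
    kdist <- sort(apply(d, 1, function(r) sort(r)[min_samples + 1]))
    knee_idx <- find_knee(seq_along(kdist), kdist, decreasing = FALSE)
    if (is.na(knee_idx)) {
      abort("no knee found in the k-distance curve; supply eps explicitly",
            class = "rscuflow_error_no_knee")
    }
    eps <- kdist[knee_idx]
  }
  core <- rowSums(d <= eps) >= min_samples  # neighborhood includes the point
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier) > 0) {
      nbrs <- which(d[frontier[1], ] <= eps)
      frontier <- frontier[-1]
      for (j in nbrs) {
        if (labels[j] == -1L) {
          labels[j] <- cl
          if (core[j]) frontier <- c(frontier, j)
        }
      }
    }
  }
  degenerate <- cl == 0L
  if (degenerate) {
    warn("DBSCAN found no core points: all samples labeled noise (degenerate result)")
  }
  new_cluster_assignment(
    rownames(x), labels, "dbscan",
    list(min_samples = min_samples, eps = eps, n_clusters = cl,
         degenerate = degenerate)
  )
}

#' Ward agglomerative clustering
#'
#' Hierarchical merging on Euclidean distances with Ward's minimum-variance
#' criterion; labels come from cutting the tree at k clusters. The linkage
#' tree is retained (attribute `tree`) for dendrogram export.
#'
#' @inheritParams kmeans_cluster
#' @return A `cluster_assignment` with the `hclust` tree attached.
#' @export
agglomerative_cluster <- function(scores, k) {
  x <- as_score_matrix(scores)
  if (k > nrow(x)) abort("k exceeds the number of samples", class = "rscuflow_error_config")
  tree <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  new_cluster_assignment(rownames(x), labels, "agglomerative",
                         list(k = k, linkage = "ward"), tree = tree)
}
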