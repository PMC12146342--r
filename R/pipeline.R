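#' Configuration for one end-to-end analysis
#'
#' One analysis covers one tissue (optionally restricted to strains) and
#' one healthy-vs-disease gene-set pairing, mirroring a per-strain
#' comparison. Inputs may be in-memory objects (a study list from
#' [generate_study()]) or file paths.
#'
#' @param study Optional study list from [generate_study()]; when given,
#'   the path arguments are ignored.
#' @param fasta,expression,metadata,healthy_genes,disease_genes,pseudogenes
#'   Input file paths (used when `study` is `NULL`).
#' @param tissue,strains Sample filters ([filter_samples()]); `tissue = NULL`
#'   keeps all samples.
#' @param rscu_hi,rscu_lo Representation thresholds.
#' @param var_threshold,cap Explained-variance target and component cap for
#'   the PCA.
#' @param loading_cutoff,score_threshold Interpretation cutoffs.
#' @param alpha Significance level for the codon statistics.
#' @param k_range Candidate cluster numbers (`NULL`: `2:min(10, n - 1)`).
#' @param stratify_stats Test codons per embryonic stage (`TRUE`) or pooled
#'   (`FALSE`, default; per-stage strata need several samples per stage).
#' @param merge_singleton_batches Forwarded to [adjust_batch_effects()].
#' @param seed Seed for every stochastic stage.
#' @param out_dir Output directory for reports (`NULL`: nothing written).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(study = NULL, fasta = NULL, expression = NULL,
                            metadata = NULL, healthy_genes = NULL,
                            disease_genes = NULL, pseudogenes = NULL,
                            tissue = NULL, strains = NULL,
                            rscu_hi = 1.5, rscu_lo = 0.5,
                            var_threshold = 0.80, cap = 5,
                            loading_cutoff = 0.2, score_threshold = 5,
                            alpha = 0.05, k_range = NULL,
                            stratify_stats = FALSE,
                            merge_singleton_batches = FALSE,
                            seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full codon-usage analysis
#'
#' Executes the whole pipeline on one study: TPM weighting restricted to
#' each gene set, RSCU, library batch adjustment, 59-codon feature
#' selection, PCA with the variance/cap rule, the four-heuristic cluster
#' number consensus, the four clustering methods, external validation and
#' best-method selection, and the codon-wise healthy-vs-disease statistics.
#' Every stage is logged in the run manifest with its input/output
#' dimensions; when `out_dir` is set, TSV/JSON reports are written and
#' reruns with the same config and seed are byte-identical.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_report` list; see the elements documented below.
#'   Key elements: `profiles` (weighted usage), `rscu` (per-sample RSCU
#'   with `tissue_state`/`stage` in `sample_info`), `pca` (`codon_pca`),
#'   `heuristics`, `assignments`, `evaluations`, `best_method`,
#'   `comparison` (`codon_comparison`), `representation` (Table-style
#'   over/under calls on group mean profiles), and `manifest`.
#' @export
run_analysis <- function(config) {
  cfg <- config
  manifest <- list(seed = cfg$seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  if (!is.null(cfg$study)) {
    study <- cfg$study
    cds_counts <- study$cds_counts
    expr <- study$expression
    meta <- study$metadata
    gene_sets <- study$gene_sets
  } else {
    blacklist <- if (is.null(cfg$pseudogenes)) character() else read_gene_list(cfg$pseudogenes)
    cds_counts <- load_cds_collection(cfg$fasta, blacklist)
    expr <- read_expression_matrix(cfg$expression)
    meta <- read_sample_metadata(cfg$metadata)
    gene_sets <- list(healthy = read_gene_list(cfg$healthy_genes),
                      disease = read_gene_list(cfg$disease_genes))
  }
  log_stage("load", n_genes = nrow(cds_counts), n_samples = nrow(meta))

  samples <- if (is.null(cfg$tissue)) meta$sample_id else {
    filter_samples(meta, cfg$tissue, cfg$strains)
  }
  samples <- intersect(samples, setdiff(names(expr), "gene_id"))
  if (length(samples) == 0) {
    abort("stage sample_filter: no expression columns for the selected samples",
          class = "rscuflow_error_empty_selection")
  }
  excluded <- setdiff(meta$sample_id, samples)
  meta <- meta[match(samples, meta$sample_id), ]
  log_stage("sample_filter", n_selected = length(samples), excluded = excluded)

  # per gene set: restrict expression and weight codon usage
  profiles <- purrr::imap(gene_sets, function(ids, label) {
    sub <- restrict_to_gene_set(expr[, c("gene_id", samples)], ids, cds_counts$gene_id)
    p <- weighted_usage_profiles(sub, cds_counts)
    p$sample_id <- paste(p$sample_id, label, sep = ".")
    p
  })
  profiles <- dplyr::bind_rows(profiles)
  sample_info <- tibble::tibble(
    sample_id = profiles$sample_id,
    source_sample = sub("\\.(healthy|disease)$", "", profiles$sample_id),
    tissue_state = sub("^.*\\.", "", profiles$sample_id)
  )
  sample_info$stage <- meta$stage[match(sample_info$source_sample, meta$sample_id)]
  log_stage("weighting", n_profiles = nrow(profiles))

  rscu_tbl <- rscu(profiles)
  log_stage("rscu", n_profiles = nrow(rscu_tbl), n_codons = length(sense_codons()))

  batches <- infer_batches(meta)
  profile_batches <- tibble::tibble(
    sample_id = sample_info$sample_id,
    batch = batches$batch[match(sample_info$source_sample, batches$sample_id)]
  )
  features <- select_codon_features(rscu_tbl)
  features_adj <- adjust_batch_effects(features, profile_batches,
                                       merge_singletons = cfg$merge_singleton_batches)
  log_stage("batch_adjustment", n_batches = length(unique(profile_batches$batch)),
            n_features = ncol(features_adj) - 1)

  pca <- fit_codon_pca(features_adj, var_threshold = cfg$var_threshold, cap = cfg$cap)
  loadings <- loading_report(pca, cutoff = cfg$loading_cutoff)
  descriptors <- describe_samples(pca, score_threshold = cfg$score_threshold,
                                  cutoff = cfg$loading_cutoff)
  log_stage("pca", k = pca$k, k80 = pca$k80,
            cumulative_evr = sum(pca$explained_variance_ratio[seq_len(pca$k)]))

  heur <- heuristic_scan(pca$scores, k_range = cfg$k_range, seed = cfg$seed)
  k <- heur$consensus_k
  log_stage("heuristics", best_k = as.list(heur$best_k), consensus_k = k)

  assignments <- list(
    agglomerative = agglomerative_cluster(pca$scores, k),
    kmeans = kmeans_cluster(pca$scores, k, seed = cfg$seed),
    spectral = spectral_cluster(pca$scores, k, seed = cfg$seed),
    dbscan = tryCatch(
      dbscan_cluster(pca$scores, dims = pca$k),
      error = function(e) NULL
    )
  )
  assignments <- purrr::compact(assignments)
  log_stage("clustering", methods = names(assignments), k = k)

  refs <- list(
    tissue_state = stats::setNames(sample_info$tissue_state, sample_info$sample_id),
    stage = stats::setNames(as.character(sample_info$stage), sample_info$sample_id)
  )
  evaluations <- purrr::map_dfr(assignments, function(a) {
    purrr::map_dfr(names(refs), function(r) {
      evaluate_clustering(a, refs[[r]], reference_name = r)
    })
  })
  best <- select_best_method(evaluations)
  log_stage("evaluation", best_method = as.character(best))

  is_h <- sample_info$tissue_state == "healthy"
  strata <- if (cfg$stratify_stats) {
    stats::setNames(as.character(sample_info$stage), sample_info$sample_id)
  } else {
    NULL
  }
  comparison <- compare_groups(rscu_tbl[is_h, ], rscu_tbl[!is_h, ],
                               strata = strata, alpha = cfg$alpha,
                               seed = cfg$seed)
  log_stage("statistics", n_tests = nrow(comparison),
            fraction_significant = attr(comparison, "fraction_significant_codons"))

  # Table-style over/under representation of each group's mean profile
  representation <- purrr::map_dfr(c("healthy", "disease"), function(g) {
    idx <- sample_info$tissue_state == g
    mean_usage <- colMeans(profile_matrix(profiles[idx, ], sense_codons()))
    cls <- classify_external_usage(mean_usage, hi = cfg$rscu_hi, lo = cfg$rscu_lo)
    tibble::add_column(cls, tissue_state = g, .before = 1)
  })

  report <- list(
    config = cfg,
    profiles = profiles,
    sample_info = sample_info,
    rscu = rscu_tbl,
    features = features_adj,
    pca = pca,
    loadings = loadings,
    descriptors = descriptors,
    heuristics = heur,
    assignments = assignments,
    evaluations = evaluations,
    best_method = best,
    comparison = comparison,
    representation = representation,
    manifest = manifest
  )
  class(report) <- "analysis_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf(
    "<analysis_report> %d profiles; PCA K = %d; consensus k = %d; best method = %s; %.1f%% codons significant\n",
    nrow(x$profiles), x$pca$k, x$heuristics$consensus_k, x$best_method,
    100 * attr(x$comparison, "fraction_significant_codons")
  ))
  invisible(x)
}

# write deterministic TSV/JSON reports (no timestamps)
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$profiles, file.path(dir, "weighted_usage.tsv"))
  readr::write_tsv(report$rscu, file.path(dir, "rscu.tsv"))
  readr::write_tsv(report$pca$scores, file.path(dir, "pca_scores.tsv"))
  readr::write_tsv(tidy(report$comparison), file.path(dir, "codon_tests.tsv"))
  readr::write_tsv(report$representation, file.path(dir, "representation.tsv"))
  labels <- purrr::imap_dfr(report$assignments, function(a, m) {
    tibble::tibble(method = m, sample_id = a$sample_id, cluster = a$cluster)
  })
  readr::write_tsv(labels, file.path(dir, "cluster_labels.tsv"))
  cfg <- report$config
  cfg$study <- NULL
  cfg$out_dir <- NULL  # environment-specific; keep reports byte-stable
  json <- list(
    config = unclass(cfg),
    manifest = report$manifest,
    heuristics = list(curves = report$heuristics$curves,
                      best_k = as.list(report$heuristics$best_k),
                      consensus_k = report$heuristics$consensus_k),
    explained_variance_ratio = report$pca$explained_variance_ratio,
    evaluations = report$evaluations,
    best_method = as.character(report$best_method),
    summary = glance(report$comparison),
    stratum_contribution = stratum_contribution(report$comparison)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  # Newick-like export of the agglomerative tree
  tree <- attr(report$assignments$agglomerative, "tree")
  if (!is.null(tree)) {
    writeLines(hclust_newick(tree), file.path(dir, "dendrogram.nwk"))
  }
  invisible(dir)
}

# minimal newick serialization of an hclust tree (heights as branch lengths)
hclust_newick <- function(tree) {
  build <- function(i, parent_height) {
    if (i < 0) {
      sprintf("%s:%g", tree$labels[-i], parent_height)
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%g", build(tree$merge[i, 1], h), build(tree$merge[i, 2], h),
              parent_height - h)
    }
  }
  n <- length(tree$height)
  h <- tree$height[n]
  paste0("(", build(tree$merge[n, 1], h), ",", build(tree$merge[n, 2], h), ");")
}

#' Compare study classifications to an external usage table
#'
#' Classifies an external (e.g. genomic human) codon-usage table via
#' [classify_external_usage()] and reports, per study group, the codons
#' over- or under-represented in the external table but not in the group,
#' and vice versa.
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param usage External usage table (named vector over 61+ codons or a
#'   single-row tibble).
#' @return A list with `external` (classified table) and `overlap` (tibble:
#'   `tissue_state`, `class`, `external_only`, `group_only`, `shared` list
#'   columns).
#' @export
compare_to_reference_usage <- function(report, usage) {
  ext <- classify_external_usage(usage, hi = report$config$rscu_hi,
                                 lo = report$config$rscu_lo)
  overlap <- purrr::map_dfr(unique(report$representation$tissue_state), function(g) {
    grp <- report$representation[report$representation$tissue_state == g, ]
    purrr::map_dfr(c("over", "under"), function(cl) {
      e <- ext$codon[ext$class == cl]
      s <- grp$codon[grp$class == cl]
      tibble::tibble(
        tissue_state = g, class = cl,
        external_only = list(setdiff(e, s)),
        group_only = list(setdiff(s, e)),
        shared = list(intersect(e, s))
      )
    })
  })
  list(external = ext, overlap = overlap)
}
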