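#' Read a TPM expression matrix
#'
#' The TSV layout is genes in rows: first column the gene id, remaining
#' columns one per sample, values TPM.
#'
#' @param path Path to the TSV file.
#' @return A tibble with column `gene_id` followed by one numeric column per
#'   sample.
#' @export
read_expression_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[1] <- "gene_id"
  if (anyDuplicated(tbl$gene_id)) {
    abort("duplicated gene ids in expression matrix", class = "rscuflow_error_expression")
  }
  vals <- as.matrix(tbl[-1])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("TPM values must be finite and non-negative", class = "rscuflow_error_expression")
  }
  tbl
}

#' Read sample metadata
#'
#' Expects a TSV with header columns `sample_id`, `strain`, `tissue`,
#' `stage`, `library_id` (an optional `batch` column overrides accession
#' prefix inference downstream).
#'
#' @param path Path to the metadata TSV.
#' @param stage_range Allowed inclusive range of embryonic days.
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path, stage_range = c(6, 18)) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("sample_id", "strain", "tissue", "stage", "library_id")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata missing columns: ", paste(missing, collapse = ", ")),
          class = "rscuflow_error_metadata")
  }
  if (any(!nzchar(meta$library_id) | is.na(meta$library_id))) {
    abort("empty library_id in metadata", class = "rscuflow_error_metadata")
  }
  if (any(meta$stage < stage_range[1] | meta$stage > stage_range[2])) {
    abort(sprintf("stage outside declared study range [%g, %g]",
                  stage_range[1], stage_range[2]),
          class = "rscuflow_error_metadata")
  }
  meta
}

#' Filter samples by tissue and strain
#'
#' @param metadata Sample metadata tibble (see [read_sample_metadata()]).
#' @param tissue Tissue to keep (e.g. `"liver"`, `"heart"`, `"eye"`).
#' @param strains Strains to keep; `NULL` keeps all strains.
#' @return Character vector of matching sample ids, original order.
#' @export
filter_samples <- function(metadata, tissue, strains = NULL) {
  keep <- metadata$tissue == tissue
  if (!is.null(strains)) keep <- keep & metadata$strain %in% strains
  ids <- metadata$sample_id[keep]
  if (length(ids) == 0) {
    abort(
      sprintf("no samples match tissue '%s'%s", tissue,
              if (is.null(strains)) "" else paste0(" and strains ", paste(strains, collapse = "/"))),
      class = "rscuflow_error_empty_selection"
    )
  }
  ids
}

#' Restrict an expression matrix to a gene set
#'
#' Keeps the genes present in all three of: the expression matrix, the gene
#' set, and the CDS collection. Values of retained genes are unchanged.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param gene_set Character vector of gene ids (healthy- or
#'   disease-associated list).
#' @param cds_genes Character vector of gene ids with coding sequences.
#' @return The filtered expression tibble.
#' @export
restrict_to_gene_set <- function(expr, gene_set, cds_genes) {
  keep <- expr$gene_id %in% gene_set & expr$gene_id %in% cds_genes
  if (!any(keep)) {
    abort(
      sprintf(
        "empty intersection of expression genes (%d), gene set (%d), CDS genes (%d)",
        length(expr$gene_id), length(gene_set), length(cds_genes)
      ),
      class = "rscuflow_error_empty_intersection"
    )
  }
  expr[keep, , drop = FALSE]
}

#' Transcriptome-weighted codon usage for one sample
#'
#' The raw weight of codon c is `sum over genes of TPM(g) * counts_g(c)`;
#' with `normalize = TRUE` the vector is rescaled to sum to 1,000 weighted
#' codons (codon-usage-table convention).
#'
#' @param tpm Named numeric vector of TPM, names = gene ids. All names must
#'   have codon counts.
#' @param cds_counts CDS count tibble from [load_cds_collection()].
#' @param normalize Rescale to per-1,000 codons? Default `TRUE`.
#' @return Named numeric vector of length 64.
#' @export
weighted_codon_usage <- function(tpm, cds_counts, normalize = TRUE) {
  missing <- setdiff(names(tpm), cds_counts$gene_id)
  if (length(missing) > 0) {
    abort(paste0("genes without codon counts: ", paste(utils::head(missing, 10), collapse = ", ")),
          class = "rscuflow_error_expression")
  }
  m <- cds_count_matrix(cds_counts)[names(tpm), , drop = FALSE]
  w <- as.numeric(crossprod(m, tpm))
  names(w) <- all_codons()
  total <- sum(w)
  if (total <= 0) {
    abort("all-zero total codon weight for sample", class = "rscuflow_error_degenerate_sample")
  }
  if (normalize) w <- 1000 * w / total
  w
}

#' Transcriptome-weighted usage profiles for all samples
#'
#' Applies [weighted_codon_usage()] to every sample column of an expression
#' matrix.
#'
#' @param expr Expression tibble (`gene_id` + sample columns), typically
#'   already restricted via [restrict_to_gene_set()].
#' @inheritParams weighted_codon_usage
#' @param samples Sample columns to use; default all non-`gene_id` columns.
#' @return A tibble with `sample_id` and 64 codon columns; when normalized
#'   each row sums to 1,000.
#' @export
weighted_usage_profiles <- function(expr, cds_counts, normalize = TRUE,
                                    samples = setdiff(names(expr), "gene_id")) {
  m <- cds_count_matrix(cds_counts)
  missing <- setdiff(expr$gene_id, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("genes without codon counts: ", paste(utils::head(missing, 10), collapse = ", ")),
          class = "rscuflow_error_expression")
  }
  tpm <- as.matrix(expr[samples])
  rownames(tpm) <- expr$gene_id
  w <- crossprod(m[expr$gene_id, , drop = FALSE], tpm)  # 64 x samples
  totals <- colSums(w)
  if (any(totals <= 0)) {
    abort(paste0("all-zero total codon weight for sample(s): ",
                 paste(samples[totals <= 0], collapse = ", ")),
          class = "rscuflow_error_degenerate_sample")
  }
  if (normalize) w <- sweep(w, 2, totals / 1000, "/")
  matrix_profile(t(w), sample_id = samples)
}

#' Write a weighted-usage (or RSCU) profile table to TSV
#'
#' Rows are samples, columns codons, in the codon-usage-table style.
#'
#' @param profiles Wide profile tibble (`sample_id` + codon columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}
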