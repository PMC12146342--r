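#' Infer sequencing-library batches from archive accessions
#'
#' Batch is the archive prefix of `library_id`: `SRR` (NCBI SRA), `ERR`
#' (EGA/ENA), or `DRR` (DDBJ). An explicit `batch` column in the metadata
#' overrides inference.
#'
#' @param metadata Sample metadata tibble with `sample_id` and `library_id`
#'   (optionally `batch`).
#' @return A tibble with columns `sample_id`, `batch`.
#' @export
infer_batches <- function(metadata) {
  if ("batch" %in% names(metadata)) {
    return(tibble::tibble(sample_id = metadata$sample_id, batch = as.character(metadata$batch)))
  }
  prefix <- stringr::str_extract(metadata$library_id, "^(SRR|ERR|DRR)")
  if (anyNA(prefix)) {
    bad <- metadata$library_id[is.na(prefix)]
    abort(
      paste0("unrecognized archive prefix (expected SRR/ERR/DRR): ",
             paste(utils::head(bad, 10), collapse = ", "),
             "; add an explicit `batch` column to override"),
      class = "rscuflow_error_unknown_batch"
    )
  }
  tibble::tibble(sample_id = metadata$sample_id, batch = prefix)
}

#' Remove batch effects from a feature matrix
#'
#' Empirical-Bayes location/scale adjustment (the parametric ComBat model):
#' features are standardized, per-batch additive and multiplicative effects
#' estimated and shrunk via parametric empirical Bayes, removed, and the
#' grand location/scale restored. With a single batch the input is returned
#' unchanged. Features with zero pooled variance are passed through
#' unchanged. Row (sample) order is preserved.
#'
#' @param features Wide tibble: `sample_id` plus numeric feature columns
#'   (e.g. an RSCU matrix).
#' @param batches Tibble from [infer_batches()] or a named character vector
#'   `sample_id -> batch`.
#' @param merge_singletons Pool batches with a single sample into the
#'   largest batch instead of erroring. Default `FALSE`.
#' @return A tibble of the same shape and sample order.
#' @export
adjust_batch_effects <- function(features, batches, merge_singletons = FALSE) {
  if (is.data.frame(batches)) {
    batch <- stats::setNames(as.character(batches$batch), batches$sample_id)
  } else {
    batch <- stats::setNames(as.character(batches), names(batches))
  }
  missing <- setdiff(features$sample_id, names(batch))
  if (length(missing) > 0) {
    abort(paste0("samples without batch assignment: ", paste(utils::head(missing, 10), collapse = ", ")),
          class = "rscuflow_error_unknown_batch"
    )
  }
  batch <- batch[features$sample_id]
  if (length(unique(batch)) == 1) {
    return(features)
  }
  sizes <- table(batch)
  if (any(sizes == 1)) {
    if (!merge_singletons) {
      abort(
        paste0("batch(es) with a single sample: ",
               paste(names(sizes)[sizes == 1], collapse = ", "),
               "; drop them, merge them, or set merge_singletons = TRUE"),
        class = "rscuflow_error_singleton_batch"
      )
    }
    largest <- names(sizes)[which.max(sizes)]
    batch[batch %in% names(sizes)[sizes == 1]] <- largest
    if (length(unique(batch)) == 1) return(features)
  }
  x <- profile_matrix(features, setdiff(names(features), "sample_id"))
  dat <- t(x)  # ComBat wants features x samples
  pooled_var <- apply(dat, 1, stats::var)
  # within-batch constant features also break the EB scale model; pass through
  within_var <- sapply(split(seq_along(batch), batch), function(idx) {
    apply(dat[, idx, drop = FALSE], 1, stats::var)
  })
  adjustable <- pooled_var > 0 & apply(within_var, 1, function(v) all(v > 0))
  adj <- dat
  if (any(adjustable)) {
    corrected <- suppressMessages(
      sva::ComBat(dat = dat[adjustable, , drop = FALSE], batch = factor(batch))
    )
    adj[adjustable, ] <- corrected
  }
  matrix_profile(t(adj), sample_id = features$sample_id)
}
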