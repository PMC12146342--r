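#' @importFrom rlang abort warn inform %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# run code under a seed without disturbing the caller's RNG state;
# seed = NULL runs as-is
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# identify codon columns of a wide profile tibble
codon_cols <- function(tbl, codons = all_codons()) {
  intersect(codons, names(tbl))
}

# wide profile tibble -> numeric matrix (rows = sample_id)
profile_matrix <- function(tbl, codons = NULL) {
  cols <- if (is.null(codons)) codon_cols(tbl) else codons
  missing <- setdiff(cols %||% character(), names(tbl))
  if (length(missing) > 0) {
    abort(
      paste0("missing codon columns: ", paste(missing, collapse = ", ")),
      class = "rscuflow_error_missing_codons"
    )
  }
  m <- as.matrix(tbl[cols])
  storage.mode(m) <- "double"
  if ("sample_id" %in% names(tbl)) rownames(m) <- tbl$sample_id
  m
}

# numeric matrix (rows = samples) -> wide tibble with sample_id first
matrix_profile <- function(m, sample_id = rownames(m)) {
  out <- tibble::as_tibble(m)
  tibble::add_column(out, sample_id = sample_id, .before = 1)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"),
          class = "rscuflow_error_config")
  }
}
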