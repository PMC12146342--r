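#' Count codons in a coding sequence
#'
#' Tallies consecutive, non-overlapping triplets read in frame 0. The
#' sequence must be DNA (`A`, `C`, `G`, `T`; lowercase accepted), non-empty,
#' and of length divisible by three. Internal stop codons are counted like
#' any other codon; they are only excluded later, at feature selection.
#'
#' @param sequence A single DNA string (the CDS).
#' @return A named numeric vector of length 64 (codons in alphabetical
#'   order); entries sum to `nchar(sequence) / 3`.
#' @examples
#' count_codons("ATGGCTGCT")[c("ATG", "GCT")]
#' @export
count_codons <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    abort("`sequence` must be a single string", class = "rscuflow_error_malformed_cds")
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0 || n %% 3 != 0) {
    abort(
      sprintf("CDS length %d is not a positive multiple of 3", n),
      class = "rscuflow_error_malformed_cds"
    )
  }
  if (grepl("U", sequence, fixed = TRUE)) {
    abort("RNA input (U) is not accepted; provide DNA", class = "rscuflow_error_alphabet")
  }
  if (grepl("[^ACGT]", sequence)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", sequence), "")[[1]])
    abort(
      paste0("non-ACGT characters in CDS: ", paste(bad, collapse = ", ")),
      class = "rscuflow_error_alphabet"
    )
  }
  counts <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(sequence), step = 3)
  as.numeric(counts[all_codons()]) |> stats::setNames(all_codons())
}

#' Read a gene list file
#'
#' One gene identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to a plain-text gene list.
#' @return A character vector of unique gene ids (original order).
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  unique(lines[nzchar(lines)])
}

#' Load a CDS collection from FASTA
#'
#' Reads a (possibly multi-line) FASTA of coding sequences, drops
#' blacklisted genes (e.g. known pseudogenes), keeps only the first record
#' for a duplicated gene id (with a warning), validates every retained
#' sequence, and returns per-gene codon counts. The gene id is the first
#' whitespace-separated token of each header.
#'
#' @param fasta_path Path to the CDS FASTA file.
#' @param pseudogene_blacklist Character vector of gene ids to drop (or a
#'   path passed through [read_gene_list()] by the caller).
#' @return A tibble with columns `gene_id`, `n_codons`, and one count column
#'   per codon (64 columns, alphabetical order).
#' @export
load_cds_collection <- function(fasta_path, pseudogene_blacklist = character()) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- stringr::str_extract(names(seqs), "^\\S+")
  keep <- !ids %in% pseudogene_blacklist
  seqs <- seqs[keep]
  ids <- ids[keep]
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    warn(paste0(
      "duplicate gene ids; keeping first occurrence of: ",
      paste(utils::head(dups, 10), collapse = ", ")
    ))
    first <- !duplicated(ids)
    seqs <- seqs[first]
    ids <- ids[first]
  }
  if (length(seqs) == 0) {
    abort("no coding sequences left after filtering", class = "rscuflow_error_empty_collection")
  }
  w <- Biostrings::width(seqs)
  if (any(w == 0 | w %% 3 != 0)) {
    abort(
      paste0("CDS length not a positive multiple of 3 for: ",
             paste(utils::head(ids[w == 0 | w %% 3 != 0], 10), collapse = ", ")),
      class = "rscuflow_error_malformed_cds"
    )
  }
  alph <- Biostrings::alphabetFrequency(seqs)
  non_acgt <- rowSums(alph) - rowSums(alph[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(non_acgt > 0)) {
    abort(
      paste0("non-ACGT characters in: ",
             paste(utils::head(ids[non_acgt > 0], 10), collapse = ", ")),
      class = "rscuflow_error_alphabet"
    )
  }
  counts <- Biostrings::trinucleotideFrequency(seqs, step = 3)[, all_codons(), drop = FALSE]
  out <- tibble::as_tibble(counts)
  out <- tibble::add_column(out, gene_id = ids, n_codons = w / 3, .before = 1)
  out
}

# CDS count tibble -> genes x 64 matrix with gene_id rownames
cds_count_matrix <- function(cds_counts) {
  m <- as.matrix(cds_counts[all_codons()])
  storage.mode(m) <- "double"
  rownames(m) <- cds_counts$gene_id
  m
}
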