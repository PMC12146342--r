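#' The standard genetic code
#'
#' Returns the standard (NCBI transl_table 1) genetic code as a tibble with
#' one row per codon, together with the degeneracy (number of synonymous
#' codons) of the amino acid each codon encodes. The three stop codons
#' (TGA, TAG, TAA) carry amino acid `"*"` and degeneracy `NA`.
#'
#' @return A tibble with columns `codon` (DNA trinucleotide, alphabetical
#'   order), `aa` (one-letter amino-acid symbol or `"*"`), `aa3`
#'   (three-letter symbol or `"Stp"`), and `degeneracy`.
#' @examples
#' code <- standard_genetic_code()
#' dplyr::filter(code, aa == "L")  # six leucine codons
#' @export
standard_genetic_code <- function() {
  gc_map <- Biostrings::GENETIC_CODE
  codon <- sort(names(gc_map))
  aa <- unname(gc_map[codon])
  three <- c(
    A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
    E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val", `*` = "Stp"
  )
  deg <- table(aa[aa != "*"])
  tibble::tibble(
    codon = codon,
    aa = aa,
    aa3 = unname(three[aa]),
    degeneracy = ifelse(aa == "*", NA_integer_, as.integer(deg[aa]))
  )
}

# cached code table and frequently used codon sets
the <- new.env(parent = emptyenv())

genetic_code_tbl <- function() {
  if (is.null(the$code)) the$code <- standard_genetic_code()
  the$code
}

#' Codon name sets
#'
#' `all_codons()` lists the 64 codons in alphabetical order; `sense_codons()`
#' the 61 non-stop codons; `pca_feature_codons()` the 59 codons retained for
#' dimensionality reduction, i.e. sense codons minus the two degeneracy-1
#' codons ATG (Met) and TGG (Trp).
#'
#' @return A character vector of codon names.
#' @export
all_codons <- function() genetic_code_tbl()$codon

#' @rdname all_codons
#' @export
sense_codons <- function() {
  code <- genetic_code_tbl()
  code$codon[code$aa != "*"]
}

#' @rdname all_codons
#' @export
stop_codons <- function() {
  code <- genetic_code_tbl()
  code$codon[code$aa == "*"]
}

#' @rdname all_codons
#' @export
pca_feature_codons <- function() {
  setdiff(sense_codons(), c("ATG", "TGG"))
}

# named vector codon -> aa (one letter), sense codons only when sense = TRUE
codon_aa_map <- function(sense = FALSE) {
  code <- genetic_code_tbl()
  if (sense) code <- code[code$aa != "*", ]
  stats::setNames(code$aa, code$codon)
}

# list of synonymous families: aa -> codon vector (20 amino acids)
synonymous_families <- function() {
  code <- genetic_code_tbl()
  code <- code[code$aa != "*", ]
  split(code$codon, code$aa)
}

# "Ala-GCC"-style label used in over/under representation tables
codon_label <- function(codon) {
  code <- genetic_code_tbl()
  aa3 <- stats::setNames(code$aa3, code$codon)
  paste0(aa3[codon], "-", codon)
}
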