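#' Configuration for a synthetic codon-usage study
#'
#' Bundles every knob of the synthetic-study generator with defaults that
#' emulate a small developmental bulk-expression study: two tissue-specific
#' gene sets (healthy / disease) whose coding sequences share baseline
#' per-family codon preferences, a planted RSCU shift on selected disease-set
#' codons, log-normal TPM with strain/stage/tissue-state structure,
#' per-gene additive library batch shifts on the log scale, and a pseudogene
#' blacklist.
#'
#' @param seed Master seed; the generator is fully deterministic given it.
#' @param n_genes Genes per gene set.
#' @param cds_length_codons Mean CDS length in codons (lengths are drawn
#'   log-normally around it, minimum 50).
#' @param delta Planted RSCU shift for the disease set's target codons (the
#'   target codon's expected RSCU moves from 1 to 1 + delta).
#' @param target_codons Codons receiving the planted shift; defaults to six
#'   codons from two-codon families.
#' @param strains,tissue,stages Study structure written to the metadata.
#' @param n_samples Number of tissue samples (each yields a healthy- and a
#'   disease-weighted profile downstream).
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters per gene x sample.
#'   The default sdlog of 2 reflects the order-of-magnitude per-gene
#'   expression swings seen across embryonic stages.
#' @param batches Archive prefixes cycled over samples (library batches).
#' @param batch_sdlog SD of the per-gene additive batch shift on log-TPM.
#' @param stage_effect Per-stage slope on log-TPM for a random half of the
#'   genes (stage-dependent expression structure).
#' @param n_pseudogenes Pseudogenes emitted into the FASTA and blacklisted.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 150,
                             cds_length_codons = 300,
                             delta = 0.4,
                             target_codons = c("TTC", "TAC", "CAC", "AAC", "GAC", "TGC"),
                             strains = "C57BL/6",
                             tissue = "liver",
                             stages = 10:18,
                             n_samples = 20,
                             tpm_meanlog = 3,
                             tpm_sdlog = 2,
                             batches = c("SRR", "ERR"),
                             batch_sdlog = 0.5,
                             stage_effect = 0.05,
                             n_pseudogenes = 5) {
  if (delta < 0) abort("delta must be >= 0", class = "rscuflow_error_config")
  code <- genetic_code_tbl()
  deg <- stats::setNames(code$degeneracy, code$codon)
  bad <- target_codons[!target_codons %in% sense_codons()]
  if (length(bad) > 0) {
    abort(paste0("target codons are not sense codons: ", paste(bad, collapse = ", ")),
          class = "rscuflow_error_config")
  }
  # expected RSCU 1 + delta must stay below the family size
  over <- target_codons[1 + delta > deg[target_codons]]
  if (length(over) > 0) {
    abort(paste0("requested RSCU exceeds family size for: ", paste(over, collapse = ", ")),
          class = "rscuflow_error_config")
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = n_genes,
      cds_length_codons = cds_length_codons, delta = delta,
      target_codons = target_codons, strains = strains, tissue = tissue,
      stages = stages, n_samples = n_samples, tpm_meanlog = tpm_meanlog,
      tpm_sdlog = tpm_sdlog, batches = batches, batch_sdlog = batch_sdlog,
      stage_effect = stage_effect, n_pseudogenes = n_pseudogenes
    ),
    class = "synthetic_config"
  )
}

# baseline per-family codon preferences: uniform within each family
uniform_preferences <- function() {
  fams <- synonymous_families()
  purrr::map(fams, function(codons) {
    stats::setNames(rep(1 / length(codons), length(codons)), codons)
  })
}

# shift preferences so each target codon's expected RSCU becomes 1 + delta:
# RSCU(c) = k * p(c), so p(target) <- p + delta / k; the remaining family
# mass is spread proportionally over the other members.
shift_preferences <- function(prefs, target_codons, delta) {
  if (delta == 0 || length(target_codons) == 0) return(prefs)
  aa_of <- codon_aa_map(sense = TRUE)
  for (codon in target_codons) {
    fam <- aa_of[codon]
    p <- prefs[[fam]]
    k <- length(p)
    p_new <- p[codon] + delta / k
    if (p_new >= 1) {
      abort(paste0("planted shift leaves no mass for family partners of ", codon),
            class = "rscuflow_error_config")
    }
    others <- setdiff(names(p), codon)
    p[others] <- p[others] * (1 - p_new) / sum(p[others])
    p[codon] <- p_new
    prefs[[fam]] <- p
  }
  prefs
}

#' Generate coding sequences from codon preferences
#'
#' Each gene gets a uniformly random amino-acid backbone (Met start
#' enforced) and codons sampled per synonymous family from the preference
#' table. Deterministic given the seed.
#'
#' @param n Number of genes.
#' @param preferences Per-family preference list as from
#'   `uniform_preferences()` (names = amino acids, entries = named simplex
#'   vectors over the family's codons).
#' @param length_codons Mean gene length in codons.
#' @param seed Seed.
#' @param prefix Gene-id prefix.
#' @return A list with `sequences` (named character vector of CDS) and
#'   `counts` (CDS count tibble as from [load_cds_collection()]).
#' @export
generate_cds_set <- function(n, preferences, length_codons = 300, seed = 1L,
                             prefix = "gene") {
  for (p in preferences) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort("preferences must be simplex-valid per family", class = "rscuflow_error_config")
    }
  }
  with_seed_if(seed, {
    aas <- names(preferences)
    lens <- pmax(50L, as.integer(round(stats::rlnorm(n, log(length_codons), 0.3))))
    gene_idx <- rep(seq_len(n), lens)
    first <- !duplicated(gene_idx)  # Met start per gene
    backbone <- character(length(gene_idx))
    backbone[first] <- "M"
    backbone[!first] <- sample(aas, sum(!first), replace = TRUE)
    codons <- character(length(backbone))
    for (a in aas) {
      pos <- which(backbone == a)
      if (length(pos) == 0) next
      p <- preferences[[a]]
      codons[pos] <- if (length(p) == 1) names(p) else {
        names(p)[sample.int(length(p), length(pos), replace = TRUE, prob = p)]
      }
    }
    seqs <- vapply(split(codons, factor(gene_idx, levels = seq_len(n))),
                   paste, character(1), collapse = "")
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    names(seqs) <- ids
    counts <- Biostrings::trinucleotideFrequency(
      Biostrings::DNAStringSet(seqs), step = 3
    )[, all_codons(), drop = FALSE]
    counts_tbl <- tibble::as_tibble(counts)
    counts_tbl <- tibble::add_column(counts_tbl, gene_id = ids,
                                     n_codons = lens, .before = 1)
    list(sequences = seqs, counts = counts_tbl)
  })
}

#' Generate a complete synthetic study
#'
#' Emits everything the analysis pipeline consumes — CDS FASTA text, a TPM
#' expression table, sample metadata, healthy/disease gene lists, a
#' pseudogene blacklist — plus the ground truth (shifted codons, batch and
#' group labels). The healthy set is drawn from uniform baseline
#' preferences; the disease set from preferences shifted so the target
#' codons' expected RSCU is `1 + delta`. TPM is log-normal per gene and
#' sample with a stage-dependent trend on a random half of the genes and
#' per-gene additive batch shifts on the log scale. All outputs are
#' deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `fasta` (named character vector of
#'   sequences), `cds_counts`, `expression`, `metadata`, `gene_sets`
#'   (list of id vectors), `pseudogenes`, and `truth`.
#' @export
generate_study <- function(config = synthetic_config()) {
  cfg <- config
  with_seed_if(cfg$seed, {
    prefs <- uniform_preferences()
    healthy <- generate_cds_set(cfg$n_genes, prefs, cfg$cds_length_codons,
                                seed = NULL, prefix = "hgene")
    disease <- generate_cds_set(cfg$n_genes,
                                shift_preferences(prefs, cfg$target_codons, cfg$delta),
                                cfg$cds_length_codons, seed = NULL, prefix = "dgene")
    pseudo <- if (cfg$n_pseudogenes > 0) {
      generate_cds_set(cfg$n_pseudogenes, prefs, cfg$cds_length_codons,
                       seed = NULL, prefix = "pseudo")
    } else {
      list(sequences = character(), counts = NULL)
    }
    gene_ids <- c(healthy$counts$gene_id, disease$counts$gene_id)
    n_genes_total <- length(gene_ids)

    n <- cfg$n_samples
    sample_ids <- sprintf("sample%03d", seq_len(n))
    stages <- rep_len(cfg$stages, n)
    strains <- rep_len(cfg$strains, n)
    batch <- rep_len(cfg$batches, n)
    library_id <- sprintf("%s%06d", batch, sample.int(899999, n) + 100000)
    metadata <- tibble::tibble(
      sample_id = sample_ids, strain = strains, tissue = cfg$tissue,
      stage = stages, library_id = library_id
    )

    stage_gene <- sample(c(TRUE, FALSE), n_genes_total, replace = TRUE)
    batch_shift <- matrix(
      stats::rnorm(n_genes_total * length(cfg$batches), 0, cfg$batch_sdlog),
      nrow = n_genes_total,
      dimnames = list(gene_ids, cfg$batches)
    )
    mean_stage <- mean(cfg$stages)
    logtpm <- matrix(
      stats::rnorm(n_genes_total * n, cfg$tpm_meanlog, cfg$tpm_sdlog),
      nrow = n_genes_total, dimnames = list(gene_ids, sample_ids)
    )
    for (j in seq_len(n)) {
      logtpm[stage_gene, j] <- logtpm[stage_gene, j] +
        cfg$stage_effect * (stages[j] - mean_stage)
      logtpm[, j] <- logtpm[, j] + batch_shift[, batch[j]]
    }
    expr <- tibble::as_tibble(exp(logtpm))
    expr <- tibble::add_column(expr, gene_id = gene_ids, .before = 1)

    fasta <- c(healthy$sequences, disease$sequences, pseudo$sequences)
    cds_counts <- dplyr::bind_rows(healthy$counts, disease$counts)
    list(
      fasta = fasta,
      cds_counts = cds_counts,
      expression = expr,
      metadata = metadata,
      gene_sets = list(healthy = healthy$counts$gene_id,
                       disease = disease$counts$gene_id),
      pseudogenes = names(pseudo$sequences),
      truth = list(
        config = cfg,
        shifted_codons = if (cfg$delta > 0) cfg$target_codons else character(),
        batch = stats::setNames(batch, sample_ids),
        stage = stats::setNames(stages, sample_ids),
        strain = stats::setNames(strains, sample_ids),
        stage_genes = gene_ids[stage_gene]
      )
    )
  })
}

#' Write a synthetic study to disk
#'
#' Emits exactly the plain-text formats the upstream readers consume:
#' `cds.fasta`, `expression.tsv`, `metadata.tsv`, `healthy_genes.txt`,
#' `disease_genes.txt`, `pseudogenes.txt`, and `truth.json`.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(
    paste0(">", names(study$fasta), "\n", study$fasta),
    file.path(dir, "cds.fasta")
  )
  readr::write_tsv(study$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(study$metadata, file.path(dir, "metadata.tsv"))
  writeLines(study$gene_sets$healthy, file.path(dir, "healthy_genes.txt"))
  writeLines(study$gene_sets$disease, file.path(dir, "disease_genes.txt"))
  writeLines(study$pseudogenes, file.path(dir, "pseudogenes.txt"))
  truth <- study$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
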