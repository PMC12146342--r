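# rscuflow

Transcriptome-weighted relative synonymous codon usage (RSCU) analysis for
developmental transcriptomes.

## The problem

Synonymous codons are not used interchangeably: tissues, developmental
stages and gene sets exhibit codon usage bias (CUB), and deviations from a
tissue's codon-demand profile have been linked to developmental disease.
`rscuflow` implements a complete, tested pipeline for asking whether two
curated gene sets — e.g. genes associated with healthy versus diseased
tissue — impose different codon demands on the same expressed
transcriptome, and for mapping how those differences structure samples
across embryonic stages, strains and sequencing batches.

The pipeline takes three inputs: coding sequences (FASTA), per-sample TPM
expression (TSV), and sample metadata with archive library accessions. It
is aimed at transcriptomics researchers who want per-sample codon-usage
profiles rather than genome-wide averages.

## The model

For each sample, codon demand is the expression-weighted sum of codon
counts over the genes of a set,

    W(c) = Σ_g TPM(g) · n_g(c),

normalized to 1,000 weighted codons (codon-usage-table convention). The
relative synonymous codon usage of codon *c* encoding amino acid *a* with
degeneracy *k* is

    RSCU(c) = k · W(c) / Σ_{c' ∈ syn(a)} W(c'),

so RSCU = 1 means no bias; values ≥ 1.5 are called overrepresented and
≤ 0.5 underrepresented. Downstream the package:

* removes library-of-origin batch effects (SRR/ERR/DRR accession prefixes)
  with parametric empirical-Bayes location/scale adjustment (ComBat, via
  `sva`);
* reduces the 59-codon feature space (61 sense codons minus ATG and TGG,
  whose RSCU is identically 1) by PCA, keeping `K = min(5, k80)` components
  where `k80` reaches 80% cumulative explained variance, and interprets
  loadings (|loading| ≥ 0.2, amino acids with ≥ 2 passing codons) and
  scores (> 5);
* selects a cluster number by consensus of four heuristics (silhouette,
  Calinski–Harabasz, inertia elbow, Davies–Bouldin) and clusters with
  k-means (30% subsample / 5 attempts / 3 iterations seeding), spectral
  clustering (n/4 neighbors, rbf vs nearest-neighbor affinity chosen by
  silhouette), DBSCAN (min_samples = 2K, knee-selected eps) and Ward
  agglomeration, validated by ARI, AMI, V-measure, homogeneity and
  completeness;
* compares groups codon-by-codon with the exact two-sided Mann–Whitney U
  test (full enumeration of group assignments where feasible), Bonferroni
  correction, and unequal-variance Cohen's *d* binned as very small <
  0.2 ≤ small < 0.36 ≤ medium < 0.66 ≤ large ≤ 1 < very large.

A synthetic-study generator (`generate_study()`) emits CDS, gene sets with
a planted RSCU shift, log-normal TPM with stage/batch structure, and full
ground truth, so every stage of the pipeline can be calibrated and
power-tested.

## Worked example

```r
library(rscuflow)

study  <- generate_study(synthetic_config(seed = 42, delta = 0.8,
                                          n_genes = 300, tpm_sdlog = 1))
report <- run_analysis(analysis_config(study = study, seed = 42))
report
#> <analysis_report> 40 profiles; PCA K = 5; consensus k = 2;
#>   best method = agglomerative; 52.5% codons significant

report$heuristics
#> <heuristic_report> best k per heuristic:
#>        silhouette calinski_harabasz           inertia    davies_bouldin
#>                 2                 2                 2                 2
#> consensus k: 2

dplyr::filter(report$evaluations, reference == "tissue_state")
#>   method        reference      ari   ami v_measure homogeneity completeness
#> 1 agglomerative tissue_state 1     1         1               1        1
#> 2 kmeans        tissue_state 1     1         1               1        1
#> 3 spectral      tissue_state 1     1         1               1        1
#> 4 dbscan        tissue_state 0.907 0.891     0.895           1        0.810

head(dplyr::arrange(tidy(report$comparison), p_adj), 3)
#>   codon aa  stratum  n1  n2     u    p_raw    p_adj     d bin
#> 1 AAC   N   all      20  20     0 1.45e-11 8.56e-10 -42.4 very large
#> 2 AAT   N   all      20  20   400 1.45e-11 8.56e-10  42.4 very large
#> 3 CAC   H   all      20  20     0 1.45e-11 8.56e-10 -43.7 very large
```

Forty profiles = 20 samples weighted by each of the two gene sets. The
planted shift (expected RSCU 1 → 1.8 on six two-fold-family codons) drives
a clean two-cluster split by tissue state: all four heuristics agree on
k = 2 and three of the four clustering methods recover the split exactly
(ARI = 1). The strongest codon tests are the planted codons and their
family partners, with U = 0 or 400 at n = 20 per group — complete
separation, the smallest two-sided p the exact null distribution allows —
and at this low expression-noise setting the tests also resolve the small
composition differences between the two finite gene sets (31 of 59 codons
significant after Bonferroni in total).

`autoplot(report$pca, colour = report$sample_info$tissue_state)` draws the
score scatter; `plot_rscu_heatmap(report$rscu)` the per-sample RSCU matrix;
`compare_to_reference_usage(report, usage)` contrasts the study's over-
and underrepresented codons with an external (e.g. genomic) usage table.

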