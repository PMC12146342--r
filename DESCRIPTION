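Package: rscuflow
Title: Transcriptome-Weighted Relative Synonymous Codon Usage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying codon usage bias in developmental
    transcriptomes. Computes transcriptome-weighted codon usage from coding
    sequences and TPM expression restricted to curated gene sets, derives
    relative synonymous codon usage (RSCU) profiles with over- and
    under-representation calls, removes sequencing-library batch effects,
    reduces the 59-codon feature space by principal component analysis with
    loading- and score-interpretation rules, selects cluster numbers by a
    four-heuristic consensus, runs k-means, spectral, density-based and
    Ward agglomerative clustering with external validation, and compares
    groups codon-by-codon with exact Mann-Whitney U tests, Bonferroni
    correction and Cohen's d effect sizes. A synthetic-study generator with
    full ground truth supports calibration and power analysis of the whole
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    sva,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
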