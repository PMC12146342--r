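---
title: "Transcriptome-weighted RSCU analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-weighted RSCU analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rscuflow)
```

This vignette is the package's account of its science: the quantities it
computes, the assumptions behind each stage, the parameters that matter and
why their defaults are what they are, what the synthetic-study generator
does and does not emulate, and the numerical choices made where the design
was genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. From expression to codon demand

A gene's coding sequence fixes its codon counts $n_g(c)$; a sample's
expression fixes how often each gene's codons are actually translated. The
transcriptome-weighted codon usage of a sample, restricted to a gene set
$G$, is

$$W(c) = \sum_{g \in G} \mathrm{TPM}(g)\, n_g(c),$$

rescaled so that $\sum_c W(c) = 1000$ (the per-1,000-codons convention of
public codon-usage tables). Two assumptions are built in: TPM is taken as
the weight directly (no length re-correction — TPM is already
length-normalized), and one TPM column is weighted per sample with no
cross-sample averaging, because the downstream statistics compare
*distributions across samples*. Genes with zero TPM contribute nothing but
are not removed; a sample whose total weight is zero is an error, not a
silent NA.

Restriction to a gene set is a three-way intersection (expression genes ∩
set ∩ CDS collection); an empty intersection is an error that reports all
three set sizes, since in practice the failure is almost always an
identifier mismatch.

Reading frames: codons are counted in frame 0 of the provided CDS with no
internal-stop checking. Curated CDS are assumed clean; stop codons are
excluded later, at feature selection, not at counting. Duplicate FASTA ids
keep the first record with a warning — some choice must be made and the
first-seen rule is reproducible.

## 2. RSCU and representation calls

For codon $c$ of amino acid $a$ with degeneracy $k_a$,

$$\mathrm{RSCU}(c) = \frac{k_a\, W(c)}{\sum_{c' \in \mathrm{syn}(a)} W(c')}.$$

RSCU is scale-invariant, so raw and per-1,000 weights give identical
values, and each family sums to its degeneracy — a conservation identity
the tests assert to $10^{-9}$ over 1,000 random profiles. A family with
zero total usage yields *undefined* (`NA`) rather than zero: in sparse
synthetic data a zero family would otherwise masquerade as uniform
underrepresentation.

Representation thresholds are $\ge 1.5$ (over) and $\le 0.5$ (under),
both inclusive and configurable. The inclusive form is adopted because it
is the only variant stated with explicit operators in the conventions this
package follows; on continuous data the choice is immaterial.

Met (ATG) and Trp (TGG) have degeneracy 1, hence RSCU ≡ 1 whenever
expressed. They are retained in RSCU profiles (completeness of the table)
but excluded from the PCA feature space and from the codon-wise tests —
a constant cannot discriminate groups, and including it would only deflate
reported significant fractions.

## 3. Batch adjustment

Library of origin (SRA `SRR`, EGA/ENA `ERR`, DDBJ `DRR` accession
prefixes) is treated as the batch variable; an explicit `batch` metadata
column overrides prefix inference. Adjustment is the parametric
empirical-Bayes location/scale model (ComBat), delegated to `sva::ComBat`
behind `adjust_batch_effects()`, which adds the contract guarantees the
pipeline needs: a single batch returns the input unchanged; features with
zero pooled (or zero within-batch) variance pass through untouched; sample
order is preserved; singleton batches are an error by default, with
`merge_singletons = TRUE` pooling them into the largest batch — EB
variance estimates are undefined at $n = 1$, so silence would be worse
than either policy.

One property of EB shrinkage is worth knowing: per-feature batch effects
are shrunk toward the cross-feature mean effect. When planted shifts are
drawn around a common batch offset — the generative model ComBat assumes —
the adjustment removes upwards of 90% of every between-batch mean gap once
a few dozen samples per batch are available. When shifts vary wildly
across features, the shrinkage deliberately leaves a residual on outlying
features; that is the bias–variance trade the model makes, not a defect,
and the tests exercise the model-consistent regime.

Correction is applied to the 59-codon RSCU feature matrix, i.e. the input
to the PCA, and by default once per analysis (one tissue × one gene-set
pairing), since batch composition differs between analyses.

## 4. Dimensionality reduction and interpretation rules

The feature space drops the three stop codons and ATG/TGG, leaving exactly
59 features. Features are standardized to mean 0, SD 1 with the
*population* ($n$) denominator — the convention of common machine-learning
scalers; the $n-1$ alternative rescales all features by one constant and
cannot change components. Zero-variance features become all-zero columns
and are flagged.

The retained component count is $K = \min(5, k_{80})$, $k_{80}$ the
smallest $k$ whose cumulative explained variance reaches 0.80. The cap is
applied after the threshold ("5 or fewer"); both knobs are arguments.
Principal-component signs are indeterminate, so each component is oriented
to make its largest-magnitude loading positive — required for reproducible
"positively/negatively correlated" codon sets.

Interpretation rules mirror common practice for loading tables:

* a codon *passes* on a component when $|\mathrm{loading}| \ge 0.2$;
* an amino acid is *highlighted* when at least two of its synonymous
  codons pass on that component, pooled across signs by default (mixed-sign
  pairs are informative; `per_sign = TRUE` restores the stricter rule);
  all passing codons remain in the raw listing;
* samples are *described* by a component when their signed score exceeds 5
  (strict inequality; `absolute = TRUE` applies the rule to magnitudes,
  useful when negative-quadrant samples matter);
* each reported codon set carries a wobble-position nucleotide ranking
  such as `"C>G>T>A"` (`=` joins ties, ties print alphabetically). The
  third position is used because synonymous variation concentrates there;
  an all-positions mode exists.

## 5. Cluster number and clustering methods

Four heuristics are computed per candidate $k$ on a common centroid-based
reference partition (k-means, 10 restarts) — inertia is only defined for
centroid partitions, and using one reference keeps the four curves
comparable. Best-$k$ rules: silhouette maximum, Calinski–Harabasz maximum,
Davies–Bouldin minimum, and the knee of the inertia curve. The knee scan is
anchored at $k=1$ (total sum of squares): candidate grids start at 2, and
without the $k=1$ point an elbow at the smallest candidate is geometrically
invisible; a knee at 1 maps to the smallest candidate.

The consensus rule: if two or more heuristics agree, that modal value wins
(two modes tied at multiplicity two → the smaller, for parsimony); with no
agreement, the lower median (second order statistic) of the four values —
an integer from the candidate set by construction. The implementation is
tested against an independently coded oracle on all 1,296 four-tuples over
2..7.

The four methods follow fixed parameter protocols:

* **k-means** — stage one draws 30% of samples without replacement and
  runs 5 random initializations capped at 3 Lloyd iterations, keeping the
  lowest-inertia centers; stage two refines on the full data to
  convergence. If the subsample is smaller than $k$, stage one falls back
  to the full data (logged).
* **spectral** — rows are L2-normalized; both a Gaussian (rbf) kernel and
  a symmetrized $\lfloor n/4 \rfloor$-nearest-neighbor connectivity graph
  are embedded via the normalized Laplacian, and the labeling with the
  higher silhouette is kept; a disconnected neighbor graph falls back to
  the kernel with a warning. Row normalization projects samples onto the
  unit sphere, so structure must survive that projection: geometry
  centered exactly at the origin collapses, which the test constructions
  respect by offsetting ring fixtures onto a plane.
* **DBSCAN** — `min_samples` $= 2K$ ($K$ = retained PCA dimensions); eps
  at the knee of the sorted min_samples-th nearest-neighbor distance
  curve. The knee rule presumes the curve has a bend, i.e. the data are
  dense with bounded spread; on heavy-tailed clouds the selected eps
  leaves tail points as noise (label −1), which is reported, and an
  all-noise result is flagged degenerate rather than silently returned.
* **agglomerative** — Ward linkage on Euclidean distances, labels by
  cutting the retained tree (exportable as Newick).

Validation against external labelings (tissue state; embryonic day) uses
ARI, AMI (hypergeometric expected MI, arithmetic-mean normalization),
V-measure, homogeneity and completeness, all computed from the
contingency table in-package (no R equivalent of the full metric set was
available) and cross-checked in the tests against an independent ARI
implementation and closed-form cases. DBSCAN noise points are kept as
their own category by default — excluding them would inflate agreement —
with `drop_noise = TRUE` available. The best method is the arg-max of the
five metrics averaged over the two references; ties break by tissue-state
ARI, then by a fixed method order (agglomerative, k-means, spectral,
DBSCAN).

## 6. Codon-wise statistics

Per synonymous codon (59 testable), group A and B RSCU values are compared
with the exact two-sided Mann–Whitney U test:
$U = \sum_{i,j} [x_i > y_j] + \tfrac12 [x_i = y_j]$, with the two-sided
p-value $P(|U' - n_1 n_2/2| \ge |U - n_1 n_2/2|)$ under the permutation
null over all $\binom{n_1+n_2}{n_1}$ group assignments. The null is
enumerated exactly when that count is ≤ 2×10⁶; tie-free larger inputs use
the exact no-ties distribution (`stats::dwilcox`); large tied inputs fall
back to a fixed-seed 10⁵-permutation Monte Carlo estimate with the
add-one correction keeping $p > 0$. The method used is recorded per test.

Bonferroni adjustment is $\min(1, N p)$ with $N$ = the number of tests
actually performed in the comparison family (codon × stratum within one
call); a wider declared family can be passed explicitly. Significance
means adjusted $p \le 0.05$.

Effect sizes use the unequal-variance Cohen's $d$,
$(\bar x - \bar y)/\sqrt{(s_1^2+s_2^2)/2}$ with $n-1$ variances (the
pooled form is a flag), binned contiguously on $|d|$: very small
$[0, 0.2)$, small $[0.2, 0.36)$, medium $[0.36, 0.66)$, large
$[0.66, 1]$, very large $> 1$. The conventional printed bins leave gaps
(0.1–0.2 and 0.9–1 unassigned); the contiguous bins honor every printed
boundary while classifying every value.

With strata (e.g. embryonic stages), tests run per (codon, stratum) with
at least 2 samples per group per stratum; undersized strata and codons
with undefined RSCU are skipped and reported, and each stratum's share of
the significant results is summarized — the "which stages drive the
difference" view.

## 7. The synthetic study generator

`generate_study()` produces everything the pipeline consumes, plus ground
truth. Design and defaults (the package's study conditions, chosen once):

* **CDS** — 150 genes per set, lengths log-normal around 300 codons
  (minimum 50), amino-acid backbones uniform with an enforced Met start,
  codons drawn per family from preference simplices. Uniform preferences
  give expected RSCU 1 everywhere; the disease set's preferences are
  reweighted so each target codon's expected RSCU becomes $1 + \delta$
  ($p \mapsto p + \delta/k$, the rest of the family rescaled; requests
  exceeding the family size are rejected). Default targets are six
  two-codon-family codons (TTC, TAC, CAC, AAC, GAC, TGC) at
  $\delta = 0.4$.
* **Expression** — TPM is log-normal per gene × sample, meanlog 3 and
  sdlog 2. The large sdlog reflects the order-of-magnitude per-gene
  expression changes seen across embryonic stages, and it is what makes
  sample-to-sample reweighting the dominant noise source — the regime in
  which the two gene sets' profiles are effectively exchangeable at
  $\delta = 0$. A stage-linear trend on a random half of the genes and
  per-gene additive batch shifts (sd 0.5 on log-TPM, batches cycling
  SRR/ERR) supply structured nuisance variation for the batch module to
  remove.
* **Ground truth** — shifted codons, per-sample batch/stage/strain, and
  the generator config itself, emitted alongside the files.

Two named configurations serve different purposes:

* the **calibration/power study** (the defaults): at $\delta = 0$ the
  mean significant fraction over replicates stays below $\alpha$; at
  $\delta = 0.4$ with 20 samples per group all planted codons are
  Bonferroni-significant in ≥ 90% of replicates. Both properties are
  computed by the acceptance tests at 100 and 50 replicates respectively.
* the **clustering-recovery study**
  (`synthetic_config(delta = 0.8, n_genes = 300, tpm_sdlog = 1)`): a
  planted two-group structure separated by roughly an order of magnitude
  more than the within-group spread on the leading component, on which
  the full pipeline recovers the tissue-state split (consensus $k = 2$,
  best-method ARI ≥ 0.8, typically 1) and reruns under one seed are
  byte-identical.

What the generator does **not** emulate: read-level sampling noise
(counts are abundances, not reads), gene–gene expression correlation,
isoform structure, GC/amplification biases, real codon-usage landscapes
(baseline preferences are uniform, real families are skewed), and
tissue-specific gene-set overlap (sets are disjoint). Passing tests
therefore demonstrate the pipeline's statistical behavior under a clean
generative model — calibration, power, recovery — not biological
conclusions about any real tissue.

One consequence of the design is worth stating: the two gene sets are
finite draws, so even at $\delta = 0$ their realized codon compositions
differ slightly, and those differences are *systematic* across samples.
With expression noise at its default scale this composition offset is
well below the detection threshold; at low noise (as in the
clustering-recovery study) the tests genuinely detect it. That mirrors
the real design this emulates — the same samples weighted by two
different gene lists — where "no planted shift" is not the same as "no
difference".

## 8. Numerical choices and degenerate inputs

* Knee detection is the normalized max-distance-below-chord rule, shared
  by the inertia elbow and the DBSCAN k-distance curve; flat curves have
  no knee (`NA`), which DBSCAN converts into an actionable error
  recommending an explicit eps.
* Exact-test p-values compare deviations with a $10^{-9}$ slack so
  floating-point ties in $|U - \mu|$ count as ties.
* Standardization flags constant features instead of dividing by zero;
  PCA reconstruction from the full basis is asserted to $10^{-8}$.
* `consensus_k` and all clustering front-ends accept either a
  `sample_id` tibble or a plain matrix; every assignment is invariant (up
  to relabeling) under row permutation, and evaluation metrics are
  invariant under label permutation — both property-tested.
* All stochastic stages take a `seed`; the generator is byte-deterministic
  under it, and `run_analysis()` writes reports with no timestamps so
  reruns are byte-identical.

Problem sizes in the tests and acceptance script (1,000 random profiles,
100 null and 50 power replicates, 50-point cluster fixtures, all 1,296
consensus tuples) were chosen as the smallest sizes at which the asserted
properties are statistically stable.

## 9. Known limitations

* The exact test's tie policy (pair-counting with ½ weights and
  permutation of midranks) is one defensible convention; others exist.
* AMI's expected-MI term is $O(k_1 k_2 n)$ — fine at study scale,
  noticeable above ~10⁴ samples.
* ComBat's EB shrinkage trades per-feature exactness for stability (see
  §3); analyses needing exact per-feature gap removal should use a
  fixed-effects adjustment instead.
* The spectral protocol's row normalization assumes structure survives
  projection to the unit sphere; data whose clusters differ only in norm
  will collapse.
* `compare_groups` treats samples as exchangeable units; repeated
  measures of the same animal would need a hierarchical extension.
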