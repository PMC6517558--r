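---
title: "Rare-variant burden and phenotype clustering in case-only gene-panel cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden and phenotype clustering in case-only gene-panel cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecohort)
```

# Scope and model

`rarecohort` analyses a case-only cohort sequenced over a candidate-gene
panel. It operates on five inputs: a multi-sample VCF with per-site quality
annotations, a variant annotation table, a gene-panel table (RVIS
percentiles and background carrier probabilities), a phenotype table, and a
binarized clinical questionnaire. The pipeline has four statistical stages —
variant filtering, per-gene carrier-excess testing, weighted burden with
phenotype association, and questionnaire clustering with cluster–gene
enrichment — plus a synthetic-cohort generator that makes all of them
testable without access to patient data.

# Variant filter cascade

A variant qualifies when it survives, in order:

1. **Quality**: read depth > 10, mapping quality > 40, quality-by-depth > 2,
   all strict inequalities. Records with missing quality fields are rejected
   with a warning rather than guessed at.
2. **Canonical transcript**: when the annotation table marks transcripts
   with a logical `canonical` column only those rows are kept; otherwise
   each variant is assumed to be annotated on its canonical transcript
   already.
3. **Rarity**: at most 1 homozygous-or-hemizygous carrier AND at most 2
   heterozygous carriers within the cohort (a conjunction of caps — the
   disjunctive reading would admit unlimited heterozygotes, contradicting
   the ~5‰ cohort MAF such a cap corresponds to), and every *available*
   reference MAF (1000 Genomes European, ExAC, in-house) strictly below 5%.
   A missing reference MAF passes: absence from reference databases is
   evidence *of* rarity. Hemizygous calls (single-allele genotypes on
   X-linked genes in males) count against the homozygous cap, since one
   allele is all that is present.
4. **Effect**, by mode: `rare_all` keeps all non-synonymous consequences
   (missense, frameshift, stop-gained, canonical splice, in-frame indel);
   `rare_predicted_damaging` additionally requires loss-of-function
   (frameshift/stop/canonical-splice) or damaging missense (CADD phred ≥ 20
   OR meta-SVM "damaging" — an OR, so either predictor suffices);
   `known_pathogenic` instead keeps quality-passing, canonical variants
   carrying the ClinVar/HGMD flag regardless of rarity or prediction.

Whether a burden analysis should use all rare variants or only
predicted-damaging ones is a genuinely open question in this design; both
are exposed as modes and the carrier matrix records which mode produced it.
Multi-allelic records are decomposed into bi-allelic entries before any rule
is applied, because every rule is per-allele. Variants annotating genes
outside the panel are excluded with a reported count.

The result is the carrier matrix `v_ig`: qualifying-variant counts per
individual per gene, with columns in panel order.

# Per-gene carrier excess

For gene *g*, let `k` be the number of carrier individuals (≥ 1 qualifying
variant) among the `n` unrelated cohort members and `p_g` the background
probability that a reference-population individual carries ≥ 1 rare variant
in the gene. The test statistic is the exact binomial upper tail
`P(X ≥ k) = Σ_{i=k..n} C(n,i) p_g^i (1−p_g)^{n−i}`, computed via
`pbinom(k−1, n, p_g, lower.tail = FALSE)` for numerical stability; the suite
verifies agreement with direct pmf summation to 1e−12 over every `k ≤ n ≤ 20`
and `p_g ∈ {0.01, 0.1, 0.5}`.

Design choices worth stating:

* **Carriers, not variants, enter the test.** The binomial model is about
  carrier individuals; the scan reports the per-gene variant count
  separately so both readings of "counts" are explicit.
* **Sib-pairs are excluded from the p-value** and reported descriptively as
  `s / n_sib` shared events (both members carrying ≥ 1 qualifying variant in
  the gene). Siblings are not independent draws from the background
  distribution, and a full sib-likelihood would require inheritance
  information the carrier matrix does not retain.
* **No multiple-testing correction by default** — raw per-gene p-values
  mirror how such scans are usually tabulated — with a Bonferroni option
  over the panel (`bonferroni = TRUE`).
* `p_g = 0` with observed carriers is a model violation; the scan reports
  p = 0 with a warning instead of failing.

# RVIS-weighted burden and phenotype association

Gene weights are `w_g = 1 − RVIS percentile / 100` (percentile in (0, 100]),
so the most intolerant genes weigh most; burden is the weighted sum
`B_i = Σ_g v_ig w_g`. Siblings are scored separately — different rare
variants may contribute to each sib's phenotype. Burden–severity and
burden–malformation relationships use ordinary least squares (`stats::lm`),
reporting slope, R², and the two-sided slope p-value on n−2 df. Group
comparisons (burden by sex, malformations by syndromic status) use the
two-tailed t-test, **Welch by default** since equal variances are an
unnecessary assumption; `var_equal = TRUE` restores the pooled test.
Calibrated severity scores are a deterministic lookup in a user-supplied
(module, age band, raw range) table; out-of-range raw totals clamp to the
nearest band with a warning, and the packaged table
(`severity_table_synthetic.tsv`) is synthetic, for tests only.

# Questionnaire clustering

The similarity between two individuals is the plug-in mutual information of
their binary response vectors over the questionnaire items, in bits
(`Σ p(a,b) log2 p(a,b)/(p(a)p(b))` over the pooled empirical 2×2 joint,
`0·log 0 ≡ 0`). Bits are the conventional unit for binary data; `base`
switches to nats. Missing responses are dropped pairwise, and individuals
with more than 50% missing items are excluded (both configurable, since real
questionnaires rarely document their missing-data conventions). The diagonal
of the similarity matrix is each individual's response entropy, the MI of a
vector with itself.

Clustering is Ng–Jordan–Weiss spectral clustering: the affinity is the MI
matrix with its **diagonal zeroed** (the reference algorithm defines
`A_ii = 0`; entropy is self-similarity, not affinity), normalized as
`D^{−1/2} A D^{−1/2}`; the top-k eigenvector rows are unit-normalized and
clustered by k-means. We use base R's Hartigan–Wong k-means with 50 random
restarts under a fixed seed rather than a k-means++ initializer — with this
many restarts on an n × k embedding the two are interchangeable in practice,
and the fixed seed keeps runs reproducible. `k = 4` is the default cluster
count, in line with the small number of phenotype subgroups reported for ASD
cohorts. A similarity graph with more connected components than `k` is an
error (the embedding would be degenerate), reported with advice rather than
silently mis-clustered.

The 3-D embedding for visualization is kernel PCA: double-center the kernel,
take the top-3 eigenpairs, scale eigenvectors by √eigenvalue. The MI matrix
need not be positive semi-definite, so components with non-positive
eigenvalues are dropped (reported) and replaced by zero coordinates;
eigenvector signs are fixed by forcing the largest-magnitude loading
positive so embeddings are deterministic. Cluster characterization is the
per-cluster relative frequency of each item (missing responses excluded from
the denominator) and the top-10 items per cluster, ties broken
lexicographically; top lists of different clusters may overlap.

# Cluster–gene enrichment

Per gene, per-individual qualifying-variant counts are compared across
clusters with classic (pooled-variance) one-way ANOVA, then pairwise
pooled t-tests over all cluster pairs. Counts are the default test variable
("0/1/2+ variants" is count-like information); `use_carrier_flag = TRUE`
switches to the 0/1 carrier indicator. Bonferroni families are explicit and
separate: the ANOVA family is the number of testable genes; the pairwise
family is testable genes × cluster pairs. Genes with zero variance are
untestable and reported as such, never flagged. With two clusters the ANOVA
F equals the squared pooled t statistic, which the suite checks to 1e−10.

The distribution of syndromic cases over clusters is tested against
expectations proportional to cluster sizes: chi-square when all expected
counts are ≥ 5, otherwise an exact multinomial test that enumerates all
allocations of the syndromic cases and sums the probability of tables with a
chi-square statistic at least as extreme.

# The synthetic cohort: what it does and does not emulate

Defaults mirror the target study design: 164 unrelated cases + 5 sib-pairs
(174 individuals), a 101-gene panel with background carrier probabilities
drawn uniformly from [0.01, 0.12] (typical reference carrier fractions for
rare variants in a gene), a 149-item questionnaire with 4 planted clusters,
a ~2.9:1 male:female ratio, and a 13/174 syndromic rate.

* **Genotypes.** Each unrelated individual carries ≥ 1 qualifying variant in
  gene *g* with probability `p_g × multiplier_g`; one heterozygous SNV is
  planted per carrier event at a distinct position, so the statistics
  downstream depend only on carrier/variant counts, which is all they use.
  Each sib-pair/gene carrier event simulates one heterozygous carrier
  parent; each sib inherits independently with probability ½ (the simplest
  Mendelian model consistent with shared-variant accounting), so a pair
  shares the variant with probability ¼ given the event and each sib's
  marginal carrier probability through this channel is `p_g/2`. All
  simulated individuals are cases (a case-only cohort); whether real
  sib-pairs are concordant by design is not modelled.
* **Quality fields** are drawn to pass the filter; `n_fail_quality`,
  `n_fail_rarity` and `n_synonymous` inject records the cascade must drop,
  for filter tests. The emitted VCF and annotation table round-trip through
  `load_cohort()` + `filter_cascade()` to reproduce the generator's carrier
  matrix exactly — an identity the suite asserts at cohort size 200.
* **Questionnaires** are Bernoulli mixtures: 30 discriminative items
  assigned round-robin to clusters at probability 0.9 in the owning cluster
  and 0.1 elsewhere, remaining items at 0.1 in every cluster. Item
  probabilities sit on the support {0.1, 0.9} by design, and 0.1 is a
  realistic positive rate for binarized clinical findings, most of which are
  rare. A caveat discovered while validating the pipeline: the pooled-2×2
  plug-in MI can lose almost all cluster contrast when non-discriminative
  items sit near p ≈ 0.3, where correlated and anti-correlated item
  contributions nearly cancel; recovery is excellent for background rates
  well below (0.05–0.1) or above (0.5) that band. Real questionnaires with
  many moderately-common uninformative items may therefore cluster less
  cleanly than these simulations.
* **Phenotypes** are a linear ADOS–burden link with Gaussian noise, Poisson
  malformation counts and Bernoulli sex/syndromic flags — enough to test
  parameter recovery and error control, not a model of real symptom scales
  (no floor/ceiling effects, no age dependence).
* Not emulated: haplotype structure, linkage disequilibrium, recurrent
  mutation, de-novo vs inherited status, genotype-questionnaire coupling.
  Passing recovery tests therefore demonstrate the statistical machinery,
  not robustness to those real-data features.

Fixed seeds make every generator output bit-identical across runs; all
randomness flows through R's RNG seeded once per call.

# Problem sizes and numerical conventions

The test suite exercises the pipeline at the design cohort size where the
property matters (spectral recovery at n = 160 over 20 seeds; enrichment
error control over 200 replicates of a 160 × 101 cohort; round-trip identity
at n = 200) and at reduced sizes for distributional checks (carrier-count
Kolmogorov–Smirnov at n = 30 with a parametric-bootstrap critical value,
since the binomial is discrete). Tolerances: exact arithmetic identities at
1e−12, eigen-based identities at 1e−10. Display rounding is half-up to two
decimals (7.475 → 7.48); machine-readable outputs keep full precision.
Degenerate inputs have defined behaviour throughout: empty variant sets give
zero matrices, constant response vectors give zero MI, all-equal kernels
give a zero embedding with a warning, and constant regressors or zero-variance
genes are errors or untestable rather than NaNs.

# Known limitations

* The carrier-excess test conditions on the panel's background carrier
  probabilities being correct for the ancestry at hand; mis-specified `p_g`
  shifts all p-values. The probabilities ship as a user-supplied panel
  column for exactly this reason.
* Sib-pair information never enters any p-value; with many families the
  descriptive `s / n_sib` accounting wastes information.
* The plug-in MI estimator is biased upward (~1/(2N ln 2) for independent
  binary pairs over N items) and noisy at 149 items; the spectral step
  tolerates the constant bias but the cancellation band noted above is an
  intrinsic estimator property, not an implementation artifact.
* Bonferroni is conservative for correlated genes and clusters; permutation
  FWER control would be sharper but is out of scope.
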