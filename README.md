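# rarecohort

Cohort-level rare-variant analysis for candidate-gene panels in case-only
cohorts, built around the analysis needs of autism spectrum disorder (ASD)
gene-panel studies. Such studies sequence a panel of ~100 candidate genes in
a cohort of a few hundred cases (often including sib-pairs) and ask three
questions that this package answers:

1. **Which genes carry more rare variants than expected?** After a
   quality/rarity/effect filter cascade, the number of carrier individuals
   `k` among `n` unrelated cases is tested per gene against a
   reference-population background carrier probability `p_g` with the exact
   binomial upper tail `P(X ≥ k), X ~ Bin(n, p_g)`. Sib-pair shared-variant
   events are reported descriptively alongside (`s / n_sib`).
2. **Does aggregate rare-variant burden track phenotype severity?** Each
   individual's burden is `B_i = Σ_g v_ig · w_g`, where `v_ig` counts
   qualifying rare variants and `w_g = 1 − RVIS percentile / 100` weights
   genes by intolerance to functional variation (a gene at the 2nd RVIS
   percentile gets weight 0.98). Burden is related to ADOS severity and
   minor-malformation counts by ordinary least squares, and compared across
   sexes and syndromic status with two-tailed t-tests.
3. **Do clinical subphenotypes exist, and are genes enriched in them?**
   Binarized clinical questionnaires (~149 items) are turned into a pairwise
   mutual-information kernel `S[i,j] = MI(row_i, row_j)` (bits), clustered by
   normalized-Laplacian spectral clustering (k = 4) and embedded by 3-D
   kernel PCA; per-gene variant counts are then compared across clusters
   with one-way ANOVA and pairwise t-tests under Bonferroni correction.

Because patient-level data from such studies are not publicly deposited, the
package ships a synthetic-cohort generator (`sim_config()`,
`simulate_genotypes()`, `simulate_questionnaire()`,
`simulate_phenotypes()`) that emulates the cohort structure — 164 unrelated
cases plus 5 sib-pairs, a 101-gene panel with optional planted enrichment,
and Bernoulli-mixture questionnaires with 4 planted clusters — so every
stage is testable end to end, including an exact round-trip identity between
the generator's carrier matrix and the filter cascade's output.

## Worked example

```r
library(rarecohort)

panel <- synthetic_panel(n_genes = 101, seed = 1)
cfg   <- sim_config(n_unrelated = 164, n_sibpairs = 5, panel = panel,
                    enrichment = c(GENE007 = 3), seed = 42)
sim    <- simulate_genotypes(cfg, dir = tempfile("demo"))
cohort <- load_cohort(sim$vcf_path, sim$annotation_path)
res    <- filter_cascade(cohort, panel, mode = "rare_all")
nrow(res$variants)
#> [1] 1117

scan <- sorva_scan(res$carriers, panel, families = sim$families)
head(scan[order(scan$p_value), c("gene","k","n","s","n_sib","p_value")], 3)
#>     gene  k   n s n_sib      p_value
#>  GENE007 33 164 0     5 2.429440e-09
#>  GENE021 17 164 0     5 3.668863e-02
#>  GENE022 16 164 0     5 5.692690e-02

b  <- burden_score(res$carriers, panel)        # mean(b) = 3.066
ph <- simulate_phenotypes(b, families = sim$families, seed = 42)
fit <- regress(b, ph$ados_raw)                 # R2 = 0.0000, p = 0.992

q   <- simulate_questionnaire(default_cluster_spec(n = 174), seed = 42,
                              ids = sim$sample_ids)
S   <- similarity_matrix(q$matrix)
lab <- spectral_cluster(S, k = 4, seed = 42)
table(lab)                                     # 44 43 43 44 (ARI vs truth: 1)

enr <- enrichment_scan(res$carriers, lab)
sum(enr$anova$flagged)
#> [1] 0

diagnostic_yield(13, 4, 174)[c("total_pct_display", "excl_screen_pct_display")]
#> $total_pct_display 7.47   $excl_screen_pct_display 5.17
```

Reading the output: the gene planted with a 3× enriched carrier probability
(`GENE007`, 33 carriers of 164 vs. a ~6% background) is flagged at
p ≈ 2.4e-9 while the rest of the panel stays near the null; burden shows no
association with the (independently simulated) ADOS scores, as expected
under a zero planted slope; the four planted questionnaire clusters are
recovered exactly; no gene is spuriously enriched in any cluster after
Bonferroni correction; and 13 syndromic diagnoses among 174 cases amount to
a 7.47% diagnostic yield (5.17% excluding the 4 cases found by screening).

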