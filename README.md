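# funcpanel

Tools for asking a practical dairy-breeding question: if you replace a
generic SNP-chip panel with an equally sized panel of *functionally
selected* sequence variants — production-trait GWAS tags, cis molecular-QTL
tags from RNA-seq (exon/intron expression, splicing efficiency,
allele-specific expression), allele-specific binding and chromatin-QTL
tags, and predicted-deleterious coding variants — how much genomic
prediction accuracy do you gain or lose?

The package implements the full comparison pipeline:

* **Synthetic populations** with block-wise LD (haplotype-mosaic founders),
  functional-class annotations, class-enriched causal variants, fixed
  effects, percent/volume traits, and yield traits formed as
  percent × volume with compounded measurement noise; plus allelic and
  splice-junction read counts for molecular-QTL testing.
* **Phenotype adjustment** to yield deviations by least squares on
  `y = X beta + e` (contemporary group, breed, heterosis, inbreeding,
  optional Legendre days-in-milk covariates).
* **Variant tagging**: iterative conditional GWAS (per-chromosome top hit
  at p < 1.9e-10 refitted as a covariate until no new hits), cis-window QTL
  scans (1 Mb, class-specific thresholds, MAF > 0.1), and the two-stage
  allele-specific test (pooled binomial Z gate at 1e-3, then a log
  allelic-ratio regression).
* **Panel construction**: chip-style QC (MAF ≥ 0.02, call rate ≥ 0.9,
  r² ≤ 0.9 pruning, exact HWE test at p ≥ 0.15), LD blocks at r² = 0.98
  with prioritised block representatives, MAF-bin (width 0.05) spectrum
  matching, biallelic + MAF ≥ 0.1 final filter, and size-matched random
  baseline panels.
* **BayesCπ** whole-genome regression by Gibbs sampling (compiled C++,
  seed-reproducible): each marker is in the model with probability 1 − π,
  effects share a common variance, π gets a uniform prior updated as
  Beta(m − k + 1, k + 1). GEBVs are dosage-weighted posterior mean effects.
* **Evaluation**: k-fold cross-validation with a shared fold plan, accuracy
  = Pearson correlation of GEBV with adjusted phenotype in the held-out
  fold, and improvement = 100 × (Functional − Current)/Current.

## Worked example

```r
library(funcpanel)

cfg <- sim_config(n_individuals = 800, n_chromosomes = 3,
                  variants_per_chromosome = 150, n_causal_per_trait = 15,
                  causal_enrichment = c(GWAS = 1e6, eeQTL = 1e6, aseQTL = 1e6,
                                        ieQTL = 1e6, seQTL = 1e6, asbQTL = 1e6,
                                        ChIPseqQTL = 1e6, ATACQTL = 1e6,
                                        coding = 1e6),
                  seed = 201)
pop <- simulate_population(cfg)
catal <- assign_functional_classes(pop$catalog, cfg)
ph <- simulate_traits(pop$genotypes, catal, cfg)

X <- build_design(ph, list(factors = c("contemporary_group", "breed"),
                           covariates = c("heterosis", "inbreeding")))
adj <- fit_and_adjust(ph, X, c("fat_pct", "fat_yield"))$adjusted

func <- final_filter(catal$variant_id[nzchar(catal$classes)], catal)
func$name <- "functional"
cur_ids <- catal$variant_id[!nzchar(catal$classes)]
cur <- benchmark_qc_filter(pop$genotypes[, cur_ids],
                           catal[match(cur_ids, catal$variant_id), ])
func$variant_ids <- func$variant_ids[seq_len(min(length(func), length(cur)))]

report <- benchmark_experiment(
  list(functional = func), cur, pop$genotypes, adj,
  traits = c("fat_pct", "fat_yield"),
  config = bayescpi_config(chain_length = 2000, burn_in = 400, thin = 4,
                           assumed_h2 = 0.5),
  k = 5, seed = 7)
print(report)
```

```
Panel benchmarking report (k = 5 folds)
       panel     trait n_variants accuracy baseline_accuracy improvement_pct
1 functional   fat_pct         79    0.726             0.538            34.9
2 functional fat_yield         79    0.695             0.510            36.3
```

Reading the output: with the causal variants planted inside the functional
annotation classes, the 79-variant functional panel predicts the adjusted
fat-percent phenotype with accuracy 0.73 versus 0.54 for a random panel of
the same size drawn from the generic (unannotated, QC-filtered) panel — a
+35% improvement — and the yield trait, which carries compounded
percent × volume measurement noise, is predicted less accurately than the
percent trait on both panels (0.70 vs 0.73 functional, 0.51 vs 0.54
baseline).

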