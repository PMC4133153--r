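# poptrans

Statistical toolkit for **multi-population RNA-seq studies**: given
genotypes, gene/transcript quantifications, allelic read counts and
coverage tracks for individuals sampled from several populations, it
answers the questions such studies ask —

* Are replicates and samples usable? (optimal-power-space transforms,
  per-sample **D-statistics**, outlier flags)
* Are counts biased by GC content and feature length? (**CQN-style
  offsets**: median quantile regression on natural cubic splines in GC
  and log-length, knots at the 2.5/25/50/75/97.5% quantiles)
* Which genes differ in expression across populations? (**negative
  binomial GLM** with offsets, ANOVA likelihood-ratio tests,
  conditional **exact tests** for pairs, moderated dispersions,
  Benjamini–Hochberg FDR)
* How much expression variation is attributable to population, and is it
  expression or splicing? (**Hellinger-distance** splicing variability,
  distance-based **PERMANOVA R²** with permutation p-values, and an exact
  log-scale decomposition `log2 t' = log2 e + log2 s` splitting the
  between-population signal into expression and splicing shares)
* Do cis-regulatory variants act in these populations? (**allele-specific
  expression**: exact binomial tests at heterozygous sites, downsampled
  to 30 reads, compensated by each individual's overall reference ratio;
  normalized ASE **sharing**; **eQTL enrichment** in heterozygous
  carriers; cross-study eQTL replication by Spearman ρ² with MAF
  stratification)
* How differentiated are the populations? (**Weir–Cockerham F_ST** as
  variance components combined ratio-of-sums, UPGMA trees, PCA, Mantel
  tests)
* Where is unannotated transcription? (coverage threshold of 0.05
  reads/million, merging of gaps shorter than 15 bp, max-coverage
  expression, per-individual RPKM, population-ubiquity filter)

Because the matching raw data are large external deposits, the package
ships a first-class **synthetic cohort generator** (`simulate_cohort()`)
with Balding–Nichols population structure, NB counts with planted
GC/length biases and population/eQTL effects, Dirichlet splicing ratios,
beta-binomial-style allelic counts with reference-mapping bias, and
coverage tracks with planted segments — all recorded in a `truth` object
so every estimator is validated by parameter recovery.

The core model, in the field's notation: counts follow
`y_gi ~ NB(mu_gi, phi)` with `log mu_gi = beta_0g + beta_{g,x_i} + o_gi`,
where `x_i` is individual *i*'s population label and `o` the CQN offset;
the ANOVA compares `beta = 0` against `beta != 0`. Splicing-profile
population structure is quantified by `R² = 1 − SSW/SST` on pairwise
squared distances of `log2` transcript abundances, with label-permutation
p-values.

## Worked example

```r
library(poptrans)

cfg <- sim_config(n_genes = 120, n_sites = 300, baseline_sd = 2,
                  frac_de_genes = 0.2, pop_expression_sd = 1, seed = 7)
cohort <- simulate_cohort(cfg)

# QC: D-statistics (median pairwise correlation on OPS-transformed FPKM)
qc <- d_statistics(cohort$fpkm)
head(qc, 3)
#>   sample     d outlier
#> 1 ind01  0.873 FALSE
#> 2 ind02  0.857 FALSE
#> 3 ind03  0.885 FALSE

# Genetic differentiation (the generator planted F_ST = 0.1)
fst <- pairwise_fst(cohort$genotypes$dosage, cohort$labels)
round(fst[1:3, 1:3], 3)
#>       pop1  pop2  pop3
#> pop1 0.000 0.109 0.121
#> pop2 0.109 0.000 0.102
#> pop3 0.121 0.102 0.000

# Differential expression with CQN offsets and moderated dispersion
offsets <- cqn_offsets(cohort$counts, cohort$gc, cohort$length)
kept    <- filter_features(cohort$fpkm, cohort$length)  # FPKM >= 2, >= 100 bp
disp    <- estimate_dispersion(cohort$counts[kept, ], cohort$labels)
de      <- de_anova(cohort$counts[kept, ], cohort$labels,
                    offsets[kept, ], disp)
glance(de)
#>   n_features n_significant n_flagged alpha
#> 1        120            30         0  0.05

# Splicing variance decomposition (20% of genes carry planted shifts)
prof <- splicing_profile(cohort$tensor)
dec  <- pop_variance_decomposition(prof, cohort$labels,
                                   genes = eligible_genes(cohort$tensor),
                                   n_perm = 100, seed = 7)
glance(dec)
#>   n_genes mean_r2 mean_r2_adj mean_share_expression
#> 1     118   0.226       0.118                 0.757

# Allele-specific expression with reference-bias compensation
ase <- ase_table_test(cohort$allele_counts, seed = 7)
eqtl_ase_enrichment(ase)$ratio
#> 12.84

# Novel transcribed regions
regions <- dplyr::bind_rows(lapply(cohort$coverage, call_regions))
nrow(regions)          # 17 called; 15 planted (noise adds small extras)
```

Reading the numbers: all samples clear the D < 0.8 outlier screen
comfortably (the cohort has no planted outlier); the pairwise F_ST matrix
recovers the planted differentiation of 0.1; 30 of 120 genes reach 5% FDR
(the generator planted population shifts in 24 plus eQTL effects);
`mean_r2` says ~23% of splicing-profile variation is attributable to
population in this cohort — note the plain R² carries a null expectation
of (G−1)/(n−1) ≈ 0.12 at this design, which is why the bias-adjusted
`mean_r2_adj` of 0.118 is the better effect-size readout — and ~76% of the
population-attributable variation is expression rather than splicing. The
het/hom ASE enrichment ratio of 12.8 reflects the planted cis effects.

`autoplot()` methods (for DE results, decompositions, PCA, QC reports),
`tidy()`/`glance()` and `plot_fst_tree()` cover the usual displays, and
`run_pipeline(cfg, out_dir)` writes every stage's outputs plus a run
manifest; `write_cohort()` / `read_*` round-trip all inputs through
VCF, TSV, BED and bedGraph-like text formats.

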