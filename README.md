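# crossgs

Genomic selection (GS) replaces phenotypic evaluation with predictions of a
line's genetic merit — its genomic estimated breeding value (GEBV) — from
genome-wide markers. It works well inside a breeding population, but
breeders would like to train a model on one population and predict another,
and in practice that often fails. `crossgs` is an R toolkit for studying
exactly that question in multi-family inbred wheat-style material scored
with dominant presence/absence markers (DArT-like, coded 0/1 on fully
homozygous lines): it simulates realistic doubled-haploid (DH) and
recombinant-inbred-line (RIL) breeding populations, fits the standard GEBV
prediction models, and measures how prediction accuracy behaves within,
across and between populations — including a simulation experiment that
explains cross-population failure by the fraction of QTLs the populations
share.

## What is inside

* **Data model and I/O** — `marker_matrix`, `genetic_map` and
  `phenotype_table` objects with TSV/CSV readers and writers, per-marker
  mean imputation (`impute_missing`) and marker harmonization across
  populations (`intersect_markers`).
* **Breeding-population simulator** — inbred founders with a U-shaped
  allele-frequency spectrum, meiosis under the Haldane map function (no
  interference), DH lines (one meiosis, genome doubled) and RILs by
  single-seed descent (default 8 selfing generations, which carries roughly
  twice the recombination of a DH from the same cross), plus trait
  architectures: `n` QTLs with Normal(0, σ²ₐ) additive effects and Gaussian
  noise calibrated so the realized line-mean heritability matches its
  target.
* **Phenotype adjustment** — the augmented-design model
  `Y_ij = μ + G_i + B_j + e_ij` estimated against control cultivars
  repeated in every sub-block, the across-location ANOVA
  `Y_il = μ + G_i + Location_l + e_il` (method of moments when balanced,
  REML otherwise), and line-mean heritability
  `h² = σ²_g / (σ²_g + σ²_e / ℓ)`.
* **Five GEBV predictors** — ridge RR-BLUP
  (`β = (X'X + λI)⁻¹X'y`, with `λ = (1−h²)/h² · Σⱼ Var(xⱼ)`), Bayesian
  ridge regression and the Bayesian LASSO (Park–Casella) by Gibbs sampling
  with compiled inner loops, GBLUP on a marker kinship with spectral REML
  for the variance ratio, Gaussian-kernel RKHS regression (median-heuristic
  bandwidth), and Random Forest regression.
* **Relatedness and LD** — IBS (simple-matching) kinship with mean-diagonal
  normalization, within/between-population coancestry summaries, and LD as
  the squared genotype correlation `r²` (the haplotype `r²` for inbreds).
* **Evaluation** — Pearson-correlation accuracy, 80/20 resampling in three
  schemes (single-population, composite/pooled, cross-population), and
  `qtl_sharing_experiment()`, which maps mean accuracy over a grid of
  shared-QTL fractions (10–100%) and heritabilities.
* **Pipelines** — `load_config()` / `run_pipeline()` drive
  simulate → kinship → cv → qtl-share runs from a YAML file with strict key
  checking and a reproducibility manifest.

## Worked example

```r
library(crossgs)

# simulate two related DH breeding populations on a 21-chromosome map
map <- uniform_map(1000, n_chromosomes = 21, chrom_length_cM = 150)
founders <- simulate_founders(140, map, seed = 1)
panelA <- founder_subset(founders, 1:80)
panelB <- founder_subset(founders, 61:140)
dh1 <- simulate_population(panelA,
         random_cross_plan(panelA, 50, 6:8, "DH", seed = 2),
         seed = 3, population_id = "DH1")
dh2 <- simulate_population(panelB,
         random_cross_plan(panelB, 50, 6:8, "DH", seed = 4),
         seed = 5, population_id = "DH2")
dh1
#> marker_matrix 'DH1': 351 lines x 1000 markers (0.0% missing)

# a 100-QTL trait with line-mean heritability 0.82 expressed in DH1
poly <- colnames(dh1)[apply(unclass(dh1), 2, sd) > 0]
arch <- draw_architecture(poly, n_qtl = 100, h2 = 0.82, seed = 6)
y <- simulate_trait(dh1, arch, seed = 7)

# within-population cross-validation of ridge RR-BLUP (80/20, 50 rounds)
pops <- list(DH1 = list(geno = impute_missing(dh1),
                        pheno = setNames(as.numeric(y), names(y))))
cv <- run_cv(cv_scheme("single", "DH1", n_iterations = 50, seed = 8),
             pops, method = "ridge", h2 = 0.82)
cv
#> cv_result [single/ridge, trait]: mean r = 0.695 (sd 0.060, 50 iterations)

# how fast does cross-population accuracy decay with QTL sharing?
tab <- qtl_sharing_experiment(dh1, dh2, fractions = c(0.1, 0.5, 1),
                              h2_levels = 0.6, n_reps = 25, seed = 9)
print(tab, digits = 2)
#>   fraction  h2 mean_r  sd_r  se_r n_reps
#> 1      0.1 0.6  0.057 0.178 0.036     25
#> 2      0.5 0.6  0.210 0.110 0.022     25
#> 3      1.0 0.6  0.461 0.063 0.013     25
```

The within-population accuracy (r ≈ 0.70) is what a breeder can expect when
training and validation lines come from the same families. The last table
is the cross-population story: when the two populations express the same
100 QTLs (fraction 1.0) a model trained on DH1 predicts DH2 at r ≈ 0.46,
but as the shared fraction drops the accuracy falls roughly linearly, and
at 10% sharing it is near zero — unrelated genetic architectures cannot be
predicted across populations regardless of training size.

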