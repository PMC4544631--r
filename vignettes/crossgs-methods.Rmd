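---
title: "Models and methods behind crossgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crossgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crossgs` studies genomic selection (GS) in multi-family inbred breeding
populations genotyped with dominant presence/absence markers. This
vignette is the package's account of its models: what is assumed, which
parameters matter, how the synthetic populations are calibrated, and where
the numerical behaviour needs explaining.

## The genetic material and its coding

All material is fully homozygous: doubled haploids (DH) carry the genome of
a single F1 gamete, and recombinant inbred lines (RILs) after seven or more
selfing generations are homozygous at essentially every locus. A dominant
marker on such material is informative despite its dominance — every line
is either fixed for presence (1) or absence (0) — so genotypes are a 0/1
matrix with `NA` for failed calls and no heterozygote code. Missing calls
are imputed with the marker mean (its allele frequency), which preserves
column means and adds no spurious association; markers are deliberately
*not* filtered on minor allele frequency, since rare markers carry real
signal in family-structured panels. Fractional imputed values mean
downstream code never assumes strict 0/1 coding.

## The population simulator

The generator builds what a wheat pre-breeding program produces: a panel of
inbred founders, a set of crosses, and families of DH or RIL progeny.

**Founders.** Each founder is one haplotype. Per-marker allele frequencies
are drawn from a U-shaped Beta(0.2, 0.2) by default. The U-shape is what a
dominant hybridization panel looks like across elite germplasm — many
markers near fixation — and it is what makes the polymorphic subsets of two
populations realistic: with 2,500 mapped markers and two ~350-line
populations bred from overlapping 80-parent subsets of a 140-parent panel,
roughly 1,300–1,600 markers segregate within each population and on the
order of 1,100–1,300 segregate in both. Those are the conditions under
which the cross-population experiments are run.

**Meiosis.** Crossovers between adjacent markers occur with the Haldane
probability `r = 0.5(1 − exp(−2d))` for map distance `d` Morgans;
chromosomes segregate independently and each chromosome's starting phase is
a fair coin. Haldane (no interference) is the simplest model consistent
with centimorgan maps, and interference is irrelevant to the questions the
package asks (marker–QTL co-segregation at the few-cM scale). The default
genome is 21 chromosomes of 150 cM with uniformly spaced markers, a coarse
model of hexaploid bread wheat.

**DH vs RIL.** A DH line *is* one gamete of the F1. A RIL follows
single-seed descent: the F1 is selfed for `selfing_generations` (default 8,
the middle of the realistic 7–9 range) and any residually heterozygous
marker is fixed by a fair coin. Selfing keeps recombining until loci fix,
so RILs accumulate roughly twice the observable breakpoints of DHs from the
same cross. Two caveats govern how that "roughly 2×" is measured: it is an
asymptotic small-interval result — for an interval with recombination
fraction `r` the RIL recombination fraction is `2r/(1 + 2r)`, so the
expected count ratio on a grid of markers is about `2/(1 + 2r)` — and it is
only observable where the two parents differ. The map-expansion checks
therefore use a fully informative cross and ~3 cM marker spacing, where the
expected ratio is ≈1.9; sparser maps or partially informative crosses give
genuinely smaller observed ratios, which is a property of the measurement,
not of the meiosis model.

**Traits.** An architecture is `n_qtl` markers (default 100) drawn
uniformly without replacement from a candidate set — for cross-population
work, the markers polymorphic in and common to both populations — with
i.i.d. Normal(0, σ²ₐ) additive effects (σₐ = 1; the scale cancels out of
every correlation-based quantity). The genetic value is the effect-weighted
genotype sum, and Gaussian noise is added with variance
`Var(g)(1 − h²)/h²` computed from the *realized* genetic variance in the
target population, so the expected realized heritability equals the target
regardless of how much genetic variance the population happens to express.
QTL markers stay in the predictor matrix: markers are treated as QTL
proxies, and removing them would change the estimand (pure-LD tagging)
rather than the paper-style question.

**Partially shared architectures.** Two schemes are implemented for giving
two populations related traits. The default (`"independent"`) draws, for
each population independently, `round(f · n_qtl)` QTLs from the common
architecture; the expected shared proportion of either subset is `f` and
the realized overlap is hypergeometric (at `f = 0.1`, one shared QTL in
expectation — often zero). The alternative (`"overlap"`) keeps all QTLs in
the training trait and gives the validation trait a random fraction-`f`
subset, making the shared proportion exact. The independent scheme is the
default because the experiment's description ("subsets drawn
independently") maps onto it directly; the overlap scheme exists because
results phrased as "proportion of common QTLs" can also be read as the
realized overlap.

## Phenotype adjustment and heritability

Field plots follow an augmented design: test lines sown once, control
cultivars repeated in every sub-block. The model
`Y_ij = μ + G_i + B_j + e_ij` (both effects fixed) is solved by least
squares; unreplicated lines carry no information about blocks, so block
effects are identified entirely by the controls, exactly as the design
intends. Estimated block effects are centered (sum-to-zero) and subtracted;
the procedure is translation-equivariant and idempotent. Sub-blocks without
controls are an error naming the block, since their effects are not
estimable.

Across locations, `Y_il = μ + G_i + Location_l + e_il` with random
genotypes and fixed locations. Balanced data use expected mean squares —
`σ²_g = (MS_G − MS_E)/ℓ`, the genotype F test `MS_G/MS_E` — because the
moment solution is exact and exactly testable; negative estimates truncate
to zero with a flag. Unbalanced data fall back to REML (`lme4`). Line-mean
heritability is `h² = σ²_g / (σ²_g + σ²_e/ℓ)`, the repeatability of a line
mean over `ℓ` locations — the standard scale on which plant-breeding trial
heritabilities (e.g. ≈0.7 for yield, ≈0.8–0.9 for phenology) are reported.
Control cultivars are excluded from downstream GS by default: they are
replicated checks, not selection candidates.

## The five predictors

All linear methods center marker columns on *training* means and apply the
same centering to targets; the intercept is the training phenotype mean.

**Ridge RR-BLUP.** `β = (X'X + λI)⁻¹X'(y − ȳ)` with
`λ = (1 − h²)/h² · Σⱼ Var(xⱼ)`, the classical variance-partition tie
between shrinkage and heritability: if total genetic variance `h²·Var(y)`
is spread over markers with common effect variance σ²β, then
`λ = σ²_e/σ²_β` reduces to that expression. The default `h² = 0.37` is the
conventional anchor used when no trait-specific estimate is supplied. When
markers outnumber lines the numerically identical dual form
`β = X'(XX' + λI)⁻¹(y − ȳ)` is used.

**Bayesian ridge regression (BRR).** Same likelihood, common-variance
Gaussian prior on effects, scaled-inverse-χ² priors on both variances
(defaults: residual scale 4.5 with 3 df, effect scale 0.009 with 3 df —
weak priors that let the data set the shrinkage). The Gibbs sampler uses
per-marker scalar updates with residual bookkeeping (compiled); posterior
means are Rao-Blackwellized (the conditional mean `rhs/c` is averaged
rather than the draw), which cuts Monte-Carlo error substantially at no
cost. σ²β is initialized at a 50/50 variance partition so short chains do
not start from a near-zero-variance state, and monomorphic columns are
excluded from every degree-of-freedom count — including them silently
deflates σ²β by the fraction of dead columns and over-shrinks every effect.
Default chain lengths are 20,000 burn-in of 60,000 iterations; the test
suite uses shorter chains (2,000/8,000) because its targets are statistical
summaries of a well-mixing conjugate sampler, not bit-level chain state.

A point worth being precise about: the exact posterior mean under variance
uncertainty is *not* any single ridge solution. Conditional on the
variances the posterior mean is ridge, but averaging `(X'X + λI)⁻¹X'y` over
the posterior of λ is nonlinear in λ, and with weak priors at n ≈ 100 the λ
posterior is wide enough that the largest per-effect deviations from the
best-matching single ridge fit are on the order of 0.1 standard deviations
of the effect vector (the correlation between the two effect vectors still
exceeds 0.999). The sampler itself is verified against an exact
grid-integrated posterior on a small system (agreement to ~1e-4, frozen as
a unit test), so this gap is a property of the Bayesian average, not
sampler error.

**Bayesian LASSO.** Park–Casella hierarchy:
`β_j ~ N(0, σ²_e τ²_j)`, `τ²_j ~ Exp(λ²/2)` (double-exponential marginal),
`λ² ~ Gamma(1, δ)`. The hyperprior is anchored to a heritability: the prior
effect variance is `2σ²_e/λ²`, so `λ²₀ = 2(1 − h²)/h² · Σⱼ Var(xⱼ)` matches
the ridge partition at `h² = 0.37` and `δ = 1/λ²₀` centers the hyperprior
there. The marker-specific τ²_j give differential shrinkage: null markers
are shrunk harder than under BRR while large effects escape.

**GBLUP.** The animal-model equations on a marker kinship spanning training
and target lines: `ĝ = K[·,t](K[t,t] + δI)⁻¹(y − μ̂)` with
`δ = σ²_e/σ²_g` from spectral REML on the training block (eigendecompose
once, profile the REML likelihood over log δ). With `K = XX'/c` this is
algebraically identical to ridge with `λ = cδ` — the dual identity the test
suite checks to 1e-8. Highly related panels can make `K[t,t] + δI`
numerically singular (duplicated lines, δ → 0); the default adds a 1e-6
jitter with a warning, `strict = TRUE` errors instead, reproducing the
failure mode kinship-based BLUP exhibits on excessively related material.

**RKHS.** Kernel ridge with the Gaussian kernel `exp(−d²/θ)` on squared
Euclidean marker distances. The bandwidth defaults to the median pairwise
squared distance (median heuristic) and the regularization to the spectral
REML variance ratio on the training kernel, so the method is tuning-free by
default. This is one reasonable member of the kernel-regression family, not
a replication of any particular implementation.

**Random Forest** wraps `randomForest` with the standard regression
defaults (500 trees, `mtry = ⌊p/3⌋`), seeded for reproducibility.

## Evaluation

Accuracy is the Pearson correlation between GEBVs and observed phenotypes;
constant vectors make it undefined and are recorded as `NA` (with a count)
rather than erroring out of a resampling loop. Three schemes, all refitting
per iteration with per-iteration seed substreams derived from a master
seed: **single** (80/20 random partitions of one population, 200 iterations
by default), **composite** (pool populations, then resample the pool), and
**cross** (fit on a random 80% of the training population(s), evaluate on a
random 20% of the held-out population). Training size is
`round(fraction · n)`; e.g. 341 lines split 273/68.

The shared-QTL experiment draws an architecture on the common polymorphic
markers, builds fraction-`f` subsets for the two populations, simulates
both traits, trains on the full first population and scores the full
second, over a grid of `f` (default 0.1–1.0 by 0.1) and heritabilities
(default 0.3 and 0.6), with 50 replicates per cell (the replicate count is
a package choice; each cell's Monte-Carlo standard error is reported).
For the closed-form ridge the training design is constant across
replicates, so the linear map from training phenotypes to validation
predictions is precomputed once per heritability — numerically identical to
refitting, and what makes a 1,000-fit grid take seconds.

Two behaviours of this experiment deserve emphasis. First, mean accuracy
rises monotonically with the shared fraction and is higher at higher
heritability — the qualitative result. Second, accuracy at small `f` is
*small but positive in expectation*: the experiment's construction makes
mean accuracy scale approximately linearly as `f` times the full-sharing
accuracy (at `f = 0.1` with full-sharing r ≈ 0.3–0.45, that is ≈0.03–0.05).
"Null at 10% sharing" is therefore a statement about practical
indistinguishability from zero at the precision of a plotted curve, not a
true zero: with 50 replicates the standard error of the cell mean
(~0.01–0.02) can resolve the positive floor, and the corresponding strict
two-standard-error check is expected to fail at the higher heritability.
The floor comes from the expected single shared QTL, not from population
relatedness — it persists when the two populations are bred from disjoint
founder panels.

## Method concordance

On simulated 100-QTL additive traits the four regression-type methods
(ridge/BRR, LASSO, GBLUP, RKHS) produce closely similar cross-validation
accuracies, but Random Forest's position varies with the particular
architecture draw — purely additive, many-small-effect traits are the least
favourable case for trees. The concordance experiment therefore averages
each method's mean accuracy over five independent architecture draws before
comparing: the target is the methods' expected accuracies, and conditioning
on a single draw would test the draw as much as the methods. Problem size:
one ~350-line population, 600 markers, eight 80/20 rounds per method per
trait, scaled-down Gibbs chains.

## Kinship and LD

Kinship is the IBS simple-matching proportion
`K = (XX' + (1−X)(1−X)')/m` — symmetric, positive semi-definite, unit
diagonal on complete binary data — followed by mean-diagonal normalization
(idempotent; division by the average self-kinship, the same normalization
applied to estimators whose diagonal exceeds 1). Note the *absolute* scale:
simple matching counts shared fixed markers, so unrelated inbred lines on a
U-shaped frequency spectrum already match at most markers and coancestries
sit high (≈0.8 rather than the 0.3–0.4 of expectation-corrected
estimators). The structure, not the level, is the meaningful output:
within-family exceeds between-family kinship, and within-population means
slightly exceed between-population means for populations bred from
overlapping panels. Values are reported as computed, never clipped.

LD between two markers is the squared Pearson correlation of their 0/1
columns — for fully inbred lines the genotype column *is* the haplotype, so
this equals haplotype r². Monomorphic markers make r² undefined and error;
`ld_pairs()` restricts to pairs on a shared chromosome when a map is
supplied and reports map distances.

## Configuration and reproducibility

`load_config()` resolves a YAML file against a strict schema (unknown keys
are errors, preventing silently ignored typos) with defaults matching the
package's standard conditions: full-length Gibbs chains, 80%/200-iteration
CV, 100 QTLs, fractions 0.1–1.0, heritabilities {0.3, 0.6}, a DH+RIL
two-population simulation. `run_pipeline()` executes the requested stages
and writes a manifest (resolved configuration, seeds, file checksums, stage
timings, package version) sufficient to reproduce any deterministic output.
Every stochastic function takes an explicit seed; resampling loops derive
per-iteration substreams so any single iteration is reproducible in
isolation.

## Known limitations

* The simulator models neither selection, drift across cycles, epistasis
  nor genotype-by-environment interaction; real cross-population accuracy
  is further degraded by G×E and LD-phase differences that the generator's
  shared-founder design only partially creates. Passing tests demonstrate
  internal consistency of the methods under this idealized model, not
  field-data performance.
* Genetic maps are inputs (or simulated); map construction from marker data
  is out of scope, as are heterozygous/outbred genotype calls, VCF input
  and physical coordinates.
* The RKHS implementation is a single-kernel Gaussian ridge; multi-kernel
  averaging and support-vector variants are not provided.
* The phenotype module implements only the sub-block control adjustment;
  no spatial row/column field models.
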