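---
title: "Models and methods behind metaboqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaboqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboqtl)
```

This vignette explains the statistical models the package implements, the
choices made where the design was genuinely open, and what the synthetic
cohorts do and do not emulate. It is the reference for every default the
code ships with.

## Phenotype preprocessing

Targeted metabolomics panels quantify 150–190 metabolites in µM across
analytical plates, each plate carrying aliquots of a common plasma pool as
in-house quality control. Four cleaning rules run in a fixed order:

1. **Pool detection.** A metabolite that is entirely missing or entirely
   zero among the pool measurements of at least one plate was not reliably
   measured there and is removed.
2. **Sample outliers.** A sample whose concentration lies outside
   median ± 1.5·IQR for strictly more than 30% of metabolites is removed.
   The fraction is strict (`>`), so "exactly 30%" survives; when the IQR is
   zero a value counts as deviant only if it differs from the median —
   otherwise constant metabolites would flag every sample.
3. **Missingness.** After metabolite filtering, samples with any remaining
   missing value are removed, leaving a complete matrix.
4. **Inter-plate CV.** The CV of a metabolite is sd/mean of its per-plate
   pool means; metabolites with CV ≥ 30% are removed (boundary inclusive).
   Removing *unstable* metabolites is the universal QC direction; the
   threshold and direction are arguments of `filter_metabolites_cv()`. A
   zero pool mean makes the CV undefined and removes the metabolite
   explicitly.

Zeros that survive (below the limit of detection) are imputed from
Uniform(0, minimum non-zero concentration of that metabolite), under a
caller-supplied seed. The uniform draw deliberately adds no distributional
assumption beyond the censoring bound.

**Box-Cox within a covariate regression.** Each trait y (a concentration or
a ratio) is transformed by y(λ) = (y^λ − 1)/λ (log y at λ = 0), with λ
maximizing the profile log-likelihood — including the Jacobian term
(λ − 1)·Σ log y — of the regression on intercept, sex, carcass weight (kg)
and collection-date dummies (J levels give J − 1 columns). The grid is 3001
points on [−3, 3] (spacing 0.002), λ = 0 included as an ordinary grid
point. The 95% interval keeps grid values within qchisq(0.95, 1)/2 = 1.92
log-likelihood units of the maximum; the cutoff is the standard
profile-likelihood interval, chosen here because nothing else was
specified. Identification degrades as the coefficient of variation of y
shrinks — a power transform of data with tiny relative spread is nearly
affine — which the tests respect by simulating traits with adequate spread.

Residuals e = y(λ) − ŷ from ordinary least squares are the traits used
everywhere downstream. For network estimation all metabolites share one λ:
the grid value contained in the most per-trait 95% intervals, ties broken
toward the median of the per-trait estimates, so that a single monotone
transform underlies the joint correlation structure. Ratios are formed on
the raw (imputed) concentration scale as a/b over all pairs in input-column
order, then normalized like any other trait; after Box-Cox the p-gain is
insensitive to which member is the numerator (the effect flips sign, the
P-value is unchanged up to the transform's asymmetry, which is small and
not corrected for).

## Kinship and heritability

The pedigree relationship matrix A uses the tabular method
(A_ii = 1 + F_i, A_ij = average of i's relationships to j's parents), with
ancestors beyond `max_generations = 4` treated as founders, matching
heritability estimation from four generations of records. The genomic
matrix is the centered form K = WcWcᵀ/p over p SNPs (mean-imputed
missing dosages, centering per SNP); this is the convention of the
mixed-model software the analysis chain mirrors, and the one the PVE
formula is calibrated to. Note K's average diagonal is the mean per-SNP
dosage variance, not 1; heritability is a variance *ratio* and is
insensitive to that scale as long as simulation and fitting share the K.

REML for y = μ + g + e profiles σ²_g out of the restricted likelihood and
optimizes the ratio δ = σ²_e/σ²_g on log δ ∈ [−10, 10] (41-point pre-scan,
then Brent). h² = 1/(1 + δ); its standard error comes from the numerical
curvature of the profile restricted likelihood in h². Optima at the search
boundary are flagged `"boundary"` (h² reported as 0 at the lower end —
negative genetic variance is never reported), flat likelihoods (e.g. K = I,
where h² is unidentifiable) as `"flat"`. The eigen-form likelihood is
verified in the tests against a dense-matrix evaluation at random variance
points (agreement to 1e−8) and the full optimum against a 2-D Nelder–Mead
on the dense likelihood.

Identification of h² depends on relatedness spread: full-sib-only designs
at a few hundred animals estimate h² with a standard deviation around
0.12–0.15 per trait, while phenotyping a full four-generation cohort
tightens the null distribution enough that pure-noise traits stay below
h² = 0.1 in ≥ 90% of replicates. The tests use both designs accordingly.

## Mixed-model association

Per SNP the model is y = Wα + xβ + g + e with W an intercept (covariates
having been residualized out beforehand), x the 0/1/2 minor-allele dosage,
g ~ N(0, σ²_g K). Two modes:

* `exact`: δ is re-optimized under each SNP's model; estimates equal dense
  GLS at the fitted variances to 1e−8 (tested).
* `null_vc`: δ fixed at the no-SNP fit, a fully vectorized weighted
  regression — the standard large-scan approximation. The two agree on P
  within a factor 1.5 for ≈99% of SNPs; SNPs that by chance absorb
  polygenic variance can shift their per-SNP variance ratio and move P
  somewhat further, which is a genuine property of the approximation, not
  an implementation gap.

The Wald test uses the normal approximation for β̂/se (no small-sample t
correction), matching the convention of the reference scan software; at the
cohort sizes simulated here the induced type-I inflation is within the
tested [0.045, 0.055] band at nominal 0.05.

Significance uses an LD-based Bonferroni denominator: the number of SNPs
surviving windowed greedy pruning at r² < 0.25 (window 100 SNPs, step 5;
composite LD on mean-imputed centered dosages). Of each dependent pair the
lower-MAF SNP is dropped; MAF ties drop the larger position. These
tie-breaks are fixed and documented because survivor counts depend on them.
For ratios the p-gain min(p_a, p_b)/p_ratio must reach 10 × (number of
tested ratios), and — by default, configurable — the ratio's own P must
also pass the single-trait threshold; the conjunction reflects pairing
p-gain with GWAS significance when declaring ratio mQTL. Meta-analysis uses
the sample-size-weighted Z-score: Z_i = sign(β_i)Φ⁻¹(1 − p_i/2), weights
√N_i; a shared-SNP Bonferroni threshold accompanies the LD-based one.

mQTL regions: significant SNPs of one analysis context cluster while
consecutive gaps are < 1 Mb (a separation of at least 1 Mb splits);
clusters from different contexts merge when their spans approach within
< 0.5 Mb (exactly 0.5 Mb stays separate). The lead is the most significant
member — smallest P, or largest p-gain among ratio-only members — and gene
annotation attaches genes overlapping the closed ±500 kb window around the
lead.

## Gaussian graphical models

Full-order partial correlations come from inverting the Pearson correlation
matrix: PCC_ij = −Ω_ij/√(Ω_ii·Ω_jj). This equals the correlation of the
two variables' residuals after regression on all others (the tests assert
the identity to 1e−8). Edges require PCC strictly above 0.3, signed — the
published convention this package follows lists positive edges only — with
an absolute-value mode available. Ill-conditioned correlation matrices
(condition number > 1e10, e.g. more metabolites than samples) receive a
1e−4 ridge and a flag rather than failing; the intended regime is n ≫ m.
Genotype correction regresses each metabolite on the mQTL lead SNPs coded
as genotype-class indicators (two dummies per SNP, not dosages, so
non-additive effects are removed too) before re-estimating both
correlation matrices.

## Kynurenine-pathway kinetics

All enzymes are modelled in their first-order regime ([S] ≪ K_M), so each
reaction rate is k·[S] with k = k_cat/K_M folded with the enzyme level.
Tryptophan is a clamped boundary condition — steady states are expressed as
functions of the Trp level, and the basal versus supplemented diets are
simply two Trp values. The terminal metabolites (KA, AA, XA, QUIN) receive
a first-order clearance (one shared constant by default) so finite steady
states exist. Steady states follow from mass balance on the topology
Trp→KYN→{KA, AA, HK}, HK→{XA, HAA}, HAA→QUIN:

* KYNss = k_TDO/IDO·Trp/(k_KAT1 + k_KYNU1 + k_KMO)
* HKss = k_KMO·KYNss/(k_KAT2 + k_KYNU2)
* HAAss = k_KYNU2·HKss/k_3HAO, terminal species production/clearance.

The HK denominator is the *total* consumption k_KAT2 + k_KYNU2; a
published single-branch shorthand (k_KYNU2 alone) is inconsistent with the
full expression, and the mass-balance form is verified against stiff-safe
numerical integration (lsoda, doubling horizons, max |d/dt| < 1e−10;
relative agreement 1e−6 over 100 random parameter sets). Only ratios of
rate constants enter concentration ratios, so the unknown absolute enzyme
levels are immaterial for every contrast computed. With the human-derived
constants k_KMO = 22, k_KYNU1 = 0.46, k_KAT1 = 2.08 (s⁻¹ mM⁻¹ scale),
doubling k_KMO changes HKss by ≈5% but KYNss by ≈47% — the quantitative
form of "equal HK requires k_KMO ≫ k_KYNU1 + k_KAT1". Constants not
reported (k_TDO/IDO, k_KAT2, k_KYNU2, k_3HAO, clearance) default to 1;
they scale levels but cancel from the genotype contrasts.

Group comparisons use the Wilcoxon rank-sum test: the exact two-sided
distribution when the smaller group has ≤ 12 observations and no ties
(8 vs 8 completely separated gives P = 2/C(16,8)), otherwise the normal
approximation with tie correction; fully tied data returns P = 1 with a
flag.

## The synthetic cohorts

`sim_config()` defaults emulate the structure of a performance-tested pig
population: ~250 founders growing over three offspring generations (four
generations of records) to a final phenotyped generation of roughly 800;
full-sib litters of three; 18 autosomes; founder MAF uniform on
[0.05, 0.5] (the post-QC MAF filter); first-order-Markov haplotypes with
adjacent latent correlation 0.7, a medium-density-chip level of LD;
Mendelian gene dropping with on average one crossover per chromosome per
meiosis; a 169-metabolite panel with 26 collection dates, 20 plates
(one pool aliquot each), 2% below-LOD zeros and 1% whole-sample technical
outliers (a ×5 shift in 40% of metabolites, so the IQR rule has true
positives). Zero-masking censors the *smallest* values per metabolite,
mimicking instrument censoring rather than random dropout. Heritabilities
are drawn from a truncated normal centred at 0.22 (sd 0.15) — the
magnitude reported for such panels — per-trait λ from {0, 0.25, 0.5, 1},
covariates explain 20% of latent variance, and residuals across
metabolites follow a chain-structured precision matrix (adjacent partial
correlation 0.3) as a minimal network-structured model. Planted mQTL
effects are sized as β = √(PVE/2pq) on the latent scale. One global seed
fans out deterministically to the stages, so any stage reproduces
independently of the others' draw counts.

What the generator does **not** emulate: realistic recombination maps,
breed-specific allele-frequency spectra, selection, assay-specific error
structure, metabolite-class-specific correlation, or missing genotype
calls. Passing recovery tests on these cohorts therefore demonstrates
correctness of the estimators under the stated generative model, not
robustness to everything real data can do.

## Problem sizes used by the tests and acceptance script

Chosen to exercise each property at the smallest scale where it is
statistically crisp: ratio counts at the real panel sizes (169, 164);
dense-GLS cross-check at n = 40 × 200 SNPs; type-I error on a ~300-sib
cohort × 2000 SNPs × 20 null traits (40,000 tests); heritability recovery
on a ~500-animal sib cohort × 5000 SNPs, 20 replicates per h² ∈
{0.2, 0.5, 0.8}; p-gain power at n = 300, 10 metabolites (45 ratios,
critical level 450), 20 replicates with 27,000 null p-gains; GGM chain
recovery at 20 nodes, n = 800, 20 replicates; kynurenine steady states over
100 random parameter sets. The full suite runs in well under a minute of
compute-heavy work.

## Known limitations

* The exact-mode scan loops SNPs in R; it is meant for candidate regions
  and oracle checks, with `null_vc` the volume mode.
* Ratios are Box-Cox-normalized as raw ratios; residualized log-ratios are
  an alternative the interface does not currently expose.
* X-chromosome models, dominance, multi-component GREML and regularized
  GGMs (graphical lasso) are out of scope.
* `read_genotype_matrix()` reads dosage text (CSV, PLINK .raw); binary
  PLINK and VCF are not parsed.
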