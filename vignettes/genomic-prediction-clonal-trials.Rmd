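---
title: "Genomic prediction in clonally replicated progeny trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in clonally replicated progeny trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalGBLUP)
```

## The evaluation problem

A set of parents is crossed into full-sib families; the progeny are
vegetatively propagated, and each cloned genotype is planted as many ramets
across several test sites. The breeder wants each clone's additive genetic
merit (breeding value) for a growth trait, with a defensible standard error,
and — crucially for forward selection — a way to rank full sibs against each
other. Pedigree-based evaluation cannot do that last part: the expected
relationship between any two full sibs is exactly 0.5, so without their own
phenotypes all sibs in a family collapse to the same mid-parent prediction.
Dense SNP genotypes resolve the *realized* fraction of genome shared, which
varies around 0.5 through Mendelian sampling at meiosis, and a relationship
matrix built from markers lets the mixed model exploit that variation.

## Model

All predictions come from one clone-level linear mixed model on tree-level
records:

$$y = Xb + Zu + e, \qquad
\operatorname{Var}(u) = K\sigma^2_a, \quad
\operatorname{Var}(e) = I\sigma^2_e ,$$

where $y$ holds one record per ramet, $X$ carries site effects (fixed;
reference-level parameterization, first site absorbed into the intercept),
$Z$ maps ramets to clones, and $K$ is whichever relationship matrix the
analysis uses:

* `amatrix()` — pedigree numerator matrix **A** by the tabular method
  ($A_{jj} = 1 + \tfrac12 A_{sd}$, $A_{jk} = \tfrac12(A_{ks} + A_{kd})$,
  unknown parents contributing zero);
* `gmatrix_frequency()` — $G = ZZ^\top / (2\sum_i p_i(1-p_i))$ with dosages
  centered at twice the allele frequency. Centering is essential: it is what
  makes $E(G) \approx A$, and it also makes a sample-frequency $G$ exactly
  singular (see *Numerical choices*). Frequencies default to the genotyped
  sample; base-population frequencies can be supplied and are preferable
  when known;
* `gmatrix_regression()` — regresses the similarity matrix $MM^\top$
  ($M$ = dosage − 1) on **A** over all $n^2$ cell pairs, diagonal included,
  and rescales: $G = (MM^\top - \hat g_0 11^\top)/\hat g_1$. The intercept
  absorbs mean homozygosity, so no allele frequencies are needed. $M$'s
  coding is not uniquely determined by the method's description; dosage − 1
  is the convention adopted here, and any affine recoding only moves the
  intercept.

Identity $K$ gives phenotype-only predictions (EBV1), **A** gives ABLUP
(EBV2 when validation phenotypes are withheld), and either **G** gives GBLUP
(GEBVa/GEBVb). Genomic inbreeding is $G_{jj}-1$;
`normalize_relationships()` rescales to correlation form when a unit
diagonal is wanted for compatibility with **A**.

### Solvers

`solve_blup()`/`gblup_mme()` solve Henderson's mixed-model equations, whose
coefficient matrix is only (sites + clones) square regardless of tree count;
prediction-error variances (PEV) are read off the random-effect block of the
inverse. `gblup_selection_index()` implements the index form
$\hat u = G[G + R\lambda]^{-1}(\bar y_{\text{adj}})$ on fixed-effect-adjusted
clone means with $R = \mathrm{diag}(1/n_i)$ ($n_i$ = ramets). Because the
fixed effects are taken from the same generalized-least-squares fit and
clone means are sufficient statistics under an identity residual, the two
routes are algebraically identical; the test suite enforces agreement to
1e-6 against a brute-force joint-inverse oracle, and the MME route with
$K = A$ reproduces ABLUP to 1e-8. The index path's PEV treats fixed effects
as known ($\sigma^2_a\,\mathrm{diag}(G - G[G+R\lambda]^{-1}G)$), so its SEs
are very slightly smaller than the MME SEs; the predictions themselves are
identical.

### Accuracy

Each prediction's accuracy is the reliability-based
$r = \sqrt{1 - SE^2 / ((1+f)\sigma^2_a)}$ with $f$ from the diagonal of the
relationship matrix used in that fit. The relation is sometimes printed
without the radical; the square-root form is the one with the correct units
(an accuracy, i.e. a correlation) and is used throughout. When numerical
overshoot makes the argument negative the accuracy is reported as 0 with a
warning rather than NaN.

## REML

Only two variance components exist, so the restricted likelihood is profiled
down to the single ratio $\lambda = \sigma^2_e/\sigma^2_a$: at any $\lambda$
the residual variance has the closed form
$\hat\sigma^2_e = y'Py/(n-p)$ available from the mixed-model equations, and
the profiled criterion
$(n-p)(\log\hat\sigma^2_e + 1) - q\log\lambda + \log|K| + \log|M(\lambda)|$
is minimized by Brent search on $\log\lambda$ over $[10^{-6}, 10^6]$ with
tolerance 1e-9. This is deterministic, cannot leave the positive cone, and
needs no derivatives; it was preferred over EM/average-information iteration
because with a single ratio the one-dimensional search is both simpler and
more robust. Agreement is verified in tests against `lme4` (identity $K$)
and against direct two-parameter optimization of the dense restricted
likelihood ($K = A$), and against closed-form ANOVA estimators in the
balanced one-way case. Degenerate data (zero residual or zero additive
variance) are clamped at a 1e-10 floor with a warning; an estimate at the
search-interval edge also warns.

## The simulator

`simulate_trial()` generates data under exactly the model the analysis fits,
with defaults matching the motivating study design:

| parameter | default | meaning |
|---|---|---|
| `n_parents` / `n_families` | 13 / 9 | founders crossed into full-sib families, several sharing a parent |
| `family_sizes` | 3…37, total 165 | cloned progeny per family |
| `n_markers` | 3461 | unlinked biallelic SNPs |
| `maf_range` | 0.05–0.5 | founder minor-allele frequencies (uniform) |
| `n_sites` | 16 | fixed site effects, drawn once, SD `site_sd = 1` |
| `ramets_range` | 16–50 | ramets per clone, spread evenly over sites (~5500 trees) |
| `sigma2_a`, `h2` | 1, 0.25 | additive variance; individual-tree heritability |
| `missing_rate` | 0.012 | genotype calls masked at random |
| `n_monomorphic`, `n_high_missing` | 1700, 218 | raw-mode planted loci (5379 raw markers total) |

Founder genotypes are Binomial(2, $p_i$); each offspring receives one allele
per parent per locus by fair Mendelian sampling (gene dropping). Marker
effects are i.i.d. normal with variance $\sigma^2_a/(2\sum p_i(1-p_i))$, so
true breeding values $\sum_i (z_{ij} - 2p_i) a_i$ have additive variance
$\sigma^2_a$ in the founder population; the residual variance is
$\sigma^2_a(1-h^2)/h^2$ — the default pair gives $\sigma^2_e = 3$,
a growth trait of low individual-tree heritability. `h2` is deliberately the
*single-ramet* heritability: with 16–50 ramets the clone-mean repeatability
is then ~0.9, which is why clonal trials of low-heritability traits work.

What the simulator does **not** emulate: linkage (loci are independent, so
all marker covariance comes from pedigree structure — appropriate for
populations where background LD is low and relationship capture, not
population LD, drives accuracy), incomplete-block field structure within
sites (site is the only nuisance effect; real trials add block and spatial
variation), genotype-by-environment interaction, selection, genotyping
error, and non-additive gene action. Consequently tests passing on
simulated data demonstrate *internal correctness* of the estimators — they
do not promise the same accuracy levels on field data, where these omitted
noise sources push prediction accuracies and SE comparisons noticeably
lower than the clean simulated values. Patterns that are robust to this
(ordering of training-fraction scenarios, near-equivalence of the two G
constructions and of the four imputation methods, within-family separation
of sibs by GBLUP but not ABLUP) are the meaningful comparisons.

The uniform allocation of ramets over sites, and uniform per-family
validation sampling, are simplifications chosen once; the realized
distributions in any particular trial differ without affecting the
estimators under test.

## Marker QC and imputation

Filtering drops monomorphic loci first (observed allele frequency 0 or 1 —
with 13 founders a low-frequency allele is often simply absent from the
cross, so a substantial monomorphic fraction is expected, not anomalous),
then loci with missing fraction strictly above 15%, then recodes survivors
to minor-allele dosage. Ties at frequency 0.5 keep the input coding. The
order matters for the reported counts (a monomorphic high-missing locus
counts as monomorphic) and matches the filtering sequence of the motivating
study; the operation is idempotent.

Four imputation methods fill the ~1.2% missing calls; all leave observed
cells untouched:

1. **stochastic frequency** — draw from the locus's observed genotype-class
   distribution; preserves genotype frequencies in expectation;
2. **major homozygote** — set to 0, the major homozygote under minor-allele
   coding;
3. **gene content, scaled** and 4. **truncated** — per locus, observed gene
   content is the response of a mixed model with overall mean fixed and an
   individual effect with covariance proportional to **A** (relatives share
   alleles IBD, so genotypes covary like breeding values). Gene content is
   almost fully "heritable", so the variance ratio uses a gene-content
   heritability of 0.99. Solutions are continuous predictions for every
   individual; the *truncated* variant clips them to [0, 2]; the *scaled*
   variant standardizes the per-locus solution vector and maps it back as
   $1 + (x - \bar x)/s_x \cdot s_{\text{obs}}$. The "adjust by mean and SE"
   step is ambiguous as usually stated; standardizing the full solution
   vector was chosen because per-locus missing counts (~2 of 165) make a
   missing-cells-only standard deviation degenerate. Both variants are
   provided precisely because the choice is a judgment call.

`imputation_accuracy_comparison()` runs the full GBLUP fit per method and
reports the mean accuracy, the study's own criterion for declaring the
methods equivalent — which they are here as well (differences in the third
decimal).

## Numerical choices

* **Singular G.** A sample-frequency G satisfies $G\mathbf{1} = 0$ exactly,
  and the regression G can be indefinite when markers are few relative to
  clones. `make_invertible()` repairs in escalating order: accept if the
  smallest eigenvalue exceeds 1e-8 of the largest; else blend
  $0.99\,G + 0.01\,A$; else bend eigenvalues up to a floor of 1e-4 of the
  largest (with a message). REML and the BLUP solvers additionally refuse a
  numerically singular $K$ (Cholesky pivot check) instead of silently
  amplifying error through $K^{-1}$.
* **Cross-validation partitions.** Within-family sampling rounds the
  validation count half-up per family and keeps at least one clone on each
  side of the split whenever the family has two or more members — families
  as small as 3 must contribute to both sets in the 50% scenario. Replicate
  $r$ uses seed `base_seed + r`, so schemes are reproducible and replicates
  independent.
* **Variance components in cross-validation** are re-estimated on each
  training set by default (the honest-validation choice; nothing from the
  withheld clones leaks into the components). `reestimate_vc = FALSE` with
  fixed components is available for sensitivity analysis.
* **Reference standard.** EBV1 (identity $K$, all phenotypes, no pedigree)
  is computed once on the full data and used as the comparison standard for
  all replicates; validation-set correlations with EBV2 are reported
  alongside. Mean prediction SEs are averaged over validation clones;
  `imputation_accuracy_comparison()` averages accuracies over all clones
  (full-data fits, no validation split).
* **Degenerate inputs.** Empty phenotype files, cyclic or duplicated
  pedigrees, out-of-range genotype cells, monomorphic loci entering G, a
  non-positive regression slope, and partitions that empty either side of a
  split are all hard errors with specific messages; boundary REML estimates
  and accuracy overshoot warn and clamp.

## Problem sizes in the test suite

Unit tests run on a reduced design (4–6 parents, ~36 clones, a few hundred
markers, 4–6 ramets) where dense brute-force oracles are cheap; study-scale
checks (165 clones, 16 sites) and the replicated parameter-recovery and
Mendelian-sampling experiments (20 simulation replicates each) run at
moderated marker counts (1000–1500) chosen so the whole suite completes in
well under a minute while keeping Monte-Carlo error far below the asserted
tolerances. The reproduction script `scripts/acceptance.R` runs the full
default design (5379 raw markers, ~5500 trees, six cross-validation
replicates per scenario).

## Known limitations

* Single trait, additive effects only: no dominance or epistatic
  relationship matrices, no multi-trait or random-regression models, no
  genotype-by-environment modeling.
* No Bayesian marker-effect models; GBLUP's implicit equal-variance prior
  is the only marker model.
* No haplotype- or LD-based imputation; the gene-content method uses
  relationships only.
* Pedigrees are assumed correct; no parentage verification from markers.
* The regression-method G inherits whatever errors the pedigree has, since
  **A** is its regressor.
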