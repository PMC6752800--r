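---
title: "Methods: genotype-phenotype correlation for Marfan-spectrum panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-phenotype correlation for Marfan-spectrum panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genophen)
library(dplyr)
```

## The analysis problem

Marfan syndrome and its overlapping disorders (Loeys-Dietz, Ehlers-Danlos,
familial thoracic aortic aneurysm) are diagnosed from a constellation of
binary clinical signs, while genetic testing of an 11-gene panel (FBN1,
TGFBR1/2, the fibrillar collagens, ACTA2, MYH11, NOTCH1) returns a mixture
of common polymorphisms, low-frequency variants, rare variants of uncertain
significance (VUS) and clearly pathogenic alleles. Classic
genotype-phenotype studies use only FBN1 pathogenic variants and explain
little phenotypic variance. This package implements an inclusive pipeline
that (a) predicts pathogenic-variant carriage from the phenotype alone and
(b) models each clinical sign jointly from common-variant polygenic scores
and rare-variant burdens, quantifying how much explained variance the
inclusive model adds over the FBN1-only model.

The pipeline runs from per-sample VCFs to the final model comparison:

1. **Genotype matrix.** Per-sample VCFs (which only record non-reference
   calls) are merged over the union of observed variants; a site absent
   from a sample's VCF is inferred homozygous reference *unless* it falls
   in that sample's sub-10X coverage mask, in which case it is missing.
   Every variant is keyed `chrom-pos-ref-alt`.
2. **Quality control.** Variants are dropped when the first quartile of
   their carrier Phred qualities falls below 30 (`Q = -10 log10 P`, so
   Q 30 is an error probability of 0.001), when their call rate falls
   below 98%, or when they fail an exact Hardy-Weinberg test
   (alpha 1e-3); samples with more than 2% missing calls are then dropped.
3. **Classification.** Variants are classed common (any MAF > 0.05,
   internally or in a reference database), rare (all available MAFs
   < 0.01, or unknown everywhere), or low-frequency otherwise; clinical
   classes are benign / pathogenic (pooling likely-pathogenic) / VUS.
4. **Phenotype factorization and carrier prediction** (below).
5. **Common variants:** covariate-adjusted logistic scans with max-T
   permutation correction and sign-specific polygenic risk scores (PRS).
6. **Rare variants:** negative-binomial burden regression and gene-level
   SKAT-O per clinical-class stratum.
7. **Joint path models:** explained variance of an FBN1-only model versus
   the inclusive rare-plus-common model, per sign.

## Factor analysis of mixed data and the carrier model

`famd_fit()` implements FAMD as a principal-axes SVD: quantitative columns
are standardized; each level of a categorical variable becomes an
indicator divided by the square root of its proportion and then centred.
Binary clinical signs are deliberately treated as two-level categorical
variables (the MCA side of FAMD), not numeric 0/1; age enters as an active
quantitative variable by default; the clinical-suspicion label is kept for
display only. Eigenvalue *k* is the squared singular value divided by
`n - 1`; this convention is recorded in the model and makes FAMD on an
all-quantitative table agree with correlation-matrix PCA to machine
precision, which is how the factorization is tested.

Because factor axes are sign-indeterminate, `orient_dimension()` anchors
Dim 1 so that "ectopia lentis present" — the most Marfan-specific sign —
has a negative coordinate: more Marfan-like subjects sit on the left.
`carrier_logistic()` then regresses carriage of at least one rare
pathogenic variant in FBN1/TGFBR1/TGFBR2 on the Dim 1 score and reports
the odds ratio per unit *decrease* of Dim 1 with a Wald 95% CI. Complete
separation (easy in small cohorts) is detected and handled by a
Firth-type penalized fit, prominently flagged.

## Common variants, max-T, and the PRS

Each common variant is tested per sign by additive-dosage logistic
regression adjusted for age and the per-subject counts of benign,
pathogenic and VUS rare variants (counted panel-wide). Family-wise error
within each sign's scan is controlled by max-T permutation: outcome
labels are permuted with covariates staying attached to subjects, every
test is recomputed, and the maximum absolute statistic per permutation
forms the reference distribution, with the `(1 + r) / (B + 1)` estimator.
The permuted (and observed) statistics are Rao score tests under the
covariate-only null: refitting one null model per permutation and scoring
all variants vectorises the procedure, making the prescribed
1000-permutation scans and the 500-replicate family-wise-error
calibrations tractable on one CPU; the reported per-variant
`p_unadjusted` remains the Wald p of the ML fit. By construction the
adjusted `p_maxT` can never fall below the pointwise permutation p.

Variants with unadjusted p below 0.05 are selected per sign and weighted
by `w_j = beta_j / SE(beta_j)`, so more precisely estimated effects weigh
more; a subject's PRS is the weighted sum of effect-allele dosages
`PRS_i = sum_j w_j g_ji`, with missing dosages mean-imputed (a
drop-variant mode is available) and imputations counted.

## Rare variants: burden and SKAT-O

The overall burden analysis regresses the count of positive clinical
manifestations on the per-subject number of rare plus low-frequency
variant sites carried (and, stratified, on per-clinical-class counts)
by NB2 negative-binomial regression with a log link and age as covariate,
reporting rate ratios; when the dispersion sits at the Poisson boundary
the model falls back to Poisson with a warning.

Gene-level association uses SKAT-O. For a gene's variants with MAF at or
below 0.05, weighted by the Beta(1, 25) density of their MAF,
`Q_rho = (1 - rho) Q_SKAT + rho Q_burden` is computed over the grid
`rho = (0, 0.1^2, ..., 0.9^2, 1)` from the score residuals of the null
logistic model (sign ~ age + counts of the other clinical classes). Each
`Q_rho` is a quadratic form whose null distribution is a mixture of
one-degree chi-squares; tails are evaluated by Liu-type moment matching
(default) or Imhof numerical integration. The optimal p-value is that of
the minimum per-rho p, obtained by the one-dimensional integral over the
shared burden chi-square component, with a Bonferroni cap over the grid
as a guard. Single-variant genes collapse exactly to the score test. An
optional parametric bootstrap resamples outcomes from the fitted null and
reports an empirical `(1 + r) / (R + 1)` p. The scan runs one test per
gene x sign x clinical-class stratum, with the per-subject counts of the
other classes as covariates, and deliberately applies no multiple-testing
correction (a pre-planned exploratory scan with complementary outcomes);
empty cells are reported as NA with a reason.

## The joint model comparison

Each sign (numeric 0/1, linear-probability convention) is regressed by
least squares under two specifications: Model 1 uses age plus the FBN1
pathogenic and VUS rare counts — the classic FBN1-only study — and
Model 2 adds the per-gene rare counts of scan-significant gene/class
cells for that sign plus the sign's PRS. Model 2 always includes
Model 1's predictors, so by least-squares nesting its explained variance
(R-squared x 100) can only grow; the comparison reports per-sign deltas,
their mean over the 14 clinical signs, and a two-sided paired t-test. A
linear-probability estimator was chosen because it reproduces the
"percentage of explained variance" semantics directly; the binary
endogenous variables make a logistic pseudo-R2 an alternative, but not
the default. An operational Ghent-2010 positivity flag (aortic criterion
with ectopia lentis, or either with systemic score >= 7) can be added as
an extra endogenous row; it is excluded from the mean increase by
default, because on the bundled reference table the 14-row mean
reproduces the published summary (11.07%, paired p 1.6e-7) while the
15-row mean does not.

```{r reference}
tab <- sem_reference_table()
cmp <- compare_models(select(tab, sign, r2_pct = r2_model1),
                      select(tab, sign, r2_pct = r2_model2))
glance(cmp)
```

## The synthetic cohort generator

`generate_cohort()` makes the whole pipeline testable without patient
data. Its defaults are the study conditions the package is calibrated
around: 181 subjects; 1273 variants over the 11 panel genes allocated
proportionally to gene length and split 361/128/784 into
common/low-frequency/rare classes; age lognormal with median 39.64 and
IQR 28.66 years; baseline sign prevalences matching a real
Marfan-spectrum clinic cohort (wrist sign 62.4% down to reduced elbow
extension 7.2%). Key modelling choices:

- **Logistic liability.** Each sign is Bernoulli with logit equal to the
  baseline log-odds plus an age term, a shared latent severity factor,
  and the planted genetic effects — so planted coefficients are directly
  the log-odds ratios the downstream logistic analyses should recover.
- **Latent severity (sd 0.8).** A subject-level normal term shared by all
  signs induces the positive inter-sign correlation characteristic of a
  systemic connective-tissue disease; without it the first FAMD dimension
  has nothing systematic to summarize. It slightly shrinks extreme
  baseline prevalences toward one half, which the defaults accept.
- **Observed-site conditioning.** Genotypes are Binomial(2, MAF) under
  Hardy-Weinberg equilibrium, conditioned on at least one alternate
  allele in the cohort, because a panel's variant list only ever contains
  observed sites. True rare MAFs are drawn from (0.0005, 0.006) — massing
  near singleton frequencies, as in real panel data — so that the
  *observed* classification at n = 181 reproduces the 28/10/62 split.
- **Clinical classes.** Rare variants are benign/pathogenic/VUS with
  probabilities 0.802/0.042/0.156, derived from an overall
  87.8/2.6/9.6% architecture under the assumption that all pathogenic
  and VUS variants are rare; common and low-frequency variants are
  emitted benign. A third of pathogenic variants are labelled
  `likely-pathogenic` in the emitted table to exercise the merge rule.
- **Planted effects.** The default plan gives rare pathogenic FBN1
  alleles log-odds 1.0-1.5 on the cardinal signs and a protective
  common COL1A1 polymorphism (log-odds -1.37) on scoliosis. Targets may
  be genes, literal variant ids, or symbolic `"GENE:class:k"` references
  resolved in descending true-MAF order.
- **Coverage hiding.** A fraction (default 0.5%) of calls is hidden: the
  call is omitted from the sample's VCF and its locus written to the
  sample's sub-10X BED (0-based half-open), so the matrix builder must
  reproduce the truth exactly at unhidden calls — the round-trip test.

What the generator does *not* emulate: linkage disequilibrium between
panel variants (sites are independent; real panels show haplotype
structure), sequencing error in the genotype calls themselves,
relatedness, and referral ascertainment (a real Marfan clinic cohort is
strongly enriched for pathogenic carriers, so the synthetic Dim-1 carrier
odds ratio is much noisier at n = 181 than a clinic cohort's). Passing
tests therefore validate the statistical machinery and its calibration,
not effect sizes one would see in a referral population.

## Numerical choices and problem sizes

- HWE exact test: conditional on allele counts; same-parity heterozygote
  support; probabilities compared with a 1e-10 relative tie tolerance;
  monomorphic sites return p = 1 by convention. The test equals a
  normalized-multinomial enumeration oracle on every genotype triple up
  to n = 60.
- Frequency-class boundaries are closed at low-frequency: MAF exactly
  0.05 or 0.01 classifies low-frequency (the defining inequalities are
  strict on both sides).
- Quadratic-form tails: Liu moment matching is the default (adequate to
  ~0.015 absolute against Imhof integration in the moderate tail);
  Imhof is exact but slower and is the cross-check.
- max-T uses the add-one permutation estimator to avoid zero p-values;
  an exhaustive mode enumerates all distinct label arrangements for
  small cohorts and is tested against full enumeration.
- Degenerate inputs fail loudly: constant FAMD columns, single-class
  outcomes, empty class filters, all-sample QC removal, and PRS weights
  referencing absent variants are errors; empty scan cells and
  separation fallbacks are flagged results, not errors.
- Default problem sizes keep the full test suite and the acceptance
  script to a few minutes on one CPU: the family-wise-error calibration
  runs 500 null replicates of a 200 x 50 scan at 200 permutations, the
  SKAT-O permutation oracle uses 100,000 permutations at n = 30, and the
  end-to-end run uses the full 181 x 1273 default cohort with 1000
  max-T permutations.

## Known limitations

Indels are compared literally by position and allele strings (no
left-alignment normalization); the Phred filter uses record QUAL (per-
sample VCFs carry no per-genotype GQ here) and variants with no carrier
records pass it with a warning; permutation keeps covariates attached to
subjects (label permutation, not residual permutation), which is the
procedure's classic form but can be anticonservative under strong
covariate-outcome confounding; and the linear-probability R2 of the path
models is a convention, not a claim that a linear model generated the
binary signs.
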