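# genophen

Genotype-phenotype correlation analysis for Marfan-spectrum gene panels,
from per-sample VCFs to a joint rare-plus-common model of each clinical
sign.

Marfan syndrome and its overlapping disorders are diagnosed from binary
clinical signs (wrist sign, ectopia lentis, aortic ectasia, ...), while
panel sequencing of 11 connective-tissue genes returns common
polymorphisms, rare variants of uncertain significance and pathogenic
alleles. Studies that use only FBN1 pathogenic variants explain little
phenotypic variance. `genophen` implements an inclusive pipeline:

- **Genotype matrix** — merges per-sample VCFs over the union of observed
  variants (`chrom-pos-ref-alt` keys), inferring absent sites homozygous
  reference unless they fall in the sample's sub-10X coverage BED, then
  applies QC (first-quartile Phred `Q = -10·log10(P)` ≥ 30, call rate
  ≥ 98%, exact Hardy-Weinberg test, sample missingness ≤ 2%).
- **Variant classes** — common (MAF > 0.05), low-frequency, rare
  (MAF < 0.01 or unknown); benign / pathogenic (pooling
  likely-pathogenic) / VUS; Fisher comparison against gnomAD-style
  reference allele counts.
- **Phenotype factorization** — factor analysis of mixed data (FAMD) of
  the 14 binary signs plus age; Dim 1 oriented so more Marfan-like
  subjects are negative; logistic prediction of pathogenic-variant
  carriage reported as the OR per unit *decrease* of Dim 1.
- **Common variants** — per-sign additive logistic scans adjusted for age
  and rare-variant class counts, max-T permutation family-wise
  correction, and sign-specific polygenic risk scores
  `PRS_i = Σ_j w_j g_ji` with `w_j = β_j / SE(β_j)`.
- **Rare variants** — negative-binomial burden regression of the number
  of clinical manifestations, and gene-level SKAT-O
  (`Q_ρ = (1-ρ)·Q_SKAT + ρ·Q_burden`, Beta(1,25) weights, ρ grid
  0…1, optional parametric bootstrap) per clinical-class stratum.
- **Joint models** — per-sign explained variance (R²·100) of Model 1
  (age + FBN1 pathogenic/VUS counts) versus the nested Model 2
  (+ scan-significant gene counts + PRS), with the mean increase and a
  paired t-test.

A fully synthetic cohort generator (181 subjects, 1273 panel variants
split 28/10/62% common/low-frequency/rare, logistic sign liabilities with
planted effects) makes every stage testable without patient data.

## Worked example

```r
library(genophen)
library(dplyr)

co <- generate_cohort(cohort_spec(
  n_subjects = 120, n_common = 40, n_lowfreq = 15, n_rare = 150,
  clinical_class_probs = c(benign = 0.6, pathogenic = 0.15, VUS = 0.25),
  maf_ranges = list(common = c(0.05, 0.5), low_frequency = c(0.01, 0.05),
                    rare = c(0.003, 0.009)),
  seed = 42))

td <- tempfile(); dir.create(td)
emit_vcfs(co, file.path(td, "vcf"))
emit_coverage_beds(co, file.path(td, "bed"))
write_cohort_tables(co, td)

res <- run_panel_pipeline(
  file.path(td, "vcf"), file.path(td, "bed"),
  file.path(td, "phenotypes.tsv"), file.path(td, "classification.tsv"),
  out_dir = file.path(td, "out"), n_perm = 200, seed = 1)

res$matrix
#> <geno_matrix> 119 samples x 199 variants, 101 missing calls (0.43%)
res$famd
#> <famd> 119 subjects, 5 dimensions kept (of rank 15)
#>   eigenvalues: 2.836 (18.8%), 1.372 (9.1%), 1.349 (8.9%), ...
res$carrier
#> <carrier_fit> OR per unit decrease of Dim 1 = 1.248
#>   (95% CI 0.882-1.767), ml fit, n = 119 (11 carriers)
tidy(res$burden_overall)
#> # A tibble: 1 × 7
#>   term            rr conf_low conf_high     p log_rr     se
#> 1 n_rare_total  1.03    0.978      1.08 0.273 0.0277 0.0253
res$joint$comparison
#> <model_comparison> mean explained-variance increase 7.30% over
#>   14 signs (paired p = 0.000358)
```

One sample was dropped by QC (missingness), six variants had no visible
carriers, and the carrier model shows the conventional direction: lower
Dim 1 (more Marfan-like phenotype) means higher odds of carrying a rare
pathogenic FBN1/TGFBR1/2 variant. The joint Model 2 adds about 7 points
of explained variance per sign over the FBN1-only Model 1 in this
synthetic cohort.

All report tables (QC, classes, FAMD coordinates, association results,
PRS weights and profiles, burden, SKAT-O scan, model comparison) are
written tab-separated under `out_dir`. `autoplot()` methods display the
FAMD factor map and the explained-variance comparison;
`inst/cli/genophen.R` is a thin command-line wrapper over
`run_panel_pipeline()`.

The bundled reference table `sem_reference_table()` carries the per-sign
explained-variance percentages published for a real 181-subject cohort;
`compare_models()` on it yields the mean increase 11.07% with paired
p = 1.6e-7.

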