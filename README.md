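# iristexture

Characterization and population analysis of human **iris surface features**
from photograph annotations.

The surface of a healthy iris carries five commonly studied textural
elements: Fuchs' crypts (diamond-shaped lacunae in the anterior-border
layer), contraction furrows (concentric folds near the iris periphery),
Wolfflin nodules (whitish collagen bundles along the outer ciliary border),
pigment spots (freckles/nevi, indistinguishable in photographs) and
conjunctival melanosis (pigment spotting on the surrounding sclera). Their
frequencies differ strongly between populations and some are genetically
associated (e.g. a *SEMA3A* variant with crypt grade). This package is for
anthropologists, forensic geneticists and ophthalmic researchers who grade
these features from annotated iris photographs and analyse the resulting
ordinal phenotypes, without any pixel-level image processing: the inputs are
the circles, clicks and flags a human rater records.

## What it provides

* **Annotation model + interchange formats** — validated per-iris records
  (three best-fit circles for pupillary ruff, collarette and scleral
  boundary; centre points; clicked crypt tips and pigment spots; furrow and
  nodule observations; melanosis flag; self-described colour on the
  five-level Fitzpatrick-style intensity scale), as JSON / JSON-lines, plus
  a cohort CSV format carrying grades, quadrant flags, covariates and
  genotypes.
* **Geometry engine** — ray–circle intersection from the user-defined iris
  centre (the three circles need not be concentric), annular zone
  classification (pupil / pupillary zone / ciliary zone), anatomical
  quadrant assignment (Q1 upper nasal, Q2 lower nasal, Q3 lower temporal,
  Q4 upper temporal; `eye_side`/`mirrored` control the nasal axis), crypt
  ciliary-extension fractions, angular arc unions, iris width.
* **Grading rules** — crypts on a 1–4 scale (grade 4 requires at least
  three *large* crypts — collarette origin and extension into strictly more
  than 50% of the ciliary zone — in at least three quadrants), furrows and
  nodules on 1–3 extension scales with a strict more-than-180° rule, spots
  binned by count (raw 1–4, collapsed 1–3), melanosis presence/absence.
* **Statistics, implemented from their definitions** — Goodman–Kruskal
  gamma `G = (C − D)/(C + D)` with the Brown–Benedetti null z-test, linear
  weighted kappa, Pearson chi-square homogeneity, grouped-count two-sample
  t-tests (pooled/Welch) with Bonferroni thresholds (0.05/3 = 0.0167),
  one-way ANOVA, Hardy–Weinberg chi-square, and maximum-likelihood
  **proportional-odds ordinal regression** `logit P(Y > j | x) = x'β − θ_j`
  (so OR = exp(β) > 1 means higher odds of a higher grade) with Wald tests,
  Nagelkerke R² and a likelihood-ratio parallel-lines check.
* **Synthetic cohorts and annotations** — seeded generators whose defaults
  are the published study's stated world (sample sizes, category
  frequencies, allele frequencies, odds ratios), plus an annotation
  generator that is an exact inverse of `characterize()`.
* **Packaged published tables** — the population frequency tables,
  descriptive statistics and association odds ratios, each tagged with its
  provenance, and a `reproduce_report()` that recomputes the printed
  statistics from them.

## Worked example

```r
library(iristexture)

## recompute the between-population crypt test statistics from the
## packaged published table
fx <- iris_fixtures()
chi2_homogeneity(fx$table3$crypt)
#> Pearson chi-square test of homogeneity: statistic = 67.6215, df = 6, p = 1.256e-12
grouped_grade_ttest(fx$table3$crypt["European", ], fx$table3$crypt["EastAsian", ])
#> independent samples t-test (pooled) on grouped grades: statistic = 8.3342, df = 1084, p = 2.34e-16
```

The χ² of 67.62 (6 df) says crypt grade frequencies differ overwhelmingly
between the three populations; the pooled t of 8.33 localizes one source:
Europeans carry higher crypt grades than East Asians. (The source
publication prints 67.388 and 8.333 — the small discrepancies trace to
internal inconsistencies of its frequency table; run `reproduce_report()`
for the full comparison.)

```r
## grade a synthetic iris and fit the genotype association
a <- simulate_annotation(feature_grades(4, 3, 1, spot_raw = 2), seed = 7, id = "demo")
characterize(a)$grades$crypt
#> [1] 4

co <- filter_cohort(simulate_cohort(simulation_config(seed = 1)))$included
eu <- co[co$population == "European", ]
cd <- code_genotype_dummies(eu$rs10235789)     # drops classes with n < 5
fit_proportional_odds(eu$crypt_grade[cd$keep], cd$X)
#> Proportional-odds fit: n = 619, J = 4, logLik = -773.491 (null -780.966), Nagelkerke R2 = 0.0259
#>   thresholds: -2.498, -0.362, 0.876
#>   het          beta =   0.1512  OR =  1.163  se = 0.1706  z =  0.886  p = 0.3755
#>   hom          beta =   0.8172  OR =  2.264  se = 0.2232  z =  3.661  p = 0.0002513
```

The simulated European cohort was generated with heterozygote/homozygote
odds ratios 1.507/2.203 on crypt grade; the fit recovers an OR of 2.26 for
derived homozygotes with p < 0.001, reading directly as "2.3-fold higher
odds of a higher crypt grade".

## Command line

```sh
Rscript inst/cli/iristexture reproduce                 # published-statistics report
Rscript inst/cli/iristexture simulate --seed 1 --out-cohort cohort.csv
Rscript inst/cli/iristexture grade annotations.jsonl cohort.csv
Rscript inst/cli/iristexture stats cohort.csv
Rscript inst/cli/iristexture assoc cohort.csv --marker rs10235789 --feature crypt
```

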