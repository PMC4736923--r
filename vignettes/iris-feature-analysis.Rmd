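---
title: "Grading and analysing iris surface features: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading and analysing iris surface features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iristexture)
```

# The measurement model

This package operates on *annotations* of iris photographs, never on
pixels. A rater records, per iris: whether it is too obstructed to grade;
the approximate iris and pupil centre points; best-fit circles around the
pupillary ruff, the collarette and the scleral boundary; a click on the
outermost tip of every crypt (with a flag for whether the crypt originates
from the collarette); a click on every pigment spot; presence, quadrants
and more-than-180° extension of contraction furrows and Wolfflin nodules;
a melanosis flag; and a self-described colour on a five-level intensity
scale. Everything downstream is computed from those primitives.

## Geometry

The three circles are drawn independently and in real annotations are not
concentric, so nothing is computed by comparing radii. All radial
quantities are defined along the **ray from the user-defined iris centre**
through the point of interest:

* the annular zone of a point compares its distance with the three
  ray–circle crossing distances (pupil / pupillary zone / ciliary zone /
  outside);
* the **ciliary extension fraction** of a crypt tip is
  $f = (d_p - d_\mathrm{collarette}) / (d_\mathrm{sclera} -
  d_\mathrm{collarette})$, clamped to $[0, 1]$;
* a crypt is **large** iff it originates from the collarette *and*
  $f > 0.5$ strictly. A tip at exactly 50% is small, and "more than 180°"
  for furrows and nodules is likewise strict — at-threshold cases always
  take the lower class.

Quadrants use the anatomical frame: Q1 upper nasal, Q2 lower nasal, Q3
lower temporal, Q4 upper temporal, as half-open 90° sectors starting at the
nasal axis and sweeping toward superior. Image coordinates are raster
(origin top-left, y down); for a right eye on an unmirrored image nasal is
+x and superior is −y. The source photographs were all right eyes, but the
image chirality of an arbitrary annotation tool is not knowable, so
`eye_side` and `mirrored` are explicit per-annotation fields rather than
assumptions.

Points clicked slightly outside the sclera circle are clamped to $f = 1$
with a warning instead of being rejected: click noise near the limbus is
routine and should not invalidate an otherwise sound annotation (the
`--strict` CLI mode upgrades such warnings to errors).

## Grading scales

* **Crypts (1–4):** 1 none; 2 only small crypts; 3 at least one large crypt
  in fewer than three quadrants; 4 at least three large crypts in three or
  more quadrants. Grade 4 is the *conjunction* of the two printed clauses
  (≥ 3 large crypts AND ≥ 3 distinct quadrants containing them); three
  large crypts stacked in one quadrant are grade 3. The original
  description of grade 2 differs between its methods ("only small crypts")
  and results ("small crypts … in at least three quadrants") sections; the
  methods definition is implemented and carries no quadrant requirement.
* **Furrows / nodules (1–3):** absent / less than 180° / more than 180°
  (strict), sharing one rule because their published scales are identical
  in form.
* **Spots:** raw 1–4 (0, 1–2, 3–5, > 5 spots); the collapsed 1–3 scale
  merges raw grades 3 and 4 (they were merged in the source study because
  heavy spotting is rare outside Europeans). Both are kept in every record.
* **Melanosis:** presence/absence. **Colour:** self-reported 1–5, allowed
  missing (it is not annotation-derived).

Grades are 1-based internally; the published frequency tables label the
same categories 0-based, and the packaged fixtures keep those labels.

# The statistics

All statistics are implemented from their definitions (and verified in the
test suite against brute-force/naive oracles and, for the ordinal
regression, against an established independent optimizer).

**Goodman–Kruskal gamma.** $G = (C - D)/(C + D)$ over concordant and
discordant pairs; ties count for neither. For the null test the package
uses the Brown–Benedetti standard error
$\mathrm{ASE}_0^2 = \tfrac{4}{(P+Q)^2}\bigl(\sum n_{ij}(A_{ij}-D_{ij})^2 -
(P-Q)^2/n\bigr)$ (with $A_{ij}, D_{ij}$ the per-cell concordant/discordant
partner counts and $P = 2C$, $Q = 2D$), i.e. the convention of the major
commercial packages, including the one used for the original analysis. A
simpler textbook approximation, $z = G\sqrt{(C+D)/(n(1-G^2))}$, was
evaluated and rejected during development: under independent ordinal data
(2000 replicates of $n = 500$) it rejected at 0.0035 instead of the
nominal 0.05 — useless as a calibrated test — while the Brown–Benedetti z
measured 0.0525, inside the 99% binomial band. The calibration experiment
is part of the acceptance suite.

**Weighted kappa.** Linear weights $w_{ij} = 1 - |i-j|/(k-1)$; with $k = 2$
it reduces to Cohen's kappa (tested).

**Homogeneity and pairwise tests.** Pearson chi-square with expected counts
from the margins, no continuity correction. Pairwise population contrasts
expand the per-category counts to equally spaced scores and apply the
two-sample t-test — pooled variance by default, because pooling is the
closest match to the published pairwise values; a Welch variant exists
because some published comparisons fall between the two conventions. The
statistic is invariant to affine recoding of the scores, so 0- vs 1-based
grade labels cannot change it. The Bonferroni threshold for three pairwise
comparisons is 0.05/3, reported as 0.0167.

**Hardy–Weinberg.** Plain Pearson chi-square on 1 df against
$p^2 / 2pq / q^2$ expectations from the sample allele frequency, no Yates
correction (the calculator used by the original study does not document
one); monomorphic samples return 0 with a degenerate flag.

**Proportional odds.** The cumulative-logit model is parameterized
$\operatorname{logit} P(Y > j \mid x) = x'\beta - \theta_j$, so
$e^\beta > 1$ always reads "higher odds of a *higher* grade" — matching how
the published odds ratios are phrased, and the opposite sign of some
textbook conventions; this is stated prominently wherever coefficients are
reported. Fitting is Newton ascent with step halving on the natural
parameters (the log-likelihood is concave there), analytic gradients, a
strict monotonicity guard on the thresholds, convergence at gradient norm
below 1e-8 within 100 iterations, and standard errors from the observed
information at the optimum. Null-model thresholds have the closed form
$\theta_j = \operatorname{logit}\bigl(\sum_{k \le j} n_k / n\bigr)$, which
doubles as a test oracle. Nagelkerke $R^2$ normalizes the Cox–Snell
likelihood ratio by its attainable maximum. Genotypes enter as
heterozygote/derived-homozygote indicators against the ancestral
homozygote; classes with fewer than five carriers are eliminated together
with their individuals, reproducing the original exclusion rule. The
parallel-lines check is a likelihood-ratio test against the unconstrained
cumulative model (separate slopes per threshold, fitted quasi-Newton with
a feasibility penalty, initialized at the constrained fit) on
$(J-2)\,p$ df; with $J = 2$ the models coincide and the test reports
not-applicable.

# The synthetic world

The cohort generator's defaults are the published study's stated
conditions, not tuning knobs:

| parameter | default | source |
|---|---|---|
| recruited n per population | 475 / 623 / 367 (EA/EU/SA) | published totals |
| obstructed / disorder exclusions | 8, 4, 2 / 0, 0, 1 | published results text |
| category probabilities, six traits | published frequency table | counts ÷ included n |
| rs10235789 derived-allele frequency | 0.08 / 0.48 / 0.28 | published discussion |
| genotype ORs on crypt grade | het 1.679/1.507/2.206; hom —/2.203/2.721 | published association table |
| male-vs-female OR on crypt grade | 1.54 / 1.72 / 2.07 | published results text |
| iris width mean (px) | 376.72 / 394.45 / 384.92 | published descriptives |
| iris width SD (px) | 14.543 | back-solved from printed F = 200.161 |
| age mean / SD / range | published means / 2.5 / 18–35 | SD chosen; range is the recruitment window |
| raw-spot split of collapsed grade 3 | 0.7 raw-3 | unpublished; fixed once |

Three values required a one-time choice. The within-population iris-width
SD is not published, but the one-way ANOVA F statistic is; with the
published group means and sizes, $F = 200.161$ pins the pooled
within-group SD at 14.543 px, so that is the default. The East Asian
derived-homozygote odds ratio was eliminated from the published model
(fewer than five carriers); the generator extrapolates it additively as
the squared heterozygote OR, consistent with the study's observation that
the allele's effects appear additive. The split of collapsed spot grade 3
into raw grades 3 and 4 is unpublished and fixed at 0.7.

Crypt grade is drawn from the same cumulative-logit model the analysis
fits — baseline thresholds reproduce the published category frequencies
for the reference class, genotype and sex effects enter as log-ORs — so
association-module parameter recovery has a well-defined truth. One caveat
is inherited from the source: the published ORs are covariate-adjusted
(conditional), while the generator applies them marginally; they are
approximations of the published effects, not reproductions.

The annotation generator inverts `characterize()` by construction: crypt
tips are placed at extension fractions strictly inside the intended class
(defaults 0.6–0.9 for large, 0.1–0.4 for small, overridable down to ±0.02
around the 0.5 boundary for stress tests), quadrants are distributed to
satisfy the grade clauses, and arc unions drive the furrow/nodule
observations. Circles are mildly non-concentric (centre offsets up to 5% of
the sclera radius) so the general ray-intersection path, not a concentric
shortcut, is what round-trip tests exercise.

What a green test does **not** establish: the generator draws the five
features independently given the configured marginals (real irises show
correlated features, e.g. crypts with furrows in Europeans), click noise is
absent, obstruction is a random flag rather than an image property, and
per-population ns at the defaults are fixed, not sampled. Distributional
tests therefore validate the machinery, not any biological claim.

Reproducibility: a root seed spawns fixed substreams (1–3: the three
populations' cohort rows, in fixture order; the annotation and rater
generators take explicit seeds). Identical configurations are
byte-identical through the CSV writer, across platforms.

# Reproduction of the published statistics, honestly

`reproduce_report()` recomputes the printed statistics from the packaged
frequency table. The three derived percentages (29.8% / 43.4% crypt
extension, 23.3% melanosis) reproduce exactly at 1 d.p. The six homogeneity
chi-squares and the pairwise t values do **not** reproduce at the printed
3-d.p. precision, and the package does not pretend otherwise: the
pigment-spot chi-square matches exactly only when computed from counts
implied by the table's printed *percentages* (which contradict its printed
*counts* by one individual), and the crypt chi-square matches exactly only
if one European count is shifted by one (breaking the printed row sum). The
published table is internally inconsistent with the data its statistics
were computed from — a transcription-level artifact. The corresponding
acceptance assertions are deliberately left failing at the printed-precision
tolerance; the implementation itself is verified against independent
oracles and R's own `chisq.test`/`t.test` on the same inputs.

# Numerical choices and edge cases

* Round-half-up at the reported precision for percentages and the
  Bonferroni threshold (base R rounds half to even; the published tables do
  not).
* Circle nesting is validated on 360 sampled rays at construction; any
  violation (e.g. a collarette circle larger than the sclera circle) is a
  typed validation error naming the problem.
* Half-open conventions throughout: quadrant sectors `[0°, 90°)` etc., arcs
  `[start, end)` with wraparound; unions are computed exactly by interval
  merging, never by discretization (discretization is reserved for the test
  oracle).
* All-tied gamma, zero-margin chi-square, zero-variance t, empty-reference
  genotype coding and non-convergent fits raise typed errors rather than
  returning NaN; perfectly separated regressions either fail convergence or
  are flagged as quasi-separated.

# Limitations

No pixel processing, no automatic circle fitting, no obstruction detection
(the flag is always rater-supplied), no freckle/nevus distinction (not
reliable from photographs), no multi-marker or GWAS machinery — exactly the
four-marker single-SNP design of the source study. Raw per-participant data
were never published, so gamma values, association odds ratios, Nagelkerke
R² values and Hardy–Weinberg chi-squares from the original cohort cannot be
reproduced here at all; the package substitutes property-based validation
(oracle equivalence, parameter recovery, calibration) for those quantities.
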