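---
title: "Methods: lifetime-aligned serum lipidome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime-aligned serum lipidome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipicourse)
```

# The problem and the design

`lipicourse` analyses longitudinal serum lipidomics of a Dicer1-Pten
double-knock-out (DKO) mouse model of high-grade serous ovarian carcinoma.
Fifteen DKO and fifteen control mice are bled every two weeks from week 8
until death or the 46-week study end, and each serum draw is profiled by
LC-MS, yielding a peak-area table of roughly a thousand annotated lipid
features over several hundred samples.

Because DKO mice die at different ages, calendar age is a poor axis for
comparing disease progression. Every draw is therefore mapped to a
**percentage lifetime**, `100 * age / lifespan`, where lifespan is the
animal's age at its final collection, and binned into five **lifetime
stages**: [0,30)% I, [30,45)% II, [45,60)% III, [60,75)% IV and [75,100]%
V. The stage labels in the literature are printed with overlapping
endpoints ("0--30%", "30--45%", ...); we resolve the ambiguity by making
each bin half-open with the shared boundary belonging to the *later*
stage (a draw at exactly 30% is stage II, one at exactly 75% is stage V).
Any deterministic convention would do; this one makes the bin map a true
partition, which the tests assert.

# Feature curation and drift correction

Three filters, computed on the raw values so their removal sets commute:

* **Blank filter** (default 5x): a feature whose mean study-sample area is
  below five times its mean blank-injection area is background. The
  reference population for "sample area" is not pinned down in the
  literature; we use the study-sample mean. A feature at exactly the
  threshold is kept.
* **QC presence** (default 50%): a feature must be detected (nonmissing
  and positive) in at least half of the pooled-QC injections; exactly half
  is kept. "Detected" is our operationalization -- peak-area tables do not
  carry an explicit detection flag.
* **QC RSD** (default 30%): features whose QC relative standard deviation
  (100 * sd/mean) exceeds 30% are unstable and removed; exactly 30% is
  kept. A zero QC mean leaves the RSD undefined; such features cannot be
  assessed and are removed, flagged in the report.

**Drift correction** then fits, per feature, a cubic spline of QC
intensity against injection order and divides every sample by the spline
value at its own order, rescaling by the feature's QC mean. With more
than six QCs we use a smoothing spline whose smoothness is chosen by
generalized cross-validation; with four to six QCs an exact cubic
interpolant with Forsythe-Malcolm-Moler (FMM) end conditions. FMM rather
than natural end conditions is deliberate: a natural spline forces zero
second derivatives at the run boundaries and therefore cannot reproduce a
cubic drift exactly, while the FMM interpolant restores any polynomial
drift of degree at most three to machine precision on noiseless data --
a property the test suite exercises. Linear drift lies in the null space
of the smoothing penalty, so the smoothing-spline path also removes it
exactly. A fitted spline value at or below zero would flip the sign of an
intensity; those cells are set missing and reported instead.

Missing intensities survive curation untouched and are imputed only
immediately before statistics and classification, as half the feature's
minimum observed positive value -- the usual limit-of-detection surrogate
in metabolomics.

# Lipid mass arithmetic

Annotation verification needs shorthand -> formula -> adduct m/z -> ppm.
The grammar covers `CLASS(total_C:total_DB)` with an optional sphingoid
`d` prefix, an `O-` ether prefix, and `_`- or `/`-separated chains whose
carbons and double bonds are summed, for FA, LPC, LPE, PC, PE, PI, TG,
DG, Cer, HexCer and SM (plus ether PC/PE). Composition rules are
assembled from building blocks: an esterified acyl contributes
C~c~H~2c-2d-2~O; the glycerophospholipid backbones are
glycerophosphocholine C8H20NO6P, -ethanolamine C5H14NO6P and -inositol
C9H19O11P; the sphingoid `d` backbone folds two hydroxyls and one amine
into the total count (Cer(c:d) = C~c~H~2c-2d+1~NO3); HexCer adds C6H10O5;
SM adds phosphocholine C5H12NO3P; an ether linkage removes one O and adds
two H relative to the diacyl form. Hydroxylated (`-OH`) and `t`-backbone
sphingolipids are declared unsupported rather than guessed -- their extra
oxygens are not inferable from the shorthand alone.

Adduct masses use the proton-transfer convention with a proton mass of
1.007276 Da; NH4 adds 18.033823 Da, acetate (CH3COOH - H) 59.013853 Da,
formate (HCO2H - H) 44.998204 Da. This convention reproduces the printed
acetate-adduct mass errors of the Cluster-D ceramides to within the
rounding of the 4-decimal experimental m/z (the acceptance script
recomputes them). A few published annotation rows (for example the
PE(16:0_20:4) entries) are not reproduced by any standard
formula/adduct convention we tried; the parser flags them implicitly by
disagreeing, and we do not force agreement.

# Differential statistics

Fold changes are `log2(mean DKO / mean control)` on raw (imputed)
intensities; Welch's unequal-variance t-test is run on the same raw
values. Log transformation and autoscaling are applied only where the
downstream method needs them (classification), matching the published
processing order. The global DKO-vs-control contrast pools all draws and
alone carries a Benjamini-Hochberg correction (q < 0.05); the per-stage
contrasts use unadjusted p < 0.05, exactly as described. Draws from the
same animal are treated as independent observations -- a known
simplification of the published analysis that we replicate rather than
correct; a mixed-effects treatment is out of scope.

Upset-style **exclusive intersections** partition the union of the five
stage sets by membership pattern, and features significant in at least
three stages are flagged as recurrent.

# Trajectory clustering and networks

For the globally significant lipids, each feature's trajectory is the
5-vector of stage-wise log2 fold changes. Trajectories are clustered
agglomeratively under **correlation distance** (1 - Pearson r) with
**complete linkage**, cut at k = 4 by default. The agglomeration is
written out explicitly so that ties in the merge distance break
deterministically toward the smallest feature index; `stats::hclust`
serves as the independent oracle in the tests. Complete linkage produces
nondecreasing merge heights (no inversions), which is asserted.

One practical caveat, visible on synthetic cohorts: a handful of
null-but-significant features inside the clustered set act as outliers
under complete linkage, and cutting at k = 4 can spend clusters on those
singletons while merging two genuine trajectory families. The cluster
count is exposed as a parameter for exactly this reason.

Correlation networks connect pairs of features whose trajectory Pearson r
is at least 0.5. Whether the published networks used trajectories or
per-sample abundances is ambiguous; we compute them on the 5-point
trajectories -- the same space the clustering uses -- and treat that as
the package's convention.

# Per-stage classification

The per-stage cascade is: Welch p < 0.05 within the stage, then greedy
correlation pruning at r > 0.8 (survivors scanned in ascending-p order,
the lower-p member of a correlated pair kept -- the published rule does
not say which member to keep, so we fix this convention), then a
stratified 70/30 split, autoscaling fitted on the training portion, a
100-tree random forest, and retention of features whose normalized Gini
importance is at least the mean importance.

Deliberately, the p-filter and pruning see *all* stage samples before the
split, reproducing the published ordering and its information leakage
into the test set; `leakage = FALSE` restricts every selection step to
training data for a clean variant. Splits stratify by class over samples,
not animals, again as published; repeated draws of one mouse can
therefore straddle the split.

Five classifiers are trained on the selected, autoscaled features:
logistic regression (sigmoid probability, 0.5 threshold), a 100-tree
Gini random forest, an RBF-kernel SVM with C = 1 and probability
outputs, 5-nearest-neighbors with uniform weights, and a soft-voting
ensemble whose probability is the arithmetic mean of the four members.
The RBF kernel coefficient is not specified in the source; we pin
gamma = 1/(d * mean feature variance) ("scale"-style) and record it in
the fitted object. Evaluation is ROC-AUC on the held-out 30% with the
ROC built by threshold enumeration and trapezoidal integration, plus
5-fold cross-validated accuracy on the training portion. The permutation
test refits the chosen model on 1000 label permutations and reports
`(#{perm >= true} + 1)/(n + 1)`, whose floor at n = 1000 is 1/1001.

# Survival screening

Prognostic candidates are the union of (i) volcano-selected features
(Welch p < 0.05 and |log2 FC| >= 1, DKO stage I as reference against
stages II-V) recurring in at least three of the four comparisons and
(ii) features significant in at least three of the five DKO-vs-control
stage tests. For each candidate, DKO animals are split at the median of
the feature's final-draw abundance (ties go to the low group), the two
groups get Kaplan-Meier curves, and a log-rank test (hypergeometric
variance, simultaneous risk sets at ties) decides retention at p < 0.05;
retained lipids are ranked by |ΔRMST|. The restricted mean survival time
is the exact step-function integral of S(t); its default restriction
time is the smaller of the two groups' largest observed times, the
standard restriction when none is stated. Control mice alive at week 46
are censored there. The risk tables behind the estimators come from the
`survival` package; the Nelson-Aalen cumulative hazard and the RMST
integral are assembled from those tables, and all of them are checked
against hand-computed product-limit oracles in the tests.

# The synthetic cohort generator

The generator exists so every stage of the pipeline is testable without
the deposited data. It emulates: 15 + 15 animals; DKO lifespans from a
Weibull (shape 6, scale 38, truncated below 27 weeks so the first draw at
week 8 still falls in stage I; mean ~35 weeks); control lifespans from a
longer-lived Weibull (shape 6, scale 52) censored at 46 weeks; biweekly
draws from week 8 with a terminal draw at death; ~1000 features with
log-uniform baselines (peak areas 2^13 to 2^27) and log-normal
multiplicative noise (sigma 0.5 log2 units for study samples, 0.1 for
the pooled QC); a pooled QC every 10 injections; blank injections; and a
smooth half-sine multiplicative drift (amplitude 0.15) over injection
order.

Four trajectory archetypes modulate DKO samples stage-wise (log2 units,
stages I-V): A (0.1, 2.6, 0.6, 1.2, 1.4), B (0, 2.2, 0.1, 0.3, 3.0),
C (0.1, 1.8, 0.6, 2.2, 0.8), D (0, 0.2, 0.1, 0.4, 2.6), each scaled by a
per-feature amplitude in [0.8, 1.2]. A and B share the rise-dip-spike
motif but differ in which peak dominates; all pairwise pattern
correlations stay at or below 0.77 so the four shapes are recoverable
under correlation-distance clustering, and all start near zero at stage
I so per-stage significance counts grow toward the late stages, with the
II-to-III dip, as in the modeled disease. Fractions default to
2/1/2/3% of features for A-D. Dedicated fractions exercise each
curation filter: blank-dominated background features (2%), QC-unstable
features (2%) and features absent from most QCs (1%). Prognostic lipids
(5 by default) have their final-draw log2 abundance shifted by
`beta * standardized lifespan` with beta = 1.5. They are drawn from
archetype A, whose members recur in enough stage comparisons to enter
the prognostic candidate set -- a survival-coupled lipid that is not
stage-differential would be invisible to the screen by construction,
mirroring how the screened lipids in the modeled study were themselves
differential. When a configuration simulates no archetypes, the coupling
falls back to null-background features so the survival machinery remains
testable in isolation.

What the generator does **not** emulate: within-animal serial
correlation (draws are independent given the stage effect), lipid-class
correlation structure, retention-time or m/z realism, censoring of
individual draws, batch boundaries, or missingness that depends on
abundance. Passing recovery tests therefore demonstrates that the
machinery is correct under the stated model, not that the pipeline's
operating characteristics transfer to real cohorts -- in particular the
independence assumption flatters the per-stage tests exactly as it does
in the published analysis.

# Numerical choices and problem sizes

Filters treat thresholds inclusively (exactly 5x, exactly 50%, exactly
30% all survive). The drift corrector requires at least four observed
QCs per feature and skips constant QC trends (correction would be the
identity). Welch's test refuses two zero-variance groups unless their
means agree (then t = 0, p = 1). BH uses the step-up form with
monotonicity enforcement via `stats::p.adjust`. The complete-linkage
tie-break is the smallest feature-index pair in row-major order.
Stratified splits round the per-class training count and clamp it so
both sides of the split stay nonempty.

The test suite runs cohorts of 60-1000 features (1000 only for the two
type-I calibration checks), 50 single-feature replicates for the
prognostic recovery rate, 99-1000 permutations for the permutation-test
checks, and five-by-five archetype recovery replicates; these sizes were
chosen so each check has the statistical resolution its assertion needs
(binomial 3-sigma bands, U-statistic bands for the null AUC) while the
whole suite stays fast enough to run habitually.

# Known limitations

* The published headline counts (87 global q < 0.05 lipids; per-stage
  counts 14/121/56/136/298; best AUCs 0.80/0.70/0.85/0.66/0.75; ΔRMST
  10.96/9.35/7.75 weeks) depend on the deposited cohort (Metabolomics
  Workbench ST002276) and, for the AUCs, on unpublished split seeds; they
  are reproducible only against that data, which this package reads but
  does not redistribute. The acceptance test that recomputes those counts
  stays red until the accession tables are placed under
  `data-raw/ST002276/`.
* Repeated measures are pooled in all univariate tests (as published);
  significance counts on real cohorts are anticonservative to an unknown
  degree.
* The shorthand grammar deliberately rejects hydroxylated sphingolipid
  names rather than guessing compositions.
* Classification reproduces the published selection leakage by default;
  the `leakage = FALSE` and animal-grouped split options exist but change
  the estimand and are not the default.
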