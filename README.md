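# lipicourse

Lifetime-aligned analysis of longitudinal serum lipidomics in a
Dicer1–Pten double-knock-out (DKO) mouse model of high-grade serous
ovarian carcinoma. Fifteen DKO and fifteen control mice are bled every
two weeks from week 8 until death or the 46-week study end; each draw is
profiled by LC–MS, giving a peak-area table of ~1000 annotated lipid
features over several hundred serum samples. `lipicourse` implements the
full computational course over such a cohort, for metabolomics
researchers who want the pipeline reusable, parameterized and tested:

1. **Feature curation** — blank filter (study mean ≥ 5× blank mean), QC
   presence (detected in ≥ 50% of pooled-QC injections), QC RSD
   (100·sd/mean ≤ 30%), and per-feature cubic-spline drift correction of
   intensity against injection order.
2. **Lipid mass arithmetic** — shorthand name → elemental formula →
   adduct m/z → signed ppm error, e.g.
   `Cer(d34:1)` → C34H67NO3 → [M+CH3COOH−H]⁻ at 596.52595 Th.
3. **Lifetime alignment** — percentage lifetime `100·age/lifespan`,
   binned into stages I [0,30)%, II [30,45)%, III [45,60)%, IV [60,75)%,
   V [75,100]%.
4. **Differential statistics** — log2 fold changes `log2(x̄_DKO/x̄_ctl)`,
   Welch's t-test with Satterthwaite df, Benjamini–Hochberg q-values for
   the global contrast, per-stage p < 0.05 sets, upset-style exclusive
   intersections and ≥ 3-stage recurrence.
5. **Trajectory clustering** — per-lipid 5-vectors of stage-wise log2 FC,
   agglomerative clustering with correlation distance `d(x,y) = 1 − r_xy`
   and complete linkage `D(X,Y) = max d(x,y)`, cut at k = 4; Pearson
   correlation networks at r ≥ 0.5.
6. **Per-stage classification** — Welch p-filter → correlation pruning
   (r > 0.8) → random-forest Gini-importance selection (importance ≥
   mean), then logistic regression, 100-tree random forest, RBF SVM
   (C = 1), 5-NN and a soft-voting ensemble, evaluated by ROC-AUC on a
   stratified 70/30 split with 5-fold CV and a 1000-permutation test
   (empirical p floor 1/1001).
7. **Prognostic screening** — volcano selection (p < 0.05, |log2 FC| ≥ 1,
   DKO stage I reference), median split of DKO animals at the final-draw
   abundance, Kaplan–Meier `S(t) = Π(1 − d_i/n_i)`, Nelson–Aalen
   `H(t) = Σ d_i/n_i`, log-rank test, and ranking by |ΔRMST| where
   RMST(τ) = ∫₀^τ S(t) dt.
8. **Synthetic cohorts** — a generator with four trajectory archetypes,
   QC/blank injections, instrument drift and survival-coupled prognostic
   lipids, plus ground-truth recovery scoring, so every stage is testable
   without the deposited data.

## Worked example

```r
library(lipicourse)
run <- run_lipidome_pipeline(pipeline_config(seed = 3))
summary(run)
```

```
lipidome time-course run
  features: 1000 raw -> 950 curated; study samples: 526
  global q<0.05 lipids: 87
  per-stage significant (I-V): 50/106/84/123/115 
  recurrent (>=3 stages): 64 
  trajectory clusters: A=41, B=42, C=3, D=1 
  stage I test AUC: logistic=0.59, random_forest=0.62, knn=0.66, svm_rbf=0.64, voting=0.68
  stage V test AUC: logistic=1.00, random_forest=1.00, knn=1.00, svm_rbf=1.00, voting=1.00
  prognostic candidates: 64 -> hits: 10 

prognostic lipids (log-rank p < 0.05, ranked by |delta RMST|):
 feature_id    logrank_p delta_rmst n_low n_high
      F0001 0.0017718967  -5.139852     8      7
      F0003 0.0006927057  -4.290170     8      7
      ...
```

Reading the output: 50 of 1000 simulated features were removed by the
curation filters (background, QC-unstable or QC-absent features). 87
lipids pass the global Welch + BH screen at q < 0.05. Per-stage
significant counts stay near the 5% null rate at stage I (the simulated
disease is metabolically quiet early) and grow toward the late stages,
with the II→III dip the trajectory archetypes encode. Classification is
near-chance at stage I and saturates from stage II on, where the injected
group effects are large. The prognostic screen tests 64
stage-differential candidates; the five simulated survival-coupled lipids
(`F0001`–`F0005`, negative ΔRMST: low final-draw abundance predicts
shorter life) are all recovered, alongside a handful of borderline
false positives — about what a 5% log-rank level admits over 64
candidates. Recovery can be scored against the generator's ground truth:

```r
truth_report(run$truth, prognostic_hits = run$prognostic$feature_id)
#> $prognostic_recall
#> [1] 1
```

A thin CLI covering simulation, curation and full runs ships in
`inst/scripts/lipicourse`.

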