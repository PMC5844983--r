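---
title: "Methods: untargeted metabolomics biomarker panel discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted metabolomics biomarker panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabopanel)
```

## The problem and the data model

Untargeted LC-MS metabolomics semi-quantifies hundreds of small molecules
per biofluid sample as raw peak heights. In a case/control design (here:
early Parkinson's disease vs. matched controls, in plasma and CSF), the
analysis question is whether a small panel of metabolites separates the
groups well enough to be a candidate diagnostic signature — and which
metabolites those are.

`metabopanel` models the data as a `feature_table`: a samples × features
intensity matrix with explicit `NA` missingness (a missing peak is a
distinct state from a measured zero), plus sample metadata (role:
biological / blank / QC; group; sex; age; levodopa-equivalent daily dose
LEDD; matrix) and feature metadata (m/z, retention time, annotation,
internal-standard flag, annotation validation level). Every stage of the
pipeline consumes and returns this object; results are tibbles.

## Pipeline overview

The fixed stage order is:

1. **Minimum-intensity filter** — features whose maximum biological
   intensity is below the detectability threshold (default 2000) are noise
   and removed.
2. **Blank filter** — a feature is removed iff its median intensity in
   *every* biological group is at or below its median in the extraction
   blanks. Requiring all groups minimizes false removals; medians use
   present values only. Internal standards, which are spiked into blanks
   too, are exempt.
3. **Imputation** — features missing in ≤ 10% of biological samples are
   completed by Bayesian-PCA; features above the cap are dropped (the
   conservative reading of "only sporadically missing peaks are
   estimated"). Observed cells are never altered.
4. **Internal-standard normalization** — NOMIS, then CCMN (both
   configurable), removing sample-wise technical variation measurable on
   the spiked standards.
5. **TIC normalization** — each sample scaled so its summed non-IS
   intensity equals the grand mean of the biological sample sums.
6. **Sample screening** — robust-PCA orthogonal-distance outlier removal,
   then age and sex corrections, an LEDD regression screen, and a
   covariate-interaction check.
7. **Modelling and evaluation** — PLS-DA with VIP-based panel selection,
   random-forest benchmarking, repeated-split robustness assessment, a
   single held-out 70/30 test, Monte-Carlo cross-validation of panel-size
   sufficiency.
8. **Univariate statistics and pathway enrichment** for the selected
   panel.

A provenance log records the feature count after every preprocessing
stage.

## The synthetic cohort generator

The clinical measurements this kind of study rests on are typically not
redistributable, so the package ships a generator
(`cohort_design()` / `generate_cohort()`) whose defaults are the study
conditions the pipeline is meant for, and whose planted ground truth makes
every downstream stage testable:

* **Design sizes.** Plasma arm: 80 cases / 76 controls, 334 features; CSF
  arm: 40 / 37 and 302 features; 20 (resp. 14) discriminative features
  with |log2 fold difference| uniform in [0.05, 0.5] and random sign —
  the magnitudes a real panel table reports.
* **Intensity model.** Log-normal: a per-feature baseline log-mean uniform
  over [log 2.5e3, log 8e5] (the printed group means of such panels span
  2.4e3–8e5), biological CV 0.25 (panel RSD columns cluster around
  10–40%), and a per-sample multiplicative technical factor
  (log-SD 0.15) shared with the internal standards — so IS normalization
  is demonstrably effective, mirroring why multiple spiked standards are
  used at all. Group effects multiply the case-group mean by
  `2^log2fd`, which keeps intensities positive and reproduces the
  reported effect structure.
* **QC replicates** are log-normal replicates of the pooled biological
  mean at a target replicate RSD (default 12%, matching "median QC RSD
  below 15%"). Half of their log-variance is a per-injection factor
  carried by the internal standards, half is per-feature.
* **Blanks** carry 5% of the biological median, except planted
  contaminants (default 5 features) that are 3× *higher* in blanks — the
  features the blank filter must remove.
* **Missingness** is MCAR at 5% over biological non-IS cells (so most
  features stay under the 10% imputation cap, as in a table where
  sporadic misses dominate); an intensity-dependent left-censoring mode is
  available because the true mechanism in real data is usually a mixture.
* **Covariate effects.** Ages are uniform over 45–85 in both groups
  (age-matched design, median in the 60s); sex is ~64% male in both
  groups. Planted age slopes are N(0, (0.08 · feature SD)²) per year:
  over a 40-year age span that makes the typical planted trend about one
  biological SD end-to-end — large enough that a per-feature regression
  screen at α = 0.05 detects most of them (planting effects the stated
  screen cannot see would make the ground truth vacuous), small enough
  not to dominate the group signal. Sex shifts are N(0, (0.5 · SD)²).
  Specifying slopes in absolute intensity units per year is not
  meaningful across features whose scales span two orders of magnitude,
  which is why slopes are sized relative to each feature's own SD.
* **Planted outliers** (`plant_outliers()`) perturb samples on the
  natural-log scale along a random direction orthogonal to the top
  principal subspace, scaled to a multiple of the root-mean-square
  residual norm — exactly the orthogonal-distance signal ROBPCA flags.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: correlated metabolite modules (features
are independent given the sample factor), retention-time drift and batch
order, adduct/isotope structure, heavy-tailed single-feature artifacts,
and informative (disease-related) missingness. Parameter-recovery results
on these cohorts demonstrate that the machinery is correct and unbiased
under its stated model, not that any particular clinical effect size is
attainable.

```{r generator, message = FALSE}
sim <- generate_cohort(plasma_design(seed = 1))
sim$table
head(sim$truth$discriminative, 3)
```

## Statistical components and the choices behind them

### Bayesian-PCA imputation

`bpca_impute()` fits `x = W z + mu + eps` by EM over the observed entries
only (the E-step conditions each sample's latent score on its observed
coordinates; missing cells never influence the fit), with automatic
relevance determination shrinking uninformative latent columns. The
candidate dimensionality defaults to `min(n, p) − 1` capped at 20: ARD
makes the result insensitive to the cap, while an uncapped candidate set
on a 156 × 334 table costs quadratically more for no measurable accuracy
gain. Imputation runs on natural-log intensities, which guarantees
positive imputed values and matches the multiplicative error structure;
zeros (legal measurements) are excluded from the log-scale fit but never
altered. A fixed-rank PPCA-EM fallback is available via `ard = FALSE`.

### NOMIS and CCMN

Both operate on natural-log intensities. NOMIS subtracts each feature's
least-squares projection onto the column-centered log-IS matrix. CCMN
first removes group-correlated variation from the IS matrix (residuals on
the centered class indicator), extracts principal components of those
residuals (enough for 90% of the residual variance by default), and
subtracts the projection onto those — so group signal cannot leak out of
the features through the standards. Models are fitted on biological
samples and applied to biological and QC samples; blanks are consumed by
the blank filter earlier and left alone. Constant standards make both
transforms the identity.

### Robust PCA outlier screening

`robust_pca_distances()` uses projection-pursuit initialization
(Stahel–Donoho outlyingness over directions through random sample pairs,
h = 0.75 coverage), classical PCA on the least-outlying subset, and one
reweighting step on the orthogonal-distance inliers. Flagging uses the
orthogonal distance only, with the Wilson–Hilferty cutoff
`(median(OD^{2/3}) + MAD · z_{0.975})^{3/2}`; score distances are
reported against `sqrt(χ²_{k,0.975})` but not acted on. The automatic
subspace dimension is `min(k_80, k_gap, 10)`: the 80%-of-robust-variance
rule alone degenerates on noise-dominated p > n tables (a
Marchenko–Pastur spectrum has no 80% elbow, the rule saturates the cap,
and the subset fit then overflags 13–24% of clean samples), so the
largest-spectral-gap scree cut bounds it. Measured operating
characteristics under the generator: ~1–6% false flags on clean cohorts,
~5% on clean low-rank Gaussian data, sensitivity 1.0 for
magnitude-10 orthogonal outliers. A numerical floor on the cutoff keeps
machine-precision residuals of exactly low-rank data from being flagged.

### Covariate corrections

Age: per-feature OLS of intensity on age over all biological samples
(groups pooled); slopes with two-sided p ≤ 0.05 are subtracted
(`intensity − slope · (age − mean age)`). Sex: male and female means are
shifted onto the pooled mean, making the post-correction difference
exactly zero. LEDD: a report-only regression screen over PD samples. The
interaction check fits `intensity ~ age*sex + age*ledd + sex*ledd` on PD
samples (LEDD exists only there). Corrections are computed on the full
cohort before any train/test split — the same order the emulated workflow
uses; the mild information-leakage risk of full-cohort covariate fitting
is accepted and documented here rather than silently redesigned.
Outliers are removed before covariate correction (configurable by calling
the stages directly).

### PLS-DA, VIP, and panel selection

`fit_pls()` is single-response NIPALS: predictors autoscaled, the class
coded 0/1 (PD = 1, always the positive class) and centered. For one
response each component is closed-form (`w_a ∝ X'y`), scores are mutually
orthogonal, and weights unit-norm, so

VIP_j = sqrt( p · Σ_a SSY_a w_{ja}² / Σ_a SSY_a ),  Σ_j VIP_j² = p

holds exactly. Class scores are raw regression predictions mapped back
from the centered coding and clipped to [0, 1]; 0.5 is the label
threshold (a Youden-optimal threshold was considered and rejected as an
extra tuned parameter the emulated workflow does not use). Component
count is chosen by repeated stratified CV (default 10 folds × 10
repeats, capped at 20 components), maximizing mean CV AUC with ties to
the smaller count.

The panel is cut from the top-100 VIP curve, min-max scaled, at the rank
maximizing the perpendicular distance to the chord from the first to the
last point — a parameter-free, reproducible reading of "where the slope
flattens". On an idealized knee (flat top-20, then linear decay) it
recovers rank 20 exactly. When no point is farther than 0.05 from the
chord the curve is near-linear: the selection is flagged `weak_elbow` and
the interior rank nearest the chord midpoint is used, so the degenerate
case is visible rather than silently arbitrary.

The random-forest arm wraps the canonical `randomForest` implementation
(1000 trees by default, Gini splits, permutation importance — less biased
than impurity importance) with OOB-error `mtry` tuning over
`{⌊√p/2⌋, ⌊√p⌋, 2⌊√p⌋}`, ties to the smaller value.

### Evaluation architecture

* `repeated_split_assessment()`: stratified 70/30 splits repeated (200 by
  default); per repeat the model is tuned on the 70% and its
  *cross-validated* AUC recorded (resubstitution AUC is available but
  over-optimistic by construction); the summary reports the mean, a 95%
  t-interval, and the quantile position of the first split within the
  distribution.
* `final_holdout_test()`: one stratified split; the entire selection
  procedure (component count, VIP ranking, elbow) runs on the training
  portion only — structurally, selection receives only the training rows,
  which a sentinel test verifies by corrupting held-out labels.
* `mccv_validate()`: balanced-subsample Monte-Carlo CV; per iteration a
  2/3 portion ranks features by VIP and fits models at increasing panel
  sizes, validated on the held 1/3 — answering whether the full panel is
  needed.
* AUC is the Mann–Whitney statistic (ties count 1/2), identical to
  trapezoidal ROC integration; confusion metrics leave undefined ratios
  as `NA` rather than 0.

### Univariate statistics

Per panel metabolite: group means, RSD over all biological samples,
log2 fold difference (case/control), Shapiro–Wilk-gated two-sample test
(Welch if both groups pass at α = 0.05, else Wilcoxon rank-sum — the
standard nonparametric companion; the gate requires *both* groups
normal), BH-FDR across the panel (per matrix, since plasma and CSF tables
are separate), and a stratified-bootstrap AUC with percentile 95% CI (500
resamples).

### Pathway enrichment

Over-representation is the exact hypergeometric upper tail
`P(X ≥ k)` with BH-FDR across pathways; the universe defaults to
annotated (non-"unknown") features surviving preprocessing, configurable
to all features — both readings of a mapped-compound universe are
exposed. Pathway impact is the share of summed Brandes betweenness
centrality carried by the hit nodes of the pathway's member graph
(relative betweenness; the normalization constant cancels). Edgeless or
all-leaf cases yield impact 0 with a warning. The shipped pathway
fixtures are small synthetic stand-ins (named as such) for licensed
reference databases.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; `run_pipeline()` fans
a single top-level seed out as `seed · 100 + stage index`, so changing a
later stage's seed leaves earlier stages untouched, and identical
configurations are bit-identical.

The test-suite and acceptance-script simulations use deliberately chosen
problem sizes: plasma-scale parameter recovery runs 10 paired
planted/null cohorts at 156 × 334 with 200-tree forests and 10 × 3 CV
inside the splits; imputation benchmarks use 100 × 50 rank-3 matrices
over 20 seeds; outlier operating characteristics use 50 seeds at 80 × 80.
These sizes give stable pass/fail behavior for the properties being
demonstrated; the pipeline defaults (10 × 10 CV, 200 repeats, 1000
trees) remain the study-scale configuration.

## Known limitations

* Feature independence in the generator understates the difficulty of
  panel selection on real, strongly correlated metabolite data.
* Covariate corrections on the full cohort leak a small amount of
  information into the held-out test, as in the emulated workflow.
* The elbow criterion is deterministic but still a heuristic; near-linear
  VIP curves are flagged rather than resolved.
* CCMN's component count (90% residual variance) is a pragmatic default;
  with very few standards it can retain design-orthogonal noise.
* Chromatographic peak-shape filtering, annotation, and raw-spectra
  processing are out of scope: the pipeline starts at a peak table.
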