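---
title: "Methods: lipidomic signatures of critical illness in lipidcrit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipidomic signatures of critical illness in lipidcrit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`lipidcrit` analyses longitudinal plasma lipid panels from critically ill
cohorts. Its core quantity is the **Lipid Reprogramming Score (LRS)**: the
arithmetic mean z-score of a small panel of phosphatidylethanolamine (PE)
species that rise selectively in patients who remain critically ill. The
package covers the full path from raw concentration matrices to the score
and its clinical evaluation:

1. preprocessing (missingness filter, minimum imputation, class and
   fatty-acid summaries, z-scores, PCA/UMAP embedding);
2. outcome-stratified differential analysis (covariate-adjusted logistic
   screen; two-group Wilcoxon screen);
3. LRS construction (cross-dataset candidate pool, sign-consistency
   screen, support-based candidate sets, sensitivity selection) and
   application (scoring, tertile categories);
4. constraint-based causal discovery over mixed clinical/biomarker
   variables with cross-validated significance-level selection;
5. correlation networks, Kaplan-Meier ICU recovery analysis and
   prognostic model comparison.

All stages are exercised against synthetic cohorts with planted ground
truth, so every claim a test makes is about machinery the package itself
can verify.

# Preprocessing choices

**Missingness.** Species with *strictly more than* 20% missing cells are
discarded (`filter_missing`), reading "over 20%" literally: a species
with exactly 20% missing survives. Remaining missing cells are imputed
with the per-species minimum of the observed values — lipid panels
censor at the detection limit, so the minimum is the natural stand-in.

**z-scores.** Standardisation uses the *sample* (n−1) standard deviation,
and the reference statistics (mean, sd, reference sample set) are stored
in the `zmatrix` so external samples can be scored on the identical
scale. By default the reference is all samples; whether patient-only or
per-timepoint references are preferable is data-dependent, so the
reference set is an explicit argument.

**Fatty-acid composition.** The weighting of a species' concentration
across its acyl chains is not standardised in the field; `lipidcrit`
uses equal-chain weighting (each chain of a k-chain species carries
1/k of the concentration). Chains with zero double bonds count as
saturated (SFA), the rest as unsaturated (USFA); the two masses
decompose the class total exactly.

**Nomenclature.** `parse_lipid_name` accepts `CLASS(c:d_c:d…)` with
whitespace, `/` separators and sphingoid-base prefixes (`d18:1`), and
canonicalises by sorting chains — the notation lists side chains without
positional assignment, so order carries no information. The summed TAG
dialect (`TAG52:3`) is accepted read-only and matched across datasets by
class plus total carbons:double-bonds.

**Embedding.** Dimension reduction is PCA on z-scores followed by UMAP of
the first 20 component scores (`uwot`, single-threaded SGD under a fixed
seed for determinism). The embedding is for reporting only; no decision
in the pipeline consumes it.

# The synthetic world

`generate_trauma_cohort` emulates the statistical structure of a
plasma-randomised severe-trauma cohort:

* group sizes default to the study design it mirrors (41 resolving, 101
  non-resolving, 51 early non-survivors, 17 healthy controls; roughly
  half of each patient group in the prehospital-plasma arm);
* a 996-species panel with the published class representation (TAG 518,
  PE 128, PC 121, DAG 58, the remainder over ten further classes);
* log-normal concentrations with multiplicative effects: a global 0 h
  drop to 0.6 of the healthy mean (0.3 in early non-survivors — the
  deepest drop), attenuated in the plasma arm
  (`tp_attenuation = 0.5` restores half of the drop), persistent
  suppression at 24 h (0.55) and 72 h (0.5) in **both** surviving
  groups, and a *selective* ×1.8 rise at 72 h in non-resolvers confined
  to a planted subset (the five canonical PE species plus 27 TAG, 6 DAG
  and 4 CER), with three LPC species moving down;
* the planted up-subset shares a per-sample latent factor giving
  within-block correlation ρ = 0.8;
* measurement noise CV 0.35 (log-normal), 2% random missingness;
* three signed mediator subsets (pro-inflammatory positively coupled to
  outcome severity; type-2/3 and reparative mediators negatively),
  endotheliopathy markers, adiponectin, and clinical covariates (age,
  sex, ISS, TBI, TRISS, INR, site, BMI) with outcome-dependent
  distributions.

Numbers the mirrored study states (drop multipliers, rise ×1.8, ρ, group
sizes) are taken as given; the remaining levels (noise CV, suppression
depths, attenuation, missingness) were chosen once as plausible for
targeted plasma lipidomics and are configuration, not claims. An early
draft additionally gave non-resolvers a globally higher 72 h level;
that contradicts the selective-elevation pattern the generator is meant
to emulate and was corrected — with equal suppression the higher
non-resolver total lipid at 72 h still emerges from the planted subset.

The generator does **not** emulate: between-subject longitudinal
correlation (samples are conditionally independent given group and
time), batch effects, platform-specific censoring, or real concentration
scales. A green pipeline test therefore establishes that the machinery
recovers planted structure of realistic effect size and correlation
shape — not that it would behave identically on any real cohort.

`generate_covid_cohort` produces a severity cohort on a 29-species
cross-platform panel (the eight shared PE candidates plus 21 other
species), with the five core PE elevated ×1.8 in severe patients, CRP
rising and lymphocyte count falling with severity.
`generate_sem` provides linear-Gaussian/logistic structural equation
fixtures with known DAGs for the causal module.

# Differential screens

`diff_logistic` fits, per species, a logistic regression of the
outcome contrast on the species z-score with age, ISS and treatment arm
as covariates, collects the Wald p-value of the species term, adjusts by
Benjamini-Hochberg *within the analysis*, and passes species with
adjusted p < 0.01 and |log2 fold change| > 0.4. The fold change is the
log2 ratio of arithmetic group means of concentrations — base 2 because
the companion Wilcoxon rule is stated in log2 units. Whether the screen
should regress on z-scores or raw concentrations is not determined by
its source; z-scores are the default and the regressor is configurable.
Perfectly separated species are flagged (`p = NA`) and excluded from the
pass list rather than reported with a meaningless p-value.

`diff_wilcoxon` uses the exact rank-sum distribution for group sizes up
to 10 without ties and the tie-corrected normal approximation otherwise;
its pass rule is one-directional (raw p < 0.05 **and** log2FC > 0.4,
"higher" in the second group), matching the figure-legend convention it
reproduces. All-tied species get p = 1.

# LRS construction

The construction mirrors a three-point design:

1. **Candidate pool** — PE species present in every dataset
   (`common_lipids`, canonical-label intersection).
2. **Sign-consistency screen** — each pool member must correlate
   positively with every up-regulated differential lipid and negatively
   with every down-regulated one (`screen_candidates`). Correlations are
   computed over the *contrast samples* of the differential screen
   (72 h patients): across the full longitudinal sample set the shared
   time-course drives all species positive and the screen would be
   vacuous or erratic. The correlation-magnitude threshold defaults to
   0 (sign only) and is configurable.
3. **Sensitivity selection** — candidate sets are formed by
   cross-dataset support (elevated in ≥ s of the D datasets, s = D…1,
   the same logic that produces 8-, 5- and 1-species sets from four
   datasets). Each set is scored as the mean z of its members; trauma
   datasets contribute a mixed-effects proportional-hazards recovery
   effect (frailty on site), severity datasets a logistic odds ratio.
   Scores are standardised within dataset before fitting: panels of
   different sizes have different mean-z variances, and per-unit effects
   would otherwise mechanically favour the smaller-variance score.
   Within each dataset sets are ranked by the signed log effect in the
   adverse direction; average ranks decide, ties toward the smaller
   panel (parsimony).

`compute_lrs` is the arithmetic mean of panel z-scores; raw input is
z-scored with the model's stored reference statistics. Tertile
cutpoints (`lrs_categories`) are type-7 quantiles of a declared
reference population — patients alive at 72 h — with Low ≤ lower
cutpoint < Medium ≤ upper cutpoint < High.

# Causal discovery

`learn_pag` is a desk-scale hybrid of PC and FCI: the order-independent
(stable) PC adjacency search with recorded separation sets, collider
orientation, then FCI rules R1–R4 to a fixpoint, leaving unresolved
endpoints as circles (`o`). The possible-d-sep stage of full FCI is
omitted by default; `possible_dsep = TRUE` adds an exhaustive removal
pass suitable for ≤ 10 nodes. Conditioning-set size is capped at 3 by
default for tractability.

The mixed-data conditional-independence test dispatches on types:

* continuous–continuous: classical partial-correlation Fisher-z test;
* continuous–categorical: nested linear-model deviance test with the
  continuous variable as response (computed analytically from
  conditional covariances, `χ² = n·log(RSS₀/RSS₁)`);
* binary–binary: logistic-regression deviance test.

Multi-level categorical variables are supported as dummy-encoded
conditioning variables only; a test between two multi-level variables is
a documented limitation. With too few rows for a conditioning set the
pair is conservatively declared dependent and logged.

`select_alpha` implements nested leave-one-out cross-validation over the
grid {0.01, 0.05, 0.1, 0.15, 0.2, 0.25}: per left-out row and per α, a
PAG is learned on the remaining rows, the Markov blanket of the target
(possible parents/children — circle endpoints read inclusively — plus
spouses) feeds a logistic model, and the held-out row is predicted.
The α with the best ROC AUC wins; ties go to the smallest α (sparser
graphs). Empty blankets fall back to intercept-only predictions.

# Recovery and association analyses

`recovery_km` estimates time-to-ICU-discharge curves with the cohort's
censoring conventions: early deaths (≤ day 3) are excluded; later deaths
can never recover and are censored at the dataset-maximum observed ICU
stay (a global maximum; a per-group variant would change at-risk sets
and is intentionally not the default); stays beyond 30 days are censored
at day 30. Treating late deaths as *events* at the maximum stay would
count them as recoveries and force the curve to 0 — censoring is the
reading consistent with "cannot recover". Pairwise log-rank p-values are
reported alongside, as a labelled extra rather than part of the curve
estimate.

`correlation_network` keeps, per class, the most variable species by a
variance-stabilised rank — the residual of log10 variance from a loess
mean–variance trend (span 0.5, fitted globally; linear fallback below
10 species) — with per-class retention counts defaulting to
TAG 100 / DAG 30 / PE 40 / PC 40 and all species of smaller classes.
Edges are Pearson correlations with |r| ≥ 0.7 over all samples.

`fit_outcome_models` wraps three model families behind one tidy-table
interface: plain logistic (odds ratios), logistic with hand-rolled
cluster-robust sandwich standard errors (an independence-working GEE;
no GEE package is assumed available), and proportional hazards for
recovery with a gamma frailty on site (hazard ratios).

# Prognostic evaluation

`cv_evaluate` runs stratified k-fold (default 10) logistic models per
feature set, pools out-of-fold probabilities and reports ROC AUC via the
Mann–Whitney identity (exact on small n), Brier score, and a decile
calibration table. Folds that would lose an outcome class are redrawn
with a shifted seed and the redraw count reported.

`two_step_select` is the LASSO→SVM feature-ranking procedure: per
repeat and outer fold, `cv.glmnet` (binomial, classification-accuracy
tuning on the inner folds) selects features; an RBF-kernel maximum-margin
classifier retrains on them and is scored on the outer fold; selections
from models with accuracy > 0.8 are tallied into a frequency ranking.
The inner accuracy cutoff is the 0.5 probability threshold. The SVM is
the standard soft-margin C-SVM dual solved exactly with
`quadprog::solve.QP` (no SVM library is available in the target
environment); the RBF width defaults to the median-distance heuristic.

# Numerical conventions and degenerate inputs

* Tertiles and calibration bins use type-7 quantiles.
* BH adjustment via `p.adjust`; verified in the tests against a
  brute-force reimplementation.
* Zero-variance species make `zscore` fail loudly (listing species)
  rather than silently dropping columns.
* All-tied Wilcoxon columns give p = 1; identical groups never pass.
* α-selection ties go to the smaller α; candidate-set ties to the
  smaller panel; both choices prefer sparsity.
* Every generator is a pure function of its config and seed; identical
  seeds give byte-identical output.

# Known limitations

* The causal module omits the possible-d-sep stage by default and caps
  conditioning sets, so very dense graphs with latent confounding can
  keep extra edges; the oracle-mode tests bound what the search itself
  can do.
* The mixed CI test family is a documented stand-in for an unspecified
  mixed-graphical-model test; it is validated on synthetic SEMs, not
  proven equivalent.
* The synthetic cohorts are conditionally independent across timepoints
  and contain no batch structure; pipeline recovery rates measured on
  them are upper bounds for messy real data.
* Printed headline effect estimates from the mirrored study (hazard
  ratios, AUCs on patient data) require the original cohorts and are
  deliberately out of scope; the package reproduces procedures, not
  those numbers.
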