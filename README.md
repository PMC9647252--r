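# lipidcrit

Analysis of longitudinal plasma lipidomics in acute critical illness:
preprocessing of targeted lipid panels, outcome-stratified differential
analysis, construction and application of a composite **Lipid
Reprogramming Score (LRS)**, mixed-data causal graph discovery,
Kaplan–Meier ICU recovery analysis, and prognostic model comparison —
all exercisable end-to-end on synthetic cohorts with planted ground
truth.

## The problem

Severe trauma (and other causes of critical illness, including severe
COVID-19) produces a fast, global drop in circulating lipids at
admission — deepest in patients who die early — followed in patients who
remain critically ill by a *selective* rise of phosphatidylethanolamines
(PE), triacylglycerols, diacylglycerols and ceramides at 72 h. The LRS
captures this reprogramming in one number:

```
LRS(sample) = mean over the PE panel of z_i,   z_i = (x_i − μ_i) / σ_i
```

where μ_i, σ_i are per-species reference statistics stored with the
model, and the panel is selected by a three-step procedure: (1) PE
species detectable across all datasets form the candidate pool; (2) a
sign-consistency screen keeps members correlating positively with every
up-regulated differential lipid (covariate-adjusted logistic screen,
BH-adjusted p < 0.01, |log2FC| > 0.4) and negatively with every
down-regulated one; (3) candidate sets built by cross-dataset support
are compared by their standardized recovery hazard ratio (Cox with site
frailty) and severity odds ratio, ranked within dataset and averaged,
ties to the smaller panel. Scores are categorised Low / Medium / High by
type-7 tertiles of patients alive at 72 h.

The causal module learns a partial ancestral graph over mixed
clinical/biomarker variables (PC-stable skeleton, collider orientation,
FCI rules R1–R4), selects the conditional-independence significance
level by nested leave-one-out cross-validation of a Markov-blanket
logistic predictor over α ∈ {0.01, 0.05, 0.1, 0.15, 0.2, 0.25}.

## Worked example

```r
library(lipidcrit)

tr <- generate_trauma_cohort(trauma_config(), seed = 1)
cv <- generate_covid_cohort(covid_config(), seed = 1)

model <- build_lrs(list(matrix = tr$matrix, cohort = tr$cohort),
                   list(list(matrix = cv$matrix, cohort = cv$cohort,
                             kind = "severity")))
model$panel
#> [1] "PE(16:0_18:2)" "PE(16:0_20:4)" "PE(16:0_22:6)" "PE(18:0_18:1)"
#> [5] "PE(18:0_22:6)"
```

The pipeline recovers exactly the five planted PE species. Scoring the
training cohort and testing the association with recovery:

```r
pp <- preprocess_lipidomics(tr$matrix)
cc <- tr$cohort[match(pp$imputed$sample_ids, tr$cohort$sample_id), ]
cc$lrs <- compute_lrs(model, pp$z, min_present = 1)
d72 <- cc[cc$timepoint == "72h", ]
mean(d72$lrs[d72$outcome == "resolving"])      #> -0.514
mean(d72$lrs[d72$outcome == "non_resolving"])  #>  0.873

d72$lrs_std <- scale(d72$lrs)[, 1]
fit_outcome_models(d72, outcome = NULL,
                   covariates = c("lrs_std", "age", "iss", "tbi", "arm"),
                   kind = "cox_mixed")
#> recovery HR per LRS SD: 0.62 [0.50-0.76], p = 4.3e-06
```

A higher score means a lower probability of leaving the ICU (HR < 1),
independent of age, injury severity, TBI and treatment arm. Adding the
LRS to a reference prognostic model improves discrimination and
calibration on this cohort:

```r
d72$y <- as.integer(d72$outcome == "non_resolving")
d72$il6 <- log2(d72$IL6)
rep_ <- cv_evaluate(d72, list(ref = c("iss", "il6"),
                              with_lrs = c("iss", "il6", "lrs")),
                    "y", k = 10, seed = 1)
rep_$ref$auc       #> 0.823   rep_$ref$brier      #> 0.150
rep_$with_lrs$auc  #> 0.956   rep_$with_lrs$brier #> 0.077
```

(All numbers above are what the code prints for these seeds; being
synthetic-cohort quantities they measure the machinery, not any
patient population.)

## Command line

```sh
Rscript -e 'lipidcrit::lipidcrit_cli()' simulate trauma --config cfg.yaml --seed 3 --out sim/
Rscript -e 'lipidcrit::lipidcrit_cli()' preprocess --matrix sim/matrix.tsv \
    --cohort sim/cohort.tsv --max-missing 0.2 --out pp/
Rscript -e 'lipidcrit::lipidcrit_cli()' diff --matrix sim/matrix.tsv \
    --cohort sim/cohort.tsv --rule logistic --out diff.tsv
```

Further subcommands: `lrs build` / `lrs score`, `causal`,
`assoc network` / `assoc recovery`, `prognostic`.

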