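# gutnk

Composite gut-dysbiosis and NK-cell-exhaustion scoring for cervical cancer
cohorts, with the downstream association and survival analyses that link the
two. The package is aimed at researchers who have (a) a genus-level 16S count
table with a genus→phylum map, (b) a flow-cytometry panel of percent-positive
immune-checkpoint markers (PD-1, LAG-3, BTLA, TIM-3, TIGIT, NKG2A) on the
CD56<sup>dim</sup> and CD56<sup>bright</sup> NK subsets, and (c) subject
metadata with group labels (healthy donors, pre-treatment and
post-radio-chemotherapy patients) and censored survival times. A seeded
synthetic cohort generator reproduces the statistical structure of such a
study, so the entire pipeline runs and is tested without any data download.

## The method

**Composite scores.** For each feature *x* (a checkpoint percent-positive, an
α-diversity metric, or a CLR-transformed genus abundance), a Z-score is taken
against the healthy-donor (HD) reference, *z* = (*x* − μ<sub>HD</sub>) /
σ<sub>HD</sub>, then classified into an ordinal bin 1/2/3 by empirical
percentile cuts of the reference (defaults 66.7 and 90). Checkpoint bins are
one-sided (higher expression = worse) and are summed over the six markers per
NK subset, giving subset scores S<sub>dim</sub>, S<sub>bright</sub> ∈ [6, 18];
the **global NK exhaustion score** is their mean G = (S<sub>dim</sub> +
S<sub>bright</sub>) / 2. The **dysbiosis score** sums two-sided bins (departure
in either direction from the HD configuration counts) over four α-diversity
metrics (Shannon, Pielou, Simpson, Strong) and the CLR abundances of the taxa
panel expanded or depleted in disease (Prevotella, Escherichia-Shigella,
Ruminococcus, Christensenellaceae R-7), so it ranges over [k, 3k] for k scored
features.

**Compositional layer.** CLR transform per sample, clr<sub>i</sub> =
ln(x<sub>i</sub>) − mean<sub>j</sub> ln(x<sub>j</sub>) after a 0.5
pseudocount, plus the five-ratio panel
(Proteobacteria/Firmicutes, Bacteroidota/Firmicutes,
Escherichia/Ruminococcus, Prevotella/Ruminococcus,
Escherichia/Erysipelotrichaceae UCG-003) computed as CLR differences —
phylum-level ratios on the phylum-aggregated composition.

**Association.** Spearman correlation between the dysbiosis and exhaustion
scores; two fixed-coefficient logistic risk equations shipped as immutable
fixtures (`cc_risk_model()`: logit *P* = −3.3919 + 0.5938·PD-1<sub>bright</sub>
+ 2.6358·Escherichia/Ruminococcus; `mortality_risk_model()`: logit *P* =
−105.640 + 0.208·TIGIT⁺TIM-3⁺<sub>bright</sub> + 1.058·CD56<sup>dim</sup>),
odds ratios as exp(β), plus maximum-likelihood refits, rank-based ROC-AUC and
the Youden-optimal cutoff.

**Survival.** Subjects are stratified high/low at the Youden cutoff of a
marker against survival status, then compared by Kaplan–Meier curves and the
log-rank test over a 15-month horizon, with the hazard ratio reported as the
observed/expected ratio (default) or the Mantel–Haenszel estimate, and
concordant high/high vs low/low joint strata for two-marker analyses.

## Worked example

```r
library(gutnk)
library(dplyr)

cohort <- cohort_config(seed = 42) |>
  generate_cohort() |>
  apply_loss_to_followup(n_lost = 4, seed = 43)
#> <gutnk_cohort> 77 subjects (HD=28, CC_pre=27, CC_post=22), 20 genera

scores <- score_cohort(cohort) |>
  left_join(ratio_panel(cohort$taxa, cohort$taxonomy), by = "subject_id")

scores |>
  group_by(group) |>
  summarise(exhaustion = mean(exhaustion_global),
            dysbiosis = mean(dysbiosis_score),
            esch_rum = median(escherichia_ruminococcus))
#>   group   exhaustion dysbiosis esch_rum
#> 1 HD            8.57      11.4   -1.59
#> 2 CC_pre       10.5       17.8    0.852
#> 3 CC_post      12.3       17.3    3.15
```

Exhaustion and dysbiosis scores rise from healthy donors through pre- to
post-treatment patients, and the Escherichia/Ruminococcus log-ratio flips
sign, as the planted group effects dictate. The two composite scores
correlate:

```r
spearman_correlation(scores$dysbiosis_score, scores$exhaustion_global)
#>     rho     p_value     n
#> 1 0.538 0.000000446    77
```

The printed cancer-risk equation evaluates to a probability for any subject,
and its coefficients exponentiate to the published odds ratios:

```r
tidy(cc_risk_model())
#>   term                     estimate odds_ratio
#> 1 (Intercept)                -3.39      0.0336
#> 2 pd1_cd56bright              0.594     1.81
#> 3 escherichia_ruminococcus    2.64     14.0
```

Survival among the 23 evaluable pre-treatment patients, stratified at the
Youden cutoff of the exhaustion score:

```r
pre   <- filter(scores, group == "CC_pre", !lost_to_followup)
strat <- stratify_by_cutoff(pre, exhaustion_global, event)
glance(logrank_test(strat))
#>   chi_square p_value hazard_ratio hr_lower hr_upper hr_method     n events
#> 1       3.85  0.0496         6.04     1.78     20.4 oe           23     11

median_survival(km_estimate(strat))
#>   stratum median_months
#> 1 high             6.39
#> 2 low             NA
```

High-exhaustion patients die faster (median 6.4 months; the low stratum never
reaches median mortality inside the horizon). `autoplot(km_estimate(strat))`
draws the curves; `run_pipeline(run_config(outdir))` chains simulate → score →
associate → survive into one reproducible run writing `scores.tsv`,
`assoc.json`, `survival.json` and a provenance log.

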