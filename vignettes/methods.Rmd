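---
title: "Composite dysbiosis and NK-exhaustion scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite dysbiosis and NK-exhaustion scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutnk)
```

## The scoring model

The package quantifies two departures from a healthy-donor (HD) baseline —
gut microbiota dysbiosis and NK-cell checkpoint exhaustion — on a common
ordinal scale, then asks whether they travel together and whether either
predicts survival.

Every feature is first standardized against the HD distribution:
$z = (x - \mu_{HD})/\sigma_{HD}$, with $\mu_{HD}$, $\sigma_{HD}$ the mean and
sample SD (denominator $n-1$) of the HD subjects. Features with zero HD
variance are rejected outright rather than floored: a degenerate SD cannot
anchor a Z-score, and silently substituting a floor would let an
uninformative feature contribute arbitrary bins.

The Z-score is then classified into a bin $\in \{1,2,3\}$ by empirical
percentile cuts of the reference (defaults 66.7 and 90, i.e. the top tercile
of HD values earns 2 and the top decile 3). Two binning modes exist:

* **one-sided** (checkpoints): $z$ is compared to the reference Z-values at
  the cut percentiles — only elevation scores. Because standardization is
  monotone, this is equivalent to comparing the raw value to raw reference
  percentiles.
* **two-sided** (dysbiosis features): $|z|$ is compared to percentiles of the
  reference $|z|$ distribution, so depletion and expansion are penalized
  symmetrically. A community can be dysbiotic by losing a commensal just as
  much as by gaining a pathobiont, which is why the dysbiosis composite uses
  this mode.

Checkpoint bins are summed over the six inhibitory receptors (PD-1, LAG-3,
BTLA, TIM-3, TIGIT, NKG2A) per NK subset, giving subset scores in $[6, 18]$,
and the global exhaustion score is the mean of the CD56^dim^ and CD56^bright^
subset scores — the two subsets are weighted equally because they represent
distinct functional compartments (cytotoxic vs cytokine-producing), not
replicate measurements. The dysbiosis score sums two-sided bins over four
α-diversity metrics (Shannon, Pielou, Simpson, Strong) and the CLR abundances
of a configurable taxa panel (default: Prevotella, Escherichia-Shigella,
Ruminococcus, Christensenellaceae R-7 — the consistently expanded/depleted
genera), giving a range $[k, 3k]$ for $k$ scored features ($k = 8$ by
default).

One consequence of in-sample percentile binning worth knowing: the HD group's
own mean score is (ties aside) a deterministic function of the reference size
and the cuts, because ranking reference subjects against their own empirical
percentiles fixes the bin counts. Only the patient groups' scores carry
sampling noise relative to the reference.

### Open choices and how they were fixed

The exact percentile cuts, the dysbiosis aggregation rule, and the sidedness
of the α-diversity features are not uniquely determined by the design this
package implements; all three are exposed as configuration:

* cuts default to 66.7/90 (`bin_rule()`), preserving the 1–3 ordinal design
  with a "top tercile / top decile" reading;
* dysbiosis aggregates by **sum** (mirroring the checkpoint subset sums),
  with a mean-normalized variant behind `aggregate = "mean"` for comparing
  panels of different size;
* α-diversity features are scored **two-sided** like the taxa features. In
  practice disease lowers diversity, so the upper tail is rarely hit, but
  symmetric treatment keeps the composite's definition uniform.

## Diversity and compositional layers

The five α-diversity metrics are computed from one sample's genus counts with
proportions $p_i$, total $N$ and observed richness $S$ (taxa with nonzero
count): Shannon $H=-\sum p_i\log_b p_i$, Simpson $1-\sum p_i^2$, Pielou
$H/\log_b S$ (undefined at $S=1$, signalled as an error), Simpson evenness
$(1/\sum p_i^2)/S$, and Strong dominance $\max_i (b_i/N - i/S)$ with $b_i$
the cumulative count of the $i$ most abundant taxa. The log base defaults to
2, matching the convention of the amplicon diversity toolchain these tables
typically come from; the base cancels after Z-standardization, so it only
matters for reporting raw values. Ties in Strong's ranking are broken
arbitrarily — cumulative sums are invariant to the order of tied counts.

The CLR transform adds a pseudocount (default 0.5) to every cell and maps
each sample to $\mathrm{clr}_i = \ln x_i - \overline{\ln x}$. The geometric
mean is always taken over the **full composition** of the table passed in —
genus table for genus ratios, phylum-aggregated table for phylum ratios —
never over a selected sub-panel, because sub-compositional centering changes
the values; CLR *differences* (the ratio panel) are independent of the
centering and equal $\ln(x_{num}/x_{den})$ exactly. The symmetric additive
pseudocount is the simplest zero-replacement; it is exposed everywhere as
`pseudocount`. Taxon names are matched after whitespace normalization, and
"Escherichia" resolves to an "Escherichia-Shigella" column when present,
since 16S genus tables use both spellings.

## Association and survival

Spearman's ρ uses average ranks; its p-value comes from the exact null
distribution of the rank statistic for $n \le 10$ (tie-free case) and the
t-approximation otherwise — small-sample stability without permutation cost.

The two published logistic equations ship as immutable fixtures with their
coefficients as printed; features enter on their native scales
(percent-positive on 0–100, CLR log-ratio). Odds ratios are $e^\beta$. Refits
use `stats::glm` maximum likelihood with Wald 95% CIs
$\exp(\beta \pm 1.96\,SE)$; complete or quasi-complete separation is detected
(non-convergence, near-zero deviance, or exploding coefficients with huge
SEs) and flagged on the returned model instead of being reported as a
trustworthy fit.

ROC-AUC is the rank-sum (Mann–Whitney) estimator, ties counting ½. The
Youden cutoff scans midpoints between adjacent distinct scores (plus an
open lower extreme), classifies `score > cutoff` as positive, and resolves
ties on $J$ to the smallest cutoff; an anti-informative marker
($\max J \le 0$) is flagged rather than silently stratified.

Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package (`survfit`/`survdiff`); the package adds the two hazard
ratio conventions used in this literature — the observed/expected ratio
("log-rank HR", default) and the Mantel–Haenszel estimate
$\exp((O_1-E_1)/V)$ — with log-scale normal CIs ($SE = \sqrt{1/E_1+1/E_2}$
and $1/\sqrt{V}$ respectively). The HR compares the first stratum level
("high") against the second. Simultaneous events at a time reduce the same
risk set; subjects flagged lost to follow-up are excluded before any
estimation. Median survival uses the $S(t) \le 0.5$ convention and is
reported as missing when the curve never reaches one half. Two-marker
analyses keep only subjects concordant on both high/low stratifications
(high/high vs low/low), which by construction discards about half the sample
for independent markers — the price of the extreme-category contrast.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the structure the analysis assumes,
not a mechanistic gut model. Default group sizes are 28 HD, 27 pre-treatment
and 22 post-treatment subjects (77 total). Per subject:

* a latent **severity** scalar $s \sim N(0,1)$;
* genus counts: latent log abundance = baseline log-mean + group log-fold
  shift $\times (1 + c \cdot s)$ + $N(0, \sigma_g)$ noise, soft-maxed into
  proportions and fed to a multinomial at depth 40,000 (a realistic denoised
  read count per sample). Baseline means target a Firmicutes-dominated
  healthy community (Faecalibacterium ≈ 15%, Bacteroides ≈ 9%,
  Escherichia-Shigella ≈ 0.3%); log-SD 0.8 gives realistic between-subject
  spread. Default shifts enrich Prevotella (+2.49) and Escherichia-Shigella
  and deplete Ruminococcus and Christensenellaceae R-7 in pre-treatment
  disease, with deeper depletion plus strong Phascolarctobacterium enrichment
  post-treatment;
* checkpoint percentages: baseline + group shift + $c \cdot s \times$ 5
  percentage points + Gaussian noise, clamped to $[0,100]$. Within-group
  checkpoint SDs are free parameters (no published values exist); defaults
  of 2.5–12 points are plausible flow-cytometry spreads and sit in
  `default_checkpoint_baseline()`;
* survival: exponential with hazard $0.034 \cdot e^{0.7 s}$ per month
  (≈ one-third cumulative mortality at the horizon for an average subject),
  administratively censored at 15 months;
* the coupling strength $c$ (`latent_coupling`, default 0.6) is the single
  knob tying dysbiosis, exhaustion and survival together.

The generator reproduces: group effect directions on taxa and checkpoints, a
positive dysbiosis–exhaustion rank correlation, severity-linked mortality,
and horizon censoring. It does **not** emulate: read-level noise or
compositional artefacts of bioinformatic pipelines, inter-taxon correlation
beyond the shared severity factor, covariates (age, BMI, stage, HPV), or
longitudinal pairing between pre- and post-treatment groups (they are
independent cross-sections). Passing tests therefore demonstrate that the
pipeline recovers planted structure of this simple form — not that any real
cohort satisfies the model.

A note on the spec of group sizes: any group may be empty (e.g. a two-group
design) as long as the cohort is nonempty and at least two HD subjects exist
whenever a score is computed against the HD reference.

## Numerical conventions

* Percentiles: `stats::quantile` type 7 (linear interpolation); reference
  ties average ranks implicitly through the sorted-value interpolation.
* Bin boundaries: a value exactly at a threshold takes the lower bin
  (`z > q` moves up).
* CLR closure is exact up to floating error; tests assert row sums below
  1e-9 and oracle agreement at 1e-12.
* All randomness flows through explicit integer seeds (`cohort_config(seed=)`,
  `apply_loss_to_followup(seed=)`); a config plus seed reproduces every table
  bitwise.

## Problem sizes used by the test-suite

The suite verifies oracle equivalence on 100+ random small instances per
operation (vectors of ≤ 12 taxa, survival sets of ≤ 15 records), parameter
recovery at n = 5,000 (logistic), 1,000/group (hazard ratio 3 under horizon
censoring) and 500/500 (planted rank correlation, Monte-Carlo reference
0.531 established over 50 replicate cohorts), and group-separation
properties at 100/group — sizes chosen to keep the whole suite under half a
minute while leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The dysbiosis composite depends on the configured taxa panel; it is a
  scoring convention, not an inferred biomarker set (no differential
  abundance testing is performed here).
* The O/E hazard ratio is biased toward the null under heavy follow-up with
  large true effects; the Mantel–Haenszel variant is offered, and neither is
  a substitute for a proportional-hazards model, which is out of scope.
* Percentile bins from small HD references (n < ~30) are coarse; cut
  percentiles between reference order statistics are interpolated, and users
  with small reference groups should treat bin-boundary subjects with care.
* The printed-equation fixtures assume raw percent (0–100) predictor scales;
  rescaled inputs require refitting, not coefficient reuse.
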