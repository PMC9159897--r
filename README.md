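# rehabspc

Change detection and outcome prediction for repeated cognitive
measurements in rehabilitation.

Early after an acquired brain injury, the effect of attention training is
judged patient by patient from a short series of repeated attention-test
scores (a PASAT-type serial-addition test: the score is the count of
correct responses, higher is better, administered before training, after
every third hour of treatment, and at completion). `rehabspc` implements
the two stages of that analysis:

1. **SPC change detection.** One individuals (I) control chart per
   patient with a frozen two-observation baseline: centreline
   $CL_i = (y_{i1}+y_{i2})/2$, sigma pooled over the cohort's baseline
   pairs, $\hat\sigma = \sqrt{\frac{1}{m}\sum_i (y_{i1}-y_{i2})^2/2}$,
   control limits $CL \pm 3\hat\sigma$ and warning limits
   $CL \pm 2\hat\sigma$. Two run rules scan the post-baseline sessions —
   one point outside 3 sigma, or 2 of 3 consecutive points at or beyond
   the same 2-sigma line — and each patient is dichotomized as **CHANGE**
   (at least one improvement signal) or **NO_CHANGE**.
2. **Predictor association.** The dichotomous outcome is crossed with
   treatment arm and clinical covariates: Pearson chi-square (no
   continuity correction) with Cramér's V, Fisher's exact test, odds
   ratios with Woolf 95% intervals, one-way ANOVA with
   $\eta^2 = SS_{between}/SS_{total}$, Pearson-correlation screening, a
   linear-probability (OLS) regression of the 0/1 outcome, and the
   linear-by-linear trend statistic $(N-1)r^2$ for ordered tables.

A synthetic cohort generator (additive model: patient baseline + early
learning drift + latent-responder step + Gaussian noise, rounded and
clipped to the score range) makes the whole pipeline testable without any
patient data, and `operating_characteristics()` estimates the detection
power and false-alarm rate of the rule set by simulation. The package is
aimed at rehabilitation researchers and methodologists working with
single-case-style repeated measurements inside group designs.

## Worked example

```r
library(rehabspc)
library(dplyr)

# a 59-patient cohort under the default study conditions
coh <- simulate_cohort(sim_config(), seed = 2026)
out <- spc_classify(coh$series, coh$covariates)
count(out, arm, label)
#>   arm   label         n
#> 1 ABAT  CHANGE       16
#> 2 ABAT  NO_CHANGE     6
#> 3 APT   CHANGE       32
#> 4 APT   NO_CHANGE     5

associate(out, predictors = c("arm", "diagnosis", "cr_class")) %>%
  select(term, test, statistic, p_value, effect_size, effect_label)
#> Association screen: 6 tests (no multiplicity adjustment)
#>   term      test         statistic p_value effect_size effect_label
#> 1 arm       chi_square       1.72   0.189       0.171  weak
#> 2 arm       fisher_exact    NA      0.300       0.171  weak
#> 3 diagnosis chi_square       0.230  0.631       0.0625 weak
#> 4 diagnosis fisher_exact    NA      1           0.0625 weak
#> 5 cr_class  chi_square       2.93   0.0872      0.223  moderate
#> 6 cr_class  fisher_exact    NA      0.146       0.223  moderate
```

At this sample size a single simulated cohort often fails to reach
significance on the arm-by-outcome table — the small-sample reality the
effect-size columns are there for. The packaged reference tables (counts
transcribed from a published attention-training trial) show the suite at
desk scale:

```r
table_association(attention_trial_tables()$treatment_outcome) %>%
  select(statistic, p_value, fisher_p, cramers_v, odds_ratio, reciprocal)
#>   statistic p_value fisher_p cramers_v odds_ratio reciprocal
#> 1      5.93  0.0149   0.0214     0.317      0.231       4.32
```

Read: the treatment-by-outcome table gives chi-square 5.93 (p = 0.015),
Fisher p = 0.021, a moderate effect size V = 0.317, and odds of NO CHANGE
under APT 0.231 times those under ABAT — equivalently, odds of CHANGE 4.3
times higher with systematic attention-process training.

Per-patient charts: `autoplot(spc_fit(coh$series), patients = ...)` draws
the centreline, warning and control limits with signalling points
flagged. The false-alarm behaviour of the chart design itself is
available in closed form via `signal_probability()`.

A thin command-line wrapper exposes the stages as
`rehabspc simulate|detect|associate` (see `inst/cli/rehabspc`), writing
CSV outputs, a text report and a run log with seed and configuration
hash.

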