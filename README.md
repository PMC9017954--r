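# resilmark

Mobile-sensing indicators of stress-resilience: construction, screening,
and prediction.

## The problem

People entering a prolonged high-stress period — the motivating setting is
the medical internship, the first year of residency — differ in how their
depression symptoms (PHQ-9, 0–27) evolve. The subgroup whose symptom
trajectory stays flat is the *stress-resilient* population; finding
unobtrusive, passively sensed markers of that resilience would allow
early, low-stigma risk assessment. `resilmark` implements the full
analysis chain for this question from wearable and EMA data:

1. **Cleaning** of hourly streams (steps, seconds asleep, seconds in bed,
   mean heart rate) and daily 1–10 mood EMAs: local mood interpolation
   over the waking day, zero-filling of non-random step/sleep
   missingness, dropping of incomplete hours, isolation-forest outlier
   filtering (250 trees), and participant eligibility (≥100 cleaned hours
   per period).
2. **Indicators.** With a participant's baseline distribution $A$ and
   internship distribution $B$ over the $m = 5$ hourly features, the
   package computes per feature $j$: $\bar X_{A_j}, SD_{A_j},
   \mathrm{Skew}_{A_j}$ (Pearson skew $3(\bar x - \tilde x)/s$), the same
   for $B_j$, and Cohen's
   $d_{sj} = (\bar X_{B_j} - \bar X_{A_j}) \big/
   \sqrt{\tfrac{(n_A-1)SD_{A_j}^2 + (n_B-1)SD_{B_j}^2}{n_A+n_B-2}}$,
   plus the data counts $n_A, n_B$ — 37 indicators in all.
3. **Trajectory classes.** Quadratic growth mixture models over
   $\Delta$PHQ-9, fitted by EM with a shared random intercept, class count
   selected by AIC/BIC; the minimal-change class is labelled resilient.
4. **Screening.** Univariate logistic GEEs (exchangeable working
   correlation, clustered by medical specialty, controlling sex and age)
   of the resilient label on each standardized indicator; collinearity
   pruning (|Spearman ρ| > 0.7); one joint multivariate GEE.
5. **Prediction.** Multitask conditional GANs (CGAN, F-, P-, FP- variants
   with per-feature and per-participant-cluster output heads), plus MLP
   and direct-generator baselines, learn the baseline→internship mapping;
   predicted indicators from generated internship data are validated by
   skipped (robust) correlation, signed-rank comparison against a
   mean-assignment baseline, and GEE coefficient contrasts.

The raw data of the motivating cohort are not publicly deposited, so the
package includes a first-class synthetic cohort generator
(`simulate_cohort()`) reproducing the statistical structure the analysis
assumes — zero-inflated skewed steps, zero-heavy sleep with multi-hour
booked cycles, truncated-normal heart rate, discrete evening mood EMAs,
four planted trajectory classes, two behaviour-shift clusters, planted
indicator–resilience couplings, and quarter-increasing dropout.

## Worked example

```r
library(resilmark)

cfg <- cohort_config(n_participants = 40, baseline_weeks = 2,
                     weeks_per_quarter = 1, seed = 1234)
cohort <- apply_missingness(simulate_cohort(cfg))
cleaned <- clean_hourly(cohort$hourly, cohort$ema, seed = 1)
indicators <- build_indicator_table(cleaned$records)

fit <- select_class_count(cohort$phq, K_range = 2:3, n_restarts = 5,
                          seed = 2)
print(fit)
labels <- label_resilience(fit)

std <- standardize_indicators(indicators[c("participant_id",
                                           indicator_names())])
aligned <- merge(std, labels, by = "participant_id")
screen <- screen_indicators(
  aligned[indicator_names()], aligned$resilient,
  cohort$covariates[match(aligned$participant_id,
                          cohort$covariates$participant_id), ])
head(screen[order(screen$p), c("indicator", "beta", "p")], 3)
```

Output from this exact script:

```
Quadratic growth mixture model: K = 3 classes, n = 36 series
logLik -314.79 | AIC 655.6 | BIC 676.2 | converged
          pi     g0     g1     g2
class1 0.152 -1.357  2.391  0.353
class2 0.738  0.595 -0.445  0.104
class3 0.110 -3.551 10.186 -1.818
random-intercept var 1.183, residual var 3.653
                  indicator      beta           p
8   sleep_seconds__mean__BL 0.9223543 0.003238679
15 in_bed_seconds__mean__BL 0.9051840 0.005258088
10  sleep_seconds__skew__BL 0.8577182 0.006444853
```

Read: 36 of the 40 simulated participants survive cleaning and
eligibility; at this toy size the criteria settle on three trajectory
classes — the flat 74 % class (class 2) is the resilient label — and the
strongest univariate associations with resilience are sleep-related
indicators (log-odds per SD of indicator), reflecting the generator's
coupling between the sleep-shift cluster and the resilient class. At the
study-scale conditions used by the tests (n = 775) the four planted
classes are recovered. `run_pipeline()` chains all stages, including
generator
training and the predicted-indicator contrast, and writes the nine
artifact files (cleaned parquet, cleaning report, indicators, classes,
mixture fit, univariate/multivariate GEE tables, contrasts, evaluation
report).

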