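---
title: "Methods: identifying and predicting mobile-sensing indicators of stress-resilience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and predicting mobile-sensing indicators of stress-resilience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

People entering a prolonged high-stress period — the motivating setting is
the first year of medical residency — differ in how their depression
symptoms evolve. *Process stress-resilience* is the property of showing
minimal symptom change under that stress. This package implements a full
analysis chain for studying resilience with unobtrusive measurements:
hourly wearable features (step count, seconds asleep, seconds in bed, mean
heart rate) and a daily 1–10 mood EMA, anchored by quarterly PHQ-9
depression scores.

The chain has four scientific stages:

1. **Indicator construction.** Each participant's cleaned hourly data are
   pooled into a pre-stress baseline distribution $A$ and an in-stress
   internship distribution $B$ (quarters Q1–Q4). For each of the $m = 5$
   features $j$ the package computes the mean, sample SD, and Pearson skew
   of both periods, the between-period Cohen's $d_{sj}$, and the two data
   counts $n_A, n_B$ — 5 × 7 + 2 = 37 indicators.
2. **Trajectory classes.** Quarterly $\Delta$PHQ-9 series (change from
   baseline) are modelled with a quadratic growth mixture fitted by EM; the
   class whose fitted curve stays nearest zero is labelled stress-resilient
   and all other classes are pooled as stress-sensitive.
3. **Association screening.** Each standardized indicator is screened
   against the resilient label with a binomial logit GEE clustered by
   medical specialty (controls: sex, age); significant indicators are
   pruned for collinearity and refit jointly.
4. **Prediction.** Conditional GANs (and simpler baselines) learn the
   baseline-to-internship mapping on a training split, generate a predicted
   internship distribution $B'$ for held-out participants, and the
   predicted indicators computed from $(A, B')$ are validated against the
   actual ones — by skipped correlation of $d_s$, by squared error against
   a mean-assignment baseline, and by GEE coefficient contrasts.

Because the motivating study's raw streams are not publicly deposited, the
package ships a synthetic cohort generator that reproduces the statistical
structure the analysis relies on. All tests and the acceptance script run
against that generator.

# Key formulas and conventions

**Pearson skew** of a sample $x$: $3(\bar x - \tilde x)/s$ with $\tilde x$
the mid-rank median and $s$ the sample ($n-1$) SD. **Cohen's $d_s$**
between periods: $(\bar x_B - \bar x_A)$ divided by the pooled SD with
$(n-1)$ weights. Both use the sample-SD convention throughout; the even-$n$
median is the mean of the two central order statistics. Degenerate
(zero-variance) features raise errors naming the feature; the screening
stage drops zero-variance columns with a warning instead.

# The synthetic cohort generator

`cohort_config()` defaults encode the study conditions: 775 participants, a
6-week baseline, four 13-week quarters, a four-class $\Delta$PHQ-9
trajectory mixture with a 68 % minimal-change majority class (residual SD
2, random-intercept SD 1 PHQ points), two behaviour-shift clusters (80/20)
that differ mainly on sleep, in-bed and heart rate, evening EMAs on 85 % of
days, and a 15 % per-quarter dropout hazard. `weeks_per_quarter` scales
cohorts down without dropping any quarter; the test suite and acceptance
script use 1–4 week quarters so a full run fits in minutes, and those
problem sizes are stated where they are used.

Marginal families, chosen for qualitative realism (no marginal parameters
are published for the real streams, so all of this is configurable):

* **Steps** — an hourly activity gate (circadian Bernoulli template,
  suppressed while asleep) times a negative-binomial count; zero-mode and
  right-skewed.
* **Sleep / in-bed** — nightly episodes around a per-participant bedtime,
  split into 1–3 cycles separated by short in-bed-awake gaps, plus
  occasional naps. A cycle that crosses hour boundaries may be booked
  entirely into its start hour with probability 0.15, so single hours can
  carry more than 3600 s, as real device exports do.
* **Heart rate** — truncated normal in [35, 204] BPM around an
  awake/asleep-dependent, participant-specific level.
* **Mood** — a per-day latent normal rounded onto the integer 1–10 scale,
  delivered at a fixed per-participant evening hour (17:00–22:00).

**Shift mechanics.** Cluster mean shifts are expressed in units of the
feature's marginal hourly SD. For heart rate and mood the shift is applied
additively using the participant's own realized SD, so the empirical
$d_s$ recovers the configured multiplier directly (this is the
law-of-large-numbers oracle the tests use). Steps, sleep and in-bed are
zero-heavy, so additive shifts would create impossible values; their shifts
act on the generating process instead (count-rate scaling; nightly duration
±3 h and nap probability ±0.12 per configured unit). For those features the
realized $d_s$ is monotone in the configured multiplier but smaller than
it; analyses that need a known separation measure it empirically.

**Planted couplings.** Trajectory class is drawn first. Shift-cluster
membership then depends on resilience through a configurable log-odds
offset, which couples the cluster-separated features to the resilient
label. Additional per-indicator couplings (`indicator_effects`) plant a
per-participant indicator value $z_i + \beta\,\mathrm{resilient}_i$ with
$z_i \sim N(0,1)$; under this equal-variance normal discriminant
construction a logistic fit of the label on the planted value has true
slope $\beta$, which is what the GEE calibration checks recover. Planted
values for `*__cohens_ds__DIFF` indicators additionally feed the
participant's internship mean shift (0.25 hourly SD per planted unit), so
the coupling also exists in the hourly streams.

# Cleaning rules and their operationalization

The mood interpolation rule fills each EMA day's value from the wake time
ending the previous sleep cycle to the wake time ending the next sleep
cycle longer than two hours, capped at EMA + 24 h. Where the rule does not
define an anchor: filling starts at the day's midnight when no wake anchor
precedes the EMA, and ends at the cap when no qualifying sleep follows. A
"sleep cycle" is a contiguous run of recorded hours with positive sleep; a
run qualifies as longer than two hours when its summed sleep exceeds
7200 s. Uniform(0, 0.2) noise is added per filled hour by default; a
per-EMA-day switch (`noise_per = "ema"`) shares one draw across the day's
hours, since either reading of "noise added to each mood EMA" preserves the
0.5-increment recoverability.

Missing-data rules are applied in the order stated: zero-filling of
step/sleep non-random missingness, then dropping hours without a mood value
in the past 24 h, then dropping hours without heart rate (implemented
jointly as dropping any hour missing one of the five features).

**Outlier filtering** uses an isolation forest with 250 trees and the full
five-feature budget per tree, fitted once on the pooled cohort, flagging
scores above the standard 0.5 threshold (shorter-than-average isolation
paths). The per-tree subsample defaults to 8192 rather than the classic
256: with 256-point trees the depth cap (⌈log₂ψ⌉ = 8) binds before the
dense zero-heavy sleep/step clusters resolve, so ordinary hours land in
tiny leaves and are over-flagged (the reference implementation in
scikit-learn behaves the same way on this data shape). Deeper trees
(ψ = 8192, depth 13) keep the clean-data flag rate in the low single
percentages — the test suite asserts it stays at or below 5 % — while
still flagging every planted extreme. Tree growth runs in R on the subsample; scoring runs
in C++ so million-hour cohorts filter in seconds.

Participant eligibility: ≥ 100 cleaned baseline hours, ≥ 100 cleaned
internship hours, nonzero variance on every feature.

# Trajectory mixture

The mixture has $K$ quadratic mean curves $\gamma_{0k} + \gamma_{1k} t +
\gamma_{2k} t^2$ over the quarter index $t \in \{1..4\}$, a shared random
intercept variance $\tau^2$ and shared residual variance $\sigma^2$ —
the smallest random-effects structure that separates within- from
between-person variance, given that nothing richer is identifiable from
four post-baseline points. The baseline point ($\Delta$PHQ ≡ 0) carries no
information and is excluded from the likelihood. Participants with missing
quarters contribute marginal likelihoods over observed timepoints
(covariance $\sigma^2 I + \tau^2 J$, inverted by the rank-one Woodbury
identity; participants are grouped by missingness pattern so EM is fully
vectorised). Initialisation is k-means on mean-imputed delta vectors with
10 restarts; EM stops at a relative log-likelihood change of 1e-8 or 200
iterations, returning the best restart with a convergence flag.

Model selection fits $K \in \{2..5\}$ and minimises AIC with
$p = 3K + (K-1) + 2$ parameters; when BIC disagrees, BIC's choice wins with
a warning — the stricter criterion is preferred when the two conflict, and
in the motivating study both minimised at the same $K$. The resilient class
minimises $\max_t |\hat\Delta(t)|$ with ties broken toward the largest
mixing proportion.

The default synthetic classes are a flat 68 % class ($\gamma = (0, 0.3,
-0.06)$), an early-peaking recovering class (15 %, $(0, 6, -1.5)$), a
late-rising class (10 %, $(0, 1, 0.5)$) and a high-sustained class (7 %,
$(0, 9, -1.6)$). Peaks are separated by ≥ 4 PHQ points and the shapes are
mutually distant in curve space; with three same-shaped humps instead, the
shared random intercept makes neighbouring humps exchangeable and class
recovery degrades — a useful reminder that "peak separation" alone does not
guarantee identifiability of this model family.

# GEE screening

The GEE is binomial with logit link, an exchangeable working correlation
within specialty clusters (the standard choice when only the grouping is
known), and a moment estimate of the correlation clamped to the
positive-definite range for the largest cluster. Inference uses the
cluster-robust sandwich covariance with a $t_{G-1}$ reference ($G$ =
number of clusters, here 13 specialties): with so few clusters the plain
normal reference is anti-conservative, and the $t_{G-1}$ correction
restores near-nominal behaviour — the calibration tests and the acceptance
script measure the null rejection rate at n = 775 and hold it inside
5 % ± 3 points.
With one participant per cluster the fit reduces to ordinary logistic
regression (verified to 1e-4 in tests).

Indicators are standardized (mean 0, sample SD 1, count indicators
included) before fitting; a constant column is appended. α = 0.05
throughout. No multiple-testing correction is applied across the 37
univariate screens, matching the reporting convention of the motivating
analysis; a Benjamini–Hochberg switch exists but is off by default.
Collinearity pruning removes, within any pair with |Spearman ρ| > 0.7, the
indicator with the larger univariate p, visiting indicators in ascending-p
order (ties by name) — the published procedure's exact threshold and order
are not available, so this deterministic greedy rule is declared here.

The actual-vs-predicted contrast stacks both tables, adds a predicted-source
flag and a source×indicator interaction, and refits the same GEE; the
interaction coefficient estimates the change in association and its p-value
(α = 0.05) decides `significantly_different`.

# Generative models

All families share a trunk of two 64-unit ReLU layers and 32-unit output
heads; `P-` families have one head per participant cluster (the
discriminator also sees a cluster one-hot), `F-` families one head per
feature, `FP-` one per (cluster, feature). Inputs are z-scored by pooled
training statistics. The generator has an identity skip — output = baseline
point + learned residual — so the no-change solution is the starting point.
GAN training uses the non-saturating loss, fresh within-participant
(baseline, internship) hour pairs every epoch, Adam at 2e-4 for both
networks, batch 256, noise dimension 8.

Two stabilizers, both standard in the GAN literature, are essential on this
data and are on by default:

* **Instance noise** (SD 0.2, annealed to zero): the hourly features carry
  point masses (exact zeros, exact 3600 s) that a continuous generator can
  never hit exactly; without overlap noise the discriminator separates the
  supports perfectly and its gradients stop carrying moment information.
* **Feature matching** (weight 1): the squared difference between per-batch
  (per-cluster, for `P-` families) means and SDs of generated and real
  internship points is added to the generator loss. This anchors the
  conditional moments that the downstream $d_s$ evaluation depends on;
  without it the adversarial game wanders and cluster shifts come out with
  the wrong sign at these training budgets.

A mode-diversity guard tracks the per-feature ratio of generated to actual
SD every epoch and warns below 0.5. Generated points are de-normalized and
clipped to the training feature ranges so no negative durations or
impossible heart rates reach the indicator stage.

An intrinsic property of this design worth stating: the generator
conditions on a *single* baseline hour, which identifies the participant
only weakly, so the optimal conditional mean shrinks strongly toward the
(cluster) average. Individual-level prediction signal therefore flows
almost entirely through the participant-cluster heads — which is exactly
why the `P-` variants outperform their non-`P` counterparts, and why
features whose between-participant level variance is large (heart rate,
mood) show weaker actual-vs-predicted correlations than sleep and in-bed.

Clustering for the `P-` families standardizes the five $d_s$ columns
(their spreads differ several-fold), then sweeps no-PCA and 1–5 principal
components × {Ward, k-means} × k, choosing the configuration with the
highest silhouette on the representation used. Test participants are routed
to the head minimising the mean absolute difference between predicted and
actual Q1 $d_s$, ties toward the larger training cluster; without Q1 data
the larger cluster is the instructed fallback.

# Evaluation statistics

The skipped correlation uses the canonical "skipped Pearson" construction:
minimum-covariance-determinant centre, projection of all points onto every
centred data direction, the ideal-fourths boxplot bound on each projection,
union of flags, then Pearson on survivors with a t-based p on the reduced
n (a Spearman-on-survivors switch is provided). No adjustment is made for
the data-dependent removal, consistent with common practice and noted as a
limitation. The mean-assignment baseline assigns every test participant the
training-mean $d_s$; models are compared to it with a one-sided Wilcoxon
signed-rank test on per-participant squared errors, reported as undefined
when every paired difference is zero. Two-sample contrasts are gated by
Shapiro–Wilk at α = 0.05 onto a t-test or Mann–Whitney U.

# Problem sizes and numerical choices

The acceptance script and test suite run: oracle checks at 1000 random
samples; trajectory recovery at n = 775 over 10 seeds; GEE calibration at
n = 775 with 20 coverage seeds and 200 null fits; the generative stage on a
765-participant cohort (611 train / 154 test, ≥ 500 cleaned hours per
period from a 4-week baseline and 1-week-per-quarter internship) with
40-epoch schedules and 4 generated draws per baseline point. These sizes
are the package's choices for a complete desk-scale run; every stage
accepts larger values.

Tolerances: EM convergence 1e-8 relative; EM monotonicity asserted to 1e-8;
responsibility rows sum to 1 within 1e-9; GEE Fisher scoring to 1e-10 with
a divergence guard (|β| > 30 reported as apparent separation); formula
oracles agree to 1e-12.

# What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes — marginal
shapes, planted classes and clusters, missingness — not any real cohort's
parameter values. Passing tests therefore demonstrate that the pipeline
recovers known planted structure at realistic sizes and noise levels; they
do not certify effect sizes, correlations or class counts on real data.
Real streams also contain features the generator omits: device artefacts,
timezone shifts, weekly and seasonal rhythms, autocorrelated mood, and
informative (non-random) missingness beyond the quarter-level dropout
modelled here.

# Known limitations

* The GEE's specialty clustering uses 13 clusters; even with the $t_{G-1}$
  reference, inference with so few clusters is approximate.
* The skipped-correlation p-value ignores the data-dependent outlier
  removal.
* GAN training is stochastic; seeds make runs reproducible, but
  hyperparameters are tuned for the desk-scale synthetic cohorts, not for
  any real dataset.
* The mood EMA's planted individual-level coupling is visible to the GEE
  stage but is intrinsically unpredictable from baseline data, bounding the
  achievable actual-vs-predicted mood correlation well below 1.
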