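---
title: "Simulating a vibrotactile battery and analysing its test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a vibrotactile battery and analysing its test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(vibrotact)
library(dplyr)
```

## The battery and what it measures

Vibrotactile psychophysics probes somatosensory function with flutter-range
(25–50 Hz) stimuli delivered to the glabrous skin of two digits (labelled
LD2 and LD3 here; no skin mechanics are modelled — the sites are abstract).
The battery simulated by this package has eleven paradigms:

* **sRT, cRT** — simple and choice reaction time to a suprathreshold 300 μm
  pulse; measures are the median reaction time (correct trials only for cRT)
  and the intrasubject variability (ISV), the SD of trial reaction times
  after outlier screening.
* **sDT** — static detection threshold: which finger received a 500 ms
  stimulus, amplitude adaptively tracked from 20 μm.
* **dDT** — dynamic detection threshold: a stimulus ramps up from zero at
  2 μm/s after a uniform 0–2500 ms delay; the threshold is the mean ramp
  amplitude at the button press over correct trials, uncorrected for
  reaction time.
* **nAD, dAD, sAD** — amplitude discrimination (which of two simultaneous
  stimuli is stronger; standard 100 μm, comparison starting at 200 μm)
  without adaptation, with dual-site and with single-site adapting stimuli.
* **sqFD, smFD** — sequential and simultaneous frequency discrimination
  (standard 30 Hz, comparison starting at 40 Hz).
* **TOJs, TOJc** — temporal order judgement of two 40 ms pulses, starting
  150 ms apart, without and with a 25 Hz / 20 μm carrier stimulus.

Every task except the reaction-time pair and dDT is driven by a transformed
up-down staircase: one-up/one-down for the first ten trials, two-up/one-down
afterwards. The two-up/one-down rule converges on the stimulus level at
which the probability of a correct response is $2^{-1/2} \approx 0.707$
(Levitt targeting). Thresholds are estimated as the mean tracked level
*presented* on the final five trials, and a convergence score counts the
correct responses among those five. Each subject completes the battery three
times: two short administrations (Short1, Short2) and one long
administration with doubled trial counts, in an order randomized per
subject. The long no-adaptation amplitude-discrimination task deliberately
starts its comparison at 300 μm rather than 200 μm, mirroring the original
study's (inadvertent) configuration, which widened the tracked range of that
task only.

```{r staircase}
obs <- observer_params()
res <- run_task(default_battery("short")$sDT, obs, seed = 11)
res$measures
```

## The simulated observer

The battery itself measures only outcomes; to exercise it in silico the
package supplies a parametric observer. A two-alternative forced-choice
response is correct with probability

$$P(\text{correct} \mid d) \;=\; \tfrac12 + \left(\tfrac12 - \lambda\right)
F\!\left(d/\theta\right),$$

where $d$ is the *effective* tracked difference, $\lambda$ a lapse rate and
$F$ a Weibull (optionally logistic) rise from 0 to 1. The family is
calibrated so that $P(\theta) = 2^{-1/2}$ exactly: a two-up/one-down
staircase therefore converges on $\theta$ by construction, which is what
makes threshold recovery testable against a known truth. Task variants act
multiplicatively on the difference: single-site adaptation applies a gain
below one (it hurts discrimination, raising the measured threshold to
$\theta/g$), dual-site adaptation a gain above one (sharpening it), and a
TOJ carrier a gain below one. Reaction times are log-normal with a fixed
choice increment for cRT; the ramp task records the crossing of the
dynamic threshold plus the ramp distance travelled during a motor delay
(default 0.2 s), perturbed by log-normal trial noise.

Default population parameters (means and between-subject SDs in
`default_population()`) are calibrated so a simulated cohort lands near
published adult norms: static detection ≈ 5.1 μm, dynamic detection ≈
8.3 μm, amplitude discrimination ordered single-site > none > dual-site
(≈ 50 > 34 > 22 μm), frequency discrimination ≈ 7 Hz, temporal order with
carrier above without (≈ 35 > 24 ms). Session-to-session state variability
is modelled as multiplicative log-normal jitter on each latent parameter,
with per-domain SDs chosen to put within-subject CVs in the published
10–45% range. The generator deliberately omits attention, fatigue, learning
and practice-trial gating: passing tests show the *statistical machinery*
behaves correctly under the assumed variance structure, not that real
observers obey it. In particular the documented shortening of TOJ
thresholds in long administrations has no mechanism here and is not
reproduced.

## The measure-level generator

Reliability statistics do not need trial-level simulation, so a second
generator emits subject-by-session matrices directly from a specified
structure: per-session means $\mu_j$, per-session SDs $s_j$ and a
within-subject coefficient of variation. Entries are
$y_{ij} = \bar\mu + b_i + c_j + e_{ij}$ with $c_j = \mu_j - \bar\mu$,
residual SD $\sigma_w = \mathrm{CV_{ws}}/100 \cdot \bar\mu$, and subject
variance $\sigma_b^2 = \overline{s_j^2} - \sigma_w^2$ (clamped at zero with
a warning if the published numbers imply a negative value). The thirteen
rows of `default_measure_specs()` carry the published calibration for every
battery measure.

```{r generator}
spec <- default_measure_specs() |> filter(task == "sRT", measure == "rt_median")
m <- sample_measures(spec, n_subjects = 15, seed = 1)
round(icc_avg_absolute(m), 3)
```

## The reliability analysis

The analysis pipeline mirrors standard test-retest methodology:

* **Outlier screening.** Per task, measurements from all sessions are
  collapsed and screened with the median-absolute-deviation rule at
  threshold 2.5 (robust z = |x − median| / (1.4826 · MAD)). Individual
  measurements are removed; a zero MAD flags nothing and warns.
* **Coefficients of variation.** Between-subject
  $\mathrm{CV_{bs}} = 100\,\sigma_g/\mu_g$ per session and pooled; within-
  subject $\mathrm{CV_{ws}}$ is the mean over subjects of each subject's
  across-session CV. Sample (n − 1) SDs are used throughout, consistent
  with the reported mean ± SD convention.
* **ICC.** Two-way absolute-agreement average-measures ICC(A,k) from the
  ANOVA mean squares, $(MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$. Absolute
  agreement penalizes session shifts, unlike consistency forms. Raw
  estimates can be negative in small samples; they are kept raw in
  `icc_raw` and clamped to [0, 1] for the reported `icc` column. Subjects
  left incomplete by outlier removal are dropped from the ICC matrix only;
  CVs use all retained data. Columns are the version labels
  (Short1/Short2/Long) by default — the layout the published tables imply —
  with chronological sessions available via `session_col`, and a session
  subset (e.g. Short1/Short2 only, k = 2) via `icc_sessions`.
* **Bland–Altman.** Pair means versus percentage differences,
  $100\,(a - b)/\bar{ab}$, per version pair.
* **Truncation.** Long runs are truncated to the short trial count (keeping
  the *first* trials in presentation order) and all measures recomputed,
  emulating a third short administration.
* **Mixed models.** Version, time and task effects are tested with
  random-intercept models $y_{ij} = \beta_0 + s_j + \beta_1 x_{ij} +
  \varepsilon_{ij}$ fitted by maximum likelihood (lme4, not REML — variance
  estimates are therefore biased low, which matches the reporting
  convention here), compared by likelihood-ratio tests, with effect sizes
  as the proportional reduction in residual variance. The two short
  administrations are collapsed into one "short" level for version models;
  time enters as a linear session index by default (categorical via
  `time_coding`). Pairwise task contrasts use Tukey contrasts with normal
  (z) statistics and Holm–Bonferroni correction, reproducing the reported
  statistic type rather than studentized-range quantiles.

```{r study, eval = FALSE}
cfg <- study_config(n_subjects = 15, seed = 1)
ds <- run_study(cfg)
report <- analyze_study(ds, cfg)
report$reliability |> select(task, measure, cv_ws, icc)
```

## Numerical and design choices

* **Step sizes and floors are not part of the published protocol** (the
  commercial software's schedule is unpublished). Defaults are 10% of the
  initial tracked value (sDT 2 μm; AD 10 μm, 20 μm for the long nAD; FD
  1 Hz; TOJ 15 ms) with the floor at one step, giving at least ten
  descending steps before the floor and resolution comparable to the
  published threshold scale. Both are per-task configuration.
* **"Last five values"** is read as the levels presented on the final five
  trials (not post-update levels); the alternative is unknowable from the
  protocol description and the presented-level convention matches "the
  trials used to estimate thresholds".
* **Site randomization** is uniform Bernoulli per trial (the protocol says
  only "pseudorandomly"); intertrial intervals are carried as metadata but
  advance no clock — there is no fatigue model.
* **dDT correctness** is site localization of a clearly suprathreshold
  stimulus, modelled through the same psychometric function with the static
  detection threshold as scale; since dDT has no staircase it emits no
  convergence score, leaving eight staircase tasks — consistent with the
  degrees of freedom of the published convergence comparisons. If every
  ramp trial is incorrect the threshold is reported as missing.
* **Version orders** treat Short1/Short2/Long as three distinguishable
  labels permuted uniformly (six orders), so the two short instances are
  named by instance, not by chronology.
* **Optimization.** lme4's ML fit is used as-is with singular-fit checks
  silenced (boundary estimates of zero variance are legitimate here);
  likelihood-ratio statistics are clamped at zero against optimizer jitter.
* **Degenerate inputs** (zero MAD, zero total variance, all-incorrect ramp
  runs, sub-minimum trial counts) signal explicit conditions rather than
  returning silent zeros.

## Problem sizes used in validation

The package's own checks run at study scale chosen to bound Monte-Carlo
error, not to mimic any particular computing budget: calibrated-ICC checks
average 500 replicate 15 × 3 studies per measure; closed-form ICC recovery
uses 200 replicates of 50 subjects; Levitt-targeting checks use 600-trial
staircases over 50 seeds; likelihood-ratio calibration uses 2,000 null
datasets of 15 subjects × 3 sessions; and the task-ordering check runs 20
independently seeded full 15-subject studies. With those sizes the
calibrated generator reproduces the published reliability ordering
(reaction time ≈ 0.9, dynamic detection ≈ 0.78, static detection ≈ 0.65)
well within the ±0.10 band the checks assert.

## Known limitations

* Simulated observers are stationary within a session; convergence scores
  therefore reflect staircase geometry plus the psychometric slope, not
  attention lapses over time.
* Between-subject correlations among latent parameters are not modelled
  (draws are independent), so multivariate structure across tasks is
  weaker than in real cohorts.
* The measure-level generator is normal-additive; real threshold
  distributions are right-skewed, and published within-subject CVs above
  ~40% push a normal generator toward occasional near-zero values (clamped
  positive here).
* ICC confidence intervals are intentionally out of scope, as is ingestion
  of the original human dataset.
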