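---
title: "Keystroke fluctuation statistics as Parkinson's disease biomarkers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keystroke fluctuation statistics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyfluc)
```

## The measurement problem

Parkinson's disease degrades the fine motor control that typing exercises:
initiating, programming and executing each keystroke. A natural typing task
recorded as press/release timestamps yields four interval series per session.
With press times $P_1,\dots,P_n$ and release times $R_1,\dots,R_n$ in
press-time order over *all* keys:

* hold latency $HL_i = R_i - P_i$,
* interkey latency $IL_i = P_{i+1} - R_i$ (negative under rollover typing),
* press latency $PL_i = P_{i+1} - P_i = HL_i + IL_i$,
* release latency $RL_i = R_{i+1} - R_i = IL_i + HL_{i+1}$.

The biomarker of interest is not the interval level (a fast and a slow typist
can both be healthy) but its *step-to-step fluctuation*. For each series the
package computes the sample standard deviation of the natural log of
consecutive-interval quotients,

$$X_{SD} = \mathrm{sd}\{\ln(v_{i+1}/v_i)\},$$

a scale-free, sequential dispersion measure: multiplying a series by any
positive constant leaves it unchanged, while permuting it generally does not.
`HL_SD`, `IL_SD`, `PL_SD` and `RL_SD` use all keystrokes; `sd_restricted`
applies the same construction to hold latencies of alphanumeric, symbol and
space-bar keys only, reproducing the older restricted-key variant so both
conventions can be compared on the same data.

Interkey and release fluctuation are the most diagnostically interesting
series here: hold time reflects a single muscle contraction–relaxation cycle,
largely spared by the *consistent* rigidity of early PD, whereas the
release-to-press transition exercises movement initiation and programming,
which PD disturbs.

## Outlier policy

Raw logs contain rare, enormous glitch intervals and (for IL) negative
rollover values. Cleaning is a deterministic two-step rule applied per
subject, per latency kind:

1. negative values are invalid a priori and removed first, so they cannot
   shift the quartiles;
2. an IQR fence $[Q_1 - k\,IQR,\; Q_3 + k\,IQR]$ is computed on the remaining
   values and everything outside is removed.

The textbook extreme-outlier fence uses $k = 3$; on heavy-tailed
(approximately log-normal) latency data that fence bites into the meaningful
right tail, so the operating default is $k = 12$, which removes the glitch
population while clipping essentially nothing from an uncontaminated
log-normal bulk (< 0.1 % in the test suite). The quantile convention is
pinned to linear interpolation between order statistics (`type = 7`) and is a
switchable policy field, because statistics packages disagree at these sample
sizes even though at $k = 12$ the choice is almost never decisive. There is
no interactive "visual inspection" step: the per-subject removal report is
the machine-readable replacement for it.

After cleaning, ratios are formed over consecutive survivors (the series is
compacted). The stricter alternative — refusing ratios that span a removed
value — is available via `pairing = "strict"`; compaction is the default
because it maximises retained pairs. Non-positive values that reach the
statistic (possible with `drop_negative = FALSE`) are excluded with both
adjacent ratios dropped, as the logarithm demands. A cleaned series with
fewer than 3 values yields a *missing* statistic, never a fabricated zero.

## Screening statistics

Each feature is screened per contrast — de novo PD vs controls and early PD
vs controls are always separate, never pooled, because treatment-naïve
patients are the clinically interesting screening population. The machinery:

* **ROC / AUC.** Thresholds at midpoints between adjacent distinct scores
  plus infinite sentinels; the trapezoid AUC equals the Mann–Whitney
  probability with ties counted ½ (asserted to 1e−12 in tests).
* **Exact binomial CI.** Clopper–Pearson on `round(AUC·n)` of
  `n = n_cases + n_controls` trials. The effective `n` of this convention is
  not uniquely determined by the phrase "exact binomial CI" alone; using the
  total sample size matches common clinical ROC tabulation software, and the
  choice is isolated in one function.
* **DeLong paired test.** Placement values per subject, empirical covariance
  of the two AUCs, normal reference. Comparing a feature with itself returns
  p = 1; classes with fewer than 2 complete subjects yield a missing
  comparison rather than an error.
* **Youden cutoff.** Maximises $J = se + sp - 1$ over the staircase; ties
  resolve to higher sensitivity, then the lower threshold in the case
  direction — a screening-oriented tie-break (sensitivity is what a
  screening test must not give up).
* **Orientation.** Each feature has a declared direction (tapping scores and
  typing speed run *lower* in patients; fluctuation statistics and nQi run
  *higher*). Unknown features auto-orient (flip if AUC < 0.5) with a logged
  message, so a silent sign error cannot manufacture an AUC.

Missing clinical scores (afTap in particular: some subjects cannot complete
the alternating-finger tapping task) drop the subject for that feature only.

Group tables use the Kruskal–Wallis omnibus (tie-corrected) with a
Tukey-type rank post hoc: Nemenyi comparisons of pooled mean ranks against
the studentized-range distribution. "Nonparametric ANOVA with a Tukey post
hoc" has no unique referent; Nemenyi is the standard Tukey-type rank
procedure, and Dunn–Holm is available behind `posthoc = "dunn"` — results
near p = 0.05 can differ between the variants, which is documented rather
than resolved. Severity associations use Spearman's rho (average ranks for
ties), with the exact permutation distribution for n ≤ 9 without ties and
the t approximation otherwise. Descriptive cells are mean ± SD even though
all tests are rank-based, matching the usual clinical presentation.

## The synthetic cohort generator

Real keystroke archives cannot be redistributed with a package, so the
generator produces cohorts with the statistical structure the analysis
assumes, and the test suite treats *parameter recovery* as the acceptance
surface.

A typist is modelled as iid log-normal hold times and interkey gaps. For iid
log-normal intervals the log-ratios are Normal$(0, 2\sigma^2)$, so the
fluctuation statistic converges to $\sqrt{2}\,\sigma$ — an analytic bridge
from generator parameters to pipeline output that the tests exploit
(recovery within 2 % at $n = 1500$, 100 seeds). Overlaid on the clean
process:

* **rollover**: with small probability an interkey gap is replaced by
  $-u \cdot HL_i$, $u \sim U(0.05, 0.6)$, preserving press order;
* **glitches**: with small probability an interval is replaced by
  $\mathrm{median} \times U(30, 100)$, which the $k = 12$ fence removes
  deterministically (the injected positions are recorded as ground truth).

The default calibration (`inst/extdata/paper_defaults.yaml`) uses published
group values for cohorts of 43 controls, 24 de novo PD and 18 early PD:
interkey fluctuation targets 1.15 / 1.28 / 1.27 (subject-level SDs 0.15 /
0.11 / 0.16), hold fluctuation 0.50 / 0.57 / 0.53, alternating-finger tapping
128.99 / 94.85 / 96.33 ms (missing for 4 controls and 5 early-PD subjects),
UPDRS-III 1.92 / 19.33 / 22.32, session lengths 1634 / 1454 / 1321
keystrokes (truncated normals), and typing speeds 112 / 97 / 99 words/min.
Severity links use a Gaussian copula tying typing speed and session length
to UPDRS-III at Spearman targets (−0.37 / −0.45 in de novo, −0.76 / −0.73 in
early PD; controls unlinked — their UPDRS range is too narrow to carry a
meaningful link).

Choices the published tables do not pin down, made once here:

* **Rollover rate 0.2 %.** No negative-IL rate is published; the pooled
  removal percentages (0.36–0.56 %, negatives plus glitches together) bound
  it from above, and older, deliberate typists exhibit little rollover.
  Glitch rates per group (0.3 / 0.2 / 0.17 %) were then set so pooled
  removal lands on the published 0.56 / 0.40 / 0.36 % once the propagation
  of a glitch into the derived PL/RL series is accounted for.
* **Hold-time location** `mu_log_hl = log(0.025)` and space rate 1/6: with
  the published speeds and session lengths, the implied per-keystroke period
  is ~90 ms, which forces short hold times; the generator solves the
  interkey location per subject from the speed target, so the level is a
  consistency device, not a claim about real hold times.
* **Word convention**: a "word" is one space press, plus a trailing word if
  any non-space key occurs. Published word counts and speeds cannot
  disambiguate the definition; the convention is isolated in
  `typing_summary()` so an alternative can be swapped in.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: serial correlation within a session
(digraph-specific timing, fatigue drift; an AR(1) option on log-intervals is
the designated extension point), linguistic structure, typo/correction
behaviour, and any afTap–severity or nQi–severity link (those scores are
drawn from group distributions only, so only their *group separation*, not
their severity correlation, is meaningful in synthetic output). `RL_SD` and
`PL_SD` levels are *implied* by the HL/IL construction rather than
independently set, and the restricted-key statistic coincides with `hl_sd`
up to key-class sampling because synthetic keys are almost all admissible —
on real data, with real special-key traffic, the two differ more.

## Numerical and degenerate-input conventions

* Fluctuation statistics use the n−1 sample SD (the single most likely
  source of ±0.001-level discrepancies against other implementations);
  constant-ratio series short-circuit to exactly 0.
* All-equal score vectors give AUC 0.5 (every pair a tie at ½) and Youden
  J = 0.
* Zero-IQR series collapse the fence onto the repeated value, so any
  deviating point is removed — intended: such a point is infinitely many
  IQRs out.
* A session needs ≥ 2 events for latencies, ≥ 3 cleaned values for a
  statistic, ≥ 1 case and control for an ROC, ≥ 2 per class for DeLong,
  ≥ 3 complete pairs for a correlation; below these, results are missing
  with a reason, never silently zero.
* Reproducibility: every stochastic routine is seed-driven
  (`withr::with_seed`), cohort generation is byte-identical under a repeated
  seed, and study report files are byte-identical across repeated runs.

## Problem sizes in the test suite

Property checks run at the scale at which their distributional claims hold:
10,000 random short series against an independently coded two-pass oracle;
5,000 random ROC instances against exhaustive pair counting; 2,000-replicate
Monte-Carlo calibrations of DeLong and Kruskal–Wallis type-I error
(acceptance band 0.035–0.065 at α = 0.05); 100 seeded cohorts at the full
85-subject calibration for the end-to-end screening-direction check. These
sizes keep Monte-Carlo error comfortably below the tested tolerances.

## Worked example

```{r example, eval = FALSE}
library(keyfluc)

cohort <- simulate_cohort(paper_cohort_spec(), seed = 1)
study  <- run_study(cohort = cohort)

tidy(study)          # per-contrast screening table
study$correlations   # severity correlations per patient group
autoplot(study)      # ROC curves per contrast
```
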