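---
title: "Methods: gated OPI rubric scoring and Rasch calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gated OPI rubric scoring and Rasch calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and
conventions: what is computed, which parameters matter, what the
synthetic-data generator does and does not emulate, and where a design
was genuinely open and a choice had to be made. It states no empirical
result that the test suite does not itself compute.

## 1. The assessment model

A performance is scored on twelve dichotomous items in four ordered
levels of three items each: *completion* (1–3), *safety* (4–6),
*economy of motion* (7–9), *optimized performance* (10–12). Items 1–6
are human video ratings; items 7–12 are automatic, one per OPI
category:

| item | level | OPI category | metric |
|------|-------|--------------|--------|
| 7 | economy | energy usage | energized fraction of active time |
| 8 | economy | clutching | clutch count |
| 9 | economy | instrument movement | linear path length (mm) |
| 10 | optimized | wrist articulation | angular path length (rad) |
| 11 | optimized | smoothness | speed-peak count |
| 12 | optimized | instrument active time | idle time (s) |

**Gating.** The video items are safety-critical: at the first 0 among
items 1–6 scoring stops and all later items are 0. A 0 on items 7–12
does not gate. The gate position is recorded per person
(`gated_from`), which lets the calibration optionally treat post-gate
zeros as structurally missing (`gated_as_missing`); the default treats
them as observed zeros, matching how gated rubrics are actually
scored, and is what produces the depressed infit of gated items.

**Expert norms.** Item *j* among 7–12 scores 1 iff the OPI lies in the
closed interval \[μ_j − 2σ_j, μ_j + 2σ_j\] fitted over the expert
performances (sample SD, n − 1). The two-sided rule is the default
because the source convention is symmetric; one-sided variants
(`sided = "lower"`/`"upper"`) exist for count-like OPIs where only one
tail is poor performance, but are off by default.

**Level assignment.** The published material never states the rule
mapping item scores to a level, and its per-level counts cannot be
reconciled with its own gating counts under any single obvious rule;
we therefore made the rule explicit and configurable. Default:
cumulative — the highest level whose items and all lower levels' items
are all 1; failing any completion item gives `below_completion`.
Alternative: `count`, thresholding the total score at 3/6/9/12.

## 2. OPI signal processing

Speed is the finite-difference tip speed,
`|pos(k+1) − pos(k)| / Δt`, zero-phase low-pass filtered by a
second-order Butterworth (applied forward and backward over odd
reflection padding, so constants are exactly preserved). Parameters,
all in `opi_config()`:

* `smoothing_cutoff_hz = 5` — voluntary submovement dynamics live
  below ~3 Hz; raw 50 Hz differences are noise-dominated and would
  make peak counts meaningless.
* `peak_min_prominence_mm_s = NA` — adaptive: 10% of the 95th
  percentile of the smoothed profile. Peaks are strict local maxima by
  topographic prominence; plateaus count once.
* `idle_speed_threshold_mm_s = 1`, `idle_min_dwell_s = 0.5` — idle
  time sums maximal sub-threshold runs of at least the dwell; 0.1 s
  dips do not count.

Angular path length sums geodesic angles
`2·acos(|⟨q_k, q_{k+1}⟩|)` and is invariant to quaternion sign
conventions. *Active time* is task duration minus idle time and is the
denominator of the energy proportion — the recorder's own definition
is not public, so this one is declared, not inferred. These defaults
are package conventions: the thresholds used by the commercial
recorder analytics are unknown.

## 3. Rasch calibration

`fit_rasch_mml()` fits the dichotomous Rasch model by marginal maximum
likelihood: EM over 41-node Gauss–Hermite quadrature, normal latent
distribution with mean fixed at 0 (identification) and SD estimated.
Convergence: largest absolute parameter change < 1e-5, at most 500 EM
iterations; the marginal log-likelihood trace is retained and is
non-decreasing (asserted in tests). Items everyone passes or everyone
fails have no finite difficulty; they are flagged and excluded from
the likelihood, reported as ±Inf.

**Latent-SD cap.** Strongly gated matrices are quasi-Guttman, and
their marginal likelihood increases without bound in the latent
variance; the estimate is capped at `sd_max = 10` (reported via
`sd_capped`). For well-behaved data the cap is inert.

**Person estimation.** EAP is the posterior mean/SD on the quadrature
grid. WLE solves Warm's equation `r − ΣP + J/(2I) = 0` by
safeguarded root search, is finite at perfect/zero scores, and honours
Rasch sufficiency (equal raw scores ⇒ equal estimates; cached per raw
score). Reliabilities: `var(EAP)/(var(EAP) + mean(PSD²))` and
`1 − mean(SE²)/var(WLE)`, clipped to \[0, 1\]; zero estimate variance
returns 0 (no true-score variance) rather than erroring.

**Fit statistics.** `infit_outfit()` offers three conditioning
methods, because no single one is uniformly best on a 12-item test:

* `"posterior"` (default): squared residuals integrated over each
  person's posterior ability — the usual choice under marginal
  estimation. Null-calibrated (simulation in the acceptance suite:
  all-item infit within \[0.9, 1.1\] at n = 2000), but an aberrant
  item partially masks itself through its own contribution to the
  posterior.
* `"wle"` / `"eap"`: classic point conditioning `E = P(1|θ̂, δ)`.
  Maximally sensitive to aberrant items (a planted coin-flip item
  exceeds outfit 1.3), but deflates null mean squares by roughly one
  part per test length, pushing extreme items to ~0.89.

The acceptance suite asserts each claim under the estimator whose
sampling theory supports it and additionally checks that the planted
noise item tops the posterior outfit ranking. Flagging uses infit
against \[0.7, 1.3\] by default; the alternative \[0.75, 1.33\]
convention is a parameter.

## 4. Validity suite

*Agreement*: percent agreement and Cohen's kappa with marginal-product
chance correction; a constant rater yields kappa 0 by convention, and
kappa is undefined only when chance agreement is exactly 1.
*Biserial*: point-biserial item–ability correlations by default (the
classic biserial correction is a flag), plus per-level mean abilities
and their ordering. *Construct alignment*: Spearman rho with average
ranks for ties between level rank and difficulty — with four tied
triples against untied difficulties the attainable maximum is
`sqrt(135/143) ≈ 0.972`, not 1. *Wright map*: item and person
locations on the shared logit scale with per-level difficulty
summaries; `banding_check()` reports strictly increasing level means
and non-overlap of consecutive level ranges. *Fairness*: item
difficulties refitted per subgroup (each anchored by the latent-mean-0
convention), mean-centered over the common subset before Pearson
correlation — centering removes scale-origin artifacts the anchoring
would otherwise leave — with 95% Wald CI overlap per item; items
without response variance in either group are dropped with a logged
reason.

## 5. The synthetic cohort: a stated world

The generator emulates the *structure* of recorder data, not its
physics:

* **Trajectories** are superposed straight minimum-jerk submovements
  (`s(τ) = 10τ³ − 15τ⁴ + 6τ⁵`, peak speed `1.875·D/T`) with Poisson
  onsets outside exponential pauses, plus white positional tremor;
  orientation advances about a slowly drifting axis proportionally to
  translation. Closed forms for peak speed, helix arc length and
  geodesic additivity anchor the extraction tests.
* **Skill profiles.** Experts make few, long, flowing strokes
  (1.4 /s, 1.7 s, 15 mm, no tremor, 2 pauses/min); novices make many
  short jerky ones (3 /s, 0.3 s, 25 mm, 6 µm tremor, 8 pauses/min ×
  3 s) with heavier energy/clutch use. Two modelling points were
  forced by arithmetic, not taste: (1) with a common submovement
  duration, "more speed peaks *and* more idle time" is impossible in a
  fixed-duration task, since both scale with rate × duration — the
  duration contrast is what makes the novice signature realizable;
  (2) white tremor at 50 Hz implies a finite-difference speed floor of
  ~113·σ mm/s, so tremor above ~8 µm would permanently defeat a
  1 mm/s idle threshold; robotic tips are servo-filtered, so
  micrometre noise is the realistic regime. Profile endpoints were
  chosen once for a robust expert/novice contrast across 40 seeds.
* **Events** are an alternating renewal process with exponential
  sojourns whose stationary on-fraction equals the target duty; the
  initial state is drawn stationary so the expected energized fraction
  is exact, and a burst open at the horizon is closed there.
* **The fixture cohort** reproduces the published counts exactly:
  65 trainees (35 + 30 across two cohorts), 15 bleeding failures
  (8 + 7, rotating the failed item over 2–4 because the source does
  not identify it per subject), 4 poor-tissue-handling (item 5) and
  3 lost-tension (item 6) failures, 43 clean, 7 experts, and 13/17
  female/male labels in the second cohort only. Clean trainees split
  between a within-norms profile (drawn from the expert skill
  distribution, plus trace tremor) and the novice profile via
  `beyond_norm_fraction` (default 0.5, chosen once). The published
  per-level outcome counts are *not* forced: they cannot be derived
  from the published failure counts under any single level rule, and
  the fixture does not pretend otherwise.

A green test on this world establishes that the pipeline's *operations*
are correct and internally consistent — not that the simulator
reproduces porcine-model surgery, human raters, or the commercial
recorder's proprietary filtering. In particular, reliabilities and
difficulty ladders on fixture data are properties of the stated world,
and the study's own headline coefficients are not reproducible without
its response matrix.

## 6. Numerical conventions and degenerate inputs

Seeds are explicit everywhere; no function touches global RNG state
(`withr_seed` restores it). Units are mm, rad, s throughout. Quaternions
are scalar-first and re-normalized (and validated to 1e-9) on I/O.
Fully idle streams have zero active time; their energy proportion is
defined as 0 with no energized intervals (1 otherwise), while the
standalone `energy_proportion()` keeps the strict positive-active-time
error. Event streams validate on construction: energy events must
strictly alternate starting with `energy_on`, with no unmatched `on`.
WLE roots are bracketed in ±15 logits; quadrature uses Golub–Welsch
nodes (no quadrature package exists in the supported environment, nor
a DSP package — the Butterworth/filtfilt pair and topographic
prominence are implemented here and verified against closed forms).

## 7. Known limitations

* CML estimation, polytomous and 2PL/3PL models are out of scope; DIF
  is subgroup-refit correlation with CI overlap, not Mantel–Haenszel.
* Fit-statistic estimator bias on short tests is inherent (Section 3);
  users comparing against joint-estimation software should use
  `method = "wle"`.
* The per-instrument vs pooled OPI question is unresolved in the
  source; `extract_opis()` operates on one stream, and pooling across
  arms is the caller's composition.
* The fixture's subgroup labels are balanced by construction; fairness
  results on it demonstrate the machinery, not an empirical claim.
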