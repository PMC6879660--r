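---
title: "Methods: from wearable recordings to circadian health and chronotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wearable recordings to circadian health and chronotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circatap)
library(dplyr)
```

## The problem and the data

Ambulatory circadian monitoring (ACM) records a person's circadian system
under free-living conditions with wearable loggers: wrist skin temperature
(WT, a peripheral-vasodilation marker that *rises* at night), motor
activity (A) and body position (P) from an arm accelerometer, and light
(L) plus environmental temperature (ET) from a pendant logger. A sleep
diary contributes the binary sleep channel (S) and the intervals during
which sensors were taken off. `circatap` implements the full analysis
path from such recordings to per-subject circadian indexes and an
objective early/neither/late (E/N/L) chronotype call.

All channels are reduced to a common 10-min epoch grid
(`resample_to_grid()`): activity is accumulated (sum) per epoch, the
other channels averaged. Epochs are half-open, left-labelled and anchored
to clock decades — the 08:00 epoch covers 08:00:00–08:09:59.9. We chose
clock anchoring (rather than anchoring to the first sample) because it
makes epoch-of-day slots comparable across subjects and matches how
logger exports are normally aligned; partial epochs at either end of a
stream are dropped rather than extrapolated. A channel is analyzable only
when it spans 7 complete days; shorter channels are excluded and
reported, because every index here is defined on a week of repeated days.
`toy_mode` relaxes this for testing only.

## Cleaning

Two filters run before any statistic, in a fixed order:

1. **Diary masking** (`mask_intervals()`): epochs overlapping a reported
   sensor-off interval are invalidated. Values are never altered — all
   downstream statistics simply skip invalid epochs, and no imputation is
   performed.
2. **Rate-of-change outlier removal** (`iqd_filter()`): with
   `d_i = |x_i - x_{i-1}|` over consecutive valid epochs, epoch *i* is
   invalidated when `d_i` exceeds the interquartile distance
   IQD = Q3 − Q1 of the channel's valid values. We read "interquartile
   distance" as the standard IQR: the span from the first to the *fourth*
   quartile would be the full range, and no finite jump could ever exceed
   it. The filter is a single pass against the pre-filter distribution;
   re-running it on its own output can remove further points (the
   distribution is recomputed from survivors), which is why the pipeline
   applies it exactly once. Whether the threshold should instead be the
   IQR of the *differences* is ambiguous; the value-based reading is the
   default and `iqd_on = "diffs"` keeps the alternative available without
   silently changing results. A constant channel (IQD = 0) is returned
   untouched with a warning rather than an error.

Light is log-transformed **after** outlier filtering, as
`log10(lux + 1)` so that 0 lux maps to 0; the offset handles genuine
darkness, about which the raw scale is silent. The time-in-bin analysis
(below) always works on raw lux.

## The integrated TAP variable

TAP summarizes rest/activity state as the mean of three normalized
components: wrist temperature (inverted, because WT peaks during rest),
activity and position. Each component is mapped onto [0, 1] by an affine
map between its per-subject 5th and 95th percentiles, clamping outside.
Percentile bounds rather than the min/max make the scale robust to
residual spikes while preserving the endpoint semantics: TAP = 0 at the
fullest rest (highest WT, no movement, horizontal) and TAP = 1 at the
fullest activation. Per-subject (rather than population) bounds make TAP
a within-subject state variable, independent of between-subject
temperature offsets; population bounds can be supplied explicitly through
`normalize_channel(lo =, hi =)`. The three components carry equal weight
— nothing in the construction motivates any other weighting. By default
an epoch needs all three valid components; `min_tap_components = 2`
relaxes this as an explicit extension.

## Non-parametric indexes

All indexes are computed on the 10-min grid (p = 144 slots/day), not on
hourly means.

* **Interdaily stability**
  `IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)`:
  the fraction of total variance explained by the mean 24-h profile.
  1 for perfectly repeated days; i.i.d. noise gives ≈ p/N. Requires
  ≥ 80% valid epochs; a zero-variance channel is rejected (IS undefined).
* **Intradaily variability**
  `IV = (N * sum d_i^2) / (m * sum (x_i - xbar)^2)` with the `m`
  successive differences taken over *adjacent* valid pairs only, so
  masked gaps neither bridge nor fabricate transitions. ≈ 0 for a smooth
  sinusoid, ≈ 2 for white noise, up to 4 for strict alternation.
* **M/L levels**: exhaustive circular search over all 144 window starts
  of the mean daily waveform for the most/least active consecutive
  hours. Day-active variables (L, ET, A, P, TAP) use M10/L5; WT and S,
  whose acrophase falls in the rest period, use M5/L10. Ties break to the
  earliest onset after midnight, for determinism. Searching the mean
  waveform (rather than per-day windows averaged) follows standard
  non-parametric actigraphy practice.
* **Relative amplitude** `RA = (M − L)/(M + L)`, and its cohort
  normalization **NRA**: within each variable, the cohort's RA values
  below the 5th / above the 95th percentile are recoded to 0/1 and the
  rest rescaled linearly. Normalizing within-variable (not pooled across
  variables) keeps NRA interpretable as a rank within the cohort for that
  rhythm. With a degenerate RA distribution (p5 = p95 — e.g. diary-only
  sleep, where every subject has RA = 1) NRA is undefined and reported
  as `NA` rather than forced.
* **CFI** `= (IS + (1 − min(IV, 2)/2) + NRA)/3`: the IV term is clamped
  at 2 and inverted so all three components live on [0, 1].

Every percentile and quartile in the package uses linear interpolation
between order statistics (R's type 7) — one documented convention
everywhere.

## Phase markers, darkness center and CHI

The night phase marker (NPM) is the timing of the 5-h rest-period window
(L5, or M5 for WT/S); the day phase marker (DPM) the 10-h counterpart.
Timing is reported as the circular **midpoint** of the window: the
midpoint is symmetric under rotation and represents the phase center the
marker is used as; the onset convention remains available
(`marker_convention = "onset"`). Group summaries of clock times use
circular means — naive averaging fails near midnight.

Synchronization with the environment is measured against the center of
natural darkness, the circular midpoint from sunset to the next sunrise.
The default site values (sunset 17:47, sunrise 08:07, hence a darkness
center of 00:57) describe the study site in early winter and should be
overridden per site and season; the package deliberately does not compute
solar times from coordinates. `DM_NPM = circular_distance(NPM, center)/12 h`
lies in [0, 1]. The Circadian Health Index combines contrast, stability
and synchronization:

`CHI = (NRA + IS + (1 − DM_NPM)) / 3`

1 describes a high-amplitude, stable rhythm phased with the solar night;
0 a flat, unstable rhythm 12 h out of phase. The same convention is
applied to every variable, including ET, for comparability.

## Sleep diary, MSFsc and social jetlag

The diary yields the binary S channel (an epoch is asleep when its
midpoint falls within a declared sleep or nap interval, intervals taken
as `(start, end]`) and the cohort sleep-probability waveform (percentage
asleep per slot). For chronotype by questionnaire convention, nocturnal
episodes (naps excluded) are split into work and free days with the
asymmetric day lists: onsets on Sunday–Thursday are work nights, offsets
on Monday–Friday work mornings. Then `MSW = onset_w + SD_w/2`,
`MSF = onset_f + SD_f/2`, `SD_week = (5 SD_w + 2 SD_f)/7`, and the
sleep-debt correction `MSFsc = MSF − (SD_f − SD_week)/2` applies only
when free-day sleep exceeds work-day sleep — the common form of the
corrected midsleep. Social jetlag is the absolute circular difference
between MSF and MSW. Subjects with fewer than 3 work or 1 free night are
flagged and excluded from MSFsc analyses rather than guessed.

## Light exposure by daytime interval

Valid raw-lux epochs are classified into four intensity decades —
[0, 10), [10, 100), [100, 1000), [1000, ∞) lux — within three fixed 8-h
intervals: morning (epochs 08:00–15:50), evening (16:00–23:50) and night
(00:00–07:50), which tile the day exactly. Bin edges are half-open and
lower-inclusive, consistent with the epoch convention. Cells are reported
in minutes/day averaged over recorded days and, by construction, sum per
interval to the valid minutes in that interval.

## Chronotype classification

Subjects are classified from the TAP NPM by percentiles: the earliest
20% are E-types, the latest 20% L-types, the middle 60% N-types. Clock
times are first unwrapped onto a continuous axis centered on the cohort
circular mean, so a marker just before midnight ranks earlier than one
at 04:00. Membership is by rank — E for ranks ≤ `ceiling(0.2 n)`, L for
ranks > `n − ceiling(0.2 n)` — an inclusive reading of "lowest 20%" that
is deterministic for any n. Ties (common, since NPMs live on a 10-min
grid) break by input order with a warning when they span a class
boundary; an all-equal cohort is assigned all-N, since no phase ordering
exists. The class cut times are reported as data (attributes of the
assignment table), never hard-coded: any resemblance to particular
cut-off clock times is a property of the cohort at hand. The same rule
applied to MSFsc gives the questionnaire-convention classification, and
`chronotype_agreement()` summarizes their cross-table as coincidence,
one-step and opposite-category percentages.

## The synthetic cohort generator

`simulate_subject()` builds the five raw streams at native sampling
rates (WT 10-min; A and signed P 30-s; L and ET 10-min) and pushes them
through the same resampling path as recordings read from disk. The
construction is phenomenological, not physiological: nightly mid-sleep
is 04:00 + the chronotype phase offset, jittered night-to-night
(SD 0.35 h by default) and delayed 1 h on the two weekend nights; WT is
a 31.5 °C wake baseline plus a 3 °C squared-cosine bump of 5-h
half-width peaking at mid-sleep; A and P are wake-gated positive
signals; L is near-dark during sleep and log-normal during wake with
AR(1) persistence in log-space (lighting environments persist for tens
of minutes; without this, the IQD filter would treat ordinary daylight
as a wall of outliers), with brighter days for earlier phase offsets;
ET is a 24-h sinusoid. Sensor removals (Poisson, 1/week) drive WT to
near-ambient values and are logged in the diary; diary onsets/offsets
carry 5 min of reporting noise. Physiological nights continue one night
beyond each recording edge so the first and last days have the same
shape as interior days. Cohorts draw class-dependent phase offsets
(E/N/L means −1 h / 0 / +1.2 h, within-class SD 0.4 h) and subject-level
sleep durations (8 ± 0.5 h); all randomness flows from one root seed
through per-subject seeds, so runs are exactly reproducible.

Ground truth records the drawn class and the *realized* weekly phase
(circular mean of the programmed nightly mid-sleeps, including jitter
and the weekend delay); parameter-recovery tests compare pipeline
markers against this realized truth.

The generator emulates phase, amplitude, stability, noise, weekend
behavior and recording gaps. It does **not** emulate naps, nightly
awakenings, masking by environmental temperature, non-wear that the
diary fails to report, seasonal drift, or inter-channel artifacts —
so passing tests demonstrate that the estimators recover what the
generator encodes, not that they are robust to everything real
recordings contain.

## Numerical choices and degenerate inputs

* Clock arithmetic is circular modulo 24 h throughout; clock times are
  minutes since midnight internally and `"HH:MM"` at the interfaces.
* Quantiles: type 7 everywhere.
* Window ties: earliest onset; values within 1e−9 (relative) are treated
  as tied to keep the scan stable against floating-point summation
  order.
* Rejections (errors) are reserved for undefined quantities: zero
  variance for IS/IV, M + L ≤ 0 for RA, p5 = p95 for NRA, degenerate
  normalization bounds, mismatched grids. Recoverable oddities warn
  instead (constant IQD, boundary ties, small NRA cohorts).
* In the pipeline, per-subject-per-variable failures are quarantined
  into the exclusion log and the run continues.

## Problem sizes

The test-suite and validation runs use cohorts of 8–50 synthetic
subjects over 7-day weeks (1008 epochs/channel), 200 random waveforms
for the window-scan cross-check and 100 random walks for the filter
cross-check — sizes at which every documented property is exercised and
a full run completes in about a minute on a laptop.

## A short example

```{r example, eval = FALSE}
cohort <- simulate_cohort(n = 25, seed = 1)
analysis <- acm_pipeline(cohort)
tidy(analysis)      # one row per subject x variable
glance(analysis)    # cohort summary incl. agreement
autoplot(analysis, variables = c("TAP", "WT"))
plot_actogram(cohort[[1]]$channels$WT)
```

## Known limitations

* S (diary sleep) has RA = 1 for every subject whenever diaries contain
  no naps; its NRA, CFI and CHI are then undefined (`NA`) by design.
* The IQD filter is distribution-global: a channel whose legitimate
  dynamics exceed its own IQR (very spiky light under sparse sampling)
  loses valid epochs; the filter report in the results bundle makes the
  removal rate visible per channel.
* No sleep staging, no cosinor/periodogram analysis, no astronomical
  solar-time computation, and no between-group inferential statistics —
  the package stops at the tidy per-subject tables those analyses would
  consume.
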