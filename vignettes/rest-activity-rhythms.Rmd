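---
title: "Quantifying rest-activity rhythms from tracked locomotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rest-activity rhythms from tracked locomotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeitact)
```

## The analysis in one paragraph

`zeitact` turns a positional recording of a fish under a light:dark cycle
into a small set of interpretable chronobiological quantities. From the
tracked positions it computes per-frame swimming speed, classifies each
frame as active or inactive against a life-stage-specific speed
threshold, collapses sustained inactivity into *rest bouts*, bins
locomotion and rest into 24 zeitgeber-time (ZT) hourly bins, and reduces
the profile to a *diurnality index* (activity change ratio)

$$A_R = \frac{D - N}{D + N},$$

where $D$ and $N$ are mean hourly locomotion in the light and dark
phase, and a *crepuscularity index*

$$C_R = \frac{C}{NC} - 1,$$

where $C$ is the mean activity of the hourly bins immediately following
the two light transitions (dawn and dusk) and $NC$ the mean of the
remaining bins. $A_R$ runs from $+1$ (all activity in the light phase)
to $-1$ (all in the dark); $C_R = 0$ means no transition response and
$C_R = 1$ a 100% increase after transitions.

The same reduction can start from a manually scored ethogram (active
swimming logged as on/off state events) instead of positions; rest is
then the complement of the scored activity and the indices are computed
on time spent active rather than distance, which is unobservable in a
scored record.

## Conventions and parameters

All internal lengths are millimetres, all times seconds from recording
start. This single canonical unit matters because the two life stages
use thresholds quoted in different units in practice: 12 mm/s for
juveniles and 4 cm/s = 40 mm/s for adults (`stage_threshold()`). Both
values were established empirically in this assay lineage to separate
passive drift from active swimming; the package treats them as data, not
as tunables, though every function accepts an explicit override.

* **Speed** (`compute_speed()`): Euclidean displacement between
  consecutive samples divided by the frame interval, assigned to the
  *later* sample, so frame $j$ covers $((j-1)/\mathrm{fps},\,
  j/\mathrm{fps}]$. Speed across a tracking gap is undefined and the
  affected frames are excluded from activity, rest and locomotion
  accounting alike — never interpolated. No smoothing is applied by
  default; an optional centred boxcar (`smooth_window_s`) exists because
  some trackers export unfiltered jitter, but it is off unless asked
  for.
* **Rest bouts** (`detect_rest_bouts()`): maximal runs of frames with
  speed strictly below the threshold, lasting at least `min_duration_s`
  (default 60 s). The duration rule is *inclusive* (a bout of exactly
  60 s counts, matching the "1 min or longer" reading; at 15 frames/s
  the alternative reading differs by a single frame) and the speed
  comparison is strict — both declared so tests can be exact. Runs
  interrupted by gaps are split; gap frames belong to no bout. The
  partition is exact: rest, active, sub-minimum inactivity and gap
  frames sum to the total frame count (`time_accounting()`).
* **Hourly binning** (`bin_hourly()`): ZT bin $k$ covers
  $[\mathrm{ZT}\,k, \mathrm{ZT}\,k+1)$; a recording starting at ZT1
  (the default — animals are disturbed at ZT0 when lights come on, so
  recordings start one hour later) fills bins ZT1..ZT0 exactly once per
  24 h. Recording start must be a whole ZT hour, so frame intervals
  nest exactly inside bins. Locomotion per bin is the sum of frame
  displacements whose later sample falls in the bin; rest minutes are
  the pro-rata overlap of bouts with the bin; multi-day recordings are
  averaged per ZT hour with `n_days` recorded. Partial trailing hours
  are dropped, and day/night means refuse to guess from partially
  covered phases: `D` and `N` are means of hourly bins (identical to
  phase totals divided by phase length for complete days, which are the
  only days accepted).
* **Indices**: undefined ratios (a motionless fish, $D + N = 0$; an
  empty non-crepuscular baseline, $NC = 0$) propagate as `NA`, never as
  silent zeros, and are excluded from group statistics with a logged
  count.
* **Crepuscular window** (`window_h`): the published wording wavers
  between "hour" and "hours" after the transitions; the default here is
  one hourly bin after dawn and one after dusk ($NC$ over the remaining
  22 bins), configurable to 2. $NC$ excludes only the crepuscular bins
  themselves, not transition-adjacent pre-hours.

## The synthetic-data generator

No public recordings accompany the study design this package serves, so
validation rests on a simulator with analytically known ground truth
(`sim_params()`, `simulate_trajectory()`, `simulate_ethogram()`).

Each subject is a two-state semi-Markov process alternating between
active swimming and rest. Dwell times are exponential with
phase-dependent hazards (`rest_rate`: active→rest; `wake_rate`:
rest→active); hazards switch instantaneously at light transitions, with
in-progress dwells redrawn there — the memoryless construction, chosen
because transition-coupled behaviour is exercised separately through
the crepuscular multiplier. While active, per-frame displacement
magnitudes are uniform on $[\theta,\, 2\bar v - \theta]$, where
$\theta$ is the analysis threshold and $\bar v$ the phase's
`mean_active_speed`: the mean is exactly $\bar v$, every active frame
is strictly supra-threshold, and the step size is bounded (needed for
the arena-wall geometry below). While resting, the fish drifts at a
fixed 25% of the threshold, unambiguously sub-threshold, so that
simulated rest never straddles the classification cutoff. Headings are
isotropic and redrawn every frame (the analysis uses only speed, not
path shape); at the walls a heading is redrawn until the step stays
inside, which preserves step lengths exactly. A step can always be
placed provided it is at most half the smaller arena dimension —
validated at construction ("arena too small" otherwise). During the
first hour after each light transition, active speeds are multiplied by
`crepuscular_multiplier` ($\ge 1$); the state process is untouched, so
a seed-matched ethogram is byte-identical whatever the multiplier.

Stationary occupancy gives the closed-form ground truth: the rest
fraction per phase is $\rho = r/(r + w)$ and the expected locomotion
per hour is

$$3600\,\bigl[(1-\rho)\,\bar v\,\kappa + \rho \cdot 0.25\,\theta\bigr]
\ \mathrm{mm/h},$$

with $\kappa$ the within-phase average of the crepuscular multiplier
(one boosted hour per phase). The second term is the rest-state drift:
observed locomotion includes it, so the closed form must too — under
typical parameters it contributes 5–10% of total path length, far more
than the Monte-Carlo error the recovery tests resolve. Expected $D$,
$N$ and $A_R$ follow directly, and the test suite verifies that the
full pipeline recovers them (the $A_R = 0.5$ parameter set used in the
recovery tests was checked against brute-force averaging of 200
simulated subject-days before being frozen).

Stage defaults emulate the standard recording geometry: juveniles in
35 mm plate wells at 15 frames/s, adults in 500 × 300 mm tanks, a
14 h:10 h photoperiod, recording from ZT1 for 24 h. The six
`species_presets()` span diurnal, nocturnal, crepuscular-nocturnal and
arrhythmic phenotypes; they are illustrative only, since no published
per-species activity parameters exist to calibrate them.

What the simulator deliberately does *not* emulate: tracking noise and
lost-tracking gaps (tests inject gaps explicitly where they matter),
social interaction within groups (group recordings are independent
subjects sharing an arena), speed distributions that straddle the
threshold, and any light-quality or twilight-spectrum structure.
Passing recovery tests therefore demonstrates that the analysis
machinery is correct and unbiased on data satisfying its assumptions —
not that the thresholds themselves are right for any particular real
recording.

## Statistics

The statistical battery mirrors the comparisons this kind of study
reports, built on base R's fitting machinery: one-way fixed-effects
ANOVA across species (`species_anova()`), a two-way repeated-measures
(split-plot) ANOVA with species between subjects and day/night within
(`day_night_rm_anova()`; with a two-level within factor sphericity is
trivially satisfied), ordinary least squares of adult on juvenile
species means (`stage_correlation()`, reporting $r^2$), and a
two-sided paired $t$ test (`paired_day_night_test()`). Post hoc
day-vs-night contrasts within species are Šidák-adjusted,
$p_{\mathrm{adj}} = 1 - (1-p)^m$, with the family size $m$ equal to the
number of species-level contrasts in the analysis. All tests are
two-sided at $\alpha = 0.05$. One degenerate case is resolved
deliberately: paired differences that are identically zero return
$t = 0$, $p = 1$ (no evidence of a difference), while a constant
non-zero difference — zero variance with a non-zero mean — is an
error, since the statistic is undefined.

The suite calibrates these choices on simulator output: the paired
test's type-I error is estimated from 2,000 phase-homogeneous null runs
of 6 subjects each, and the split-plot interaction's power from 200
runs of a strongly diurnal versus a strongly nocturnal synthetic
species at 12 subjects per species. Both batteries run the simulator at
1 frame/s: frame rate enters neither the null distribution of a test on
hourly means nor the direction of a day/night contrast, and one-hertz
sampling keeps tens of thousands of simulated subject-days tractable.
Recovery and null-bias checks of the indices themselves use the full
15 frames/s (50 subject-days for the $A_R = 0.5$ recovery, 200 for the
phase-homogeneous null). The exhaustive detector-vs-oracle equivalence
enumerates every boolean activity sequence up to length 20 at 1 Hz with
a 5 s duration rule — at those lengths the 60 s rule is vacuously
empty — plus 1,000 random 15 Hz sequences at the default 60 s rule.

## Known limitations

* Species presets are phenomenological, not calibrated to any
  population; conclusions about particular species require real
  parameter estimates.
* Rest is a velocity-threshold construct: the package deliberately
  makes no claim about sleep, for which behavioural criteria are not
  established in this group.
* The crepuscularity index inherits the ratio instability of small
  denominators; near-zero baseline activity flags `NA` rather than
  returning an extreme value, which callers must handle.
* No free-running period estimation or actogram double-plotting:
  recordings under cycling light only.
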