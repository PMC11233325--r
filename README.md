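# zeitact

Rest–activity rhythm analysis for tracked animal locomotion under
light:dark cycles.

Fish activity assays — juveniles in multiwell plates, adults in tanks,
filmed for 24 h under a 14 h:10 h photoperiod — produce positional time
series from which chronobiologists want a handful of interpretable
quantities: how much an animal moves, when it rests, whether it is
diurnal or nocturnal, and whether it shows bursts of activity around the
light transitions. `zeitact` implements that reduction as a tested,
reusable pipeline, for people analysing video-tracker exports (or
manually scored ethograms) of fish and similar animals.

## What it computes

From per-frame speed it classifies activity against a life-stage
threshold (12 mm/s for juveniles, 40 mm/s for adults) and collapses
sustained inactivity into **rest bouts** (sub-threshold runs of ≥ 60 s).
Locomotion and rest are binned into 24 zeitgeber-time hourly bins
(ZT0 = lights-on), from which two indices follow:

* **Diurnality (activity change ratio)**
  `A_R = (D − N) / (D + N)`, with `D`, `N` the mean hourly locomotion in
  the light and dark phase; +1 is fully diurnal, −1 fully nocturnal.
* **Crepuscularity** `C_R = C / NC − 1`, with `C` the mean activity in
  the hour after each light transition (dawn, dusk) and `NC` the mean
  over the remaining hours; 0 means no transition response, 1 a 100%
  increase.

The accompanying statistical battery covers the comparisons such studies
report: one-way ANOVA across species, split-plot (repeated-measures)
ANOVA of day/night × species with Šidák post hoc contrasts, paired
day/night tests, and juvenile–adult regression of species means.

A two-state semi-Markov simulator (`simulate_trajectory()`,
`simulate_ethogram()`) generates trajectories and scored-event tables
with closed-form ground truth (stationary rest fractions, expected
hourly locomotion, expected `A_R`), which is how the pipeline is
validated end to end.

## Worked example

```r
library(zeitact)

p   <- sim_params(seed = 42, stage = "juvenile", duration_h = 24,
                  fps = 15, n_subjects = 1)   # moderately diurnal defaults
sim <- simulate_trajectory(p)                 # 14:10 LD, recording from ZT1
fit <- rhythm_analysis(sim$trajectories[[1]])
fit
#> Rest-activity rhythm analysis for 's01' (locomotion-based)
#>   D = 1.373e+05 mm/h, N = 5.375e+04 mm/h, A_R = 0.4373
#>   C = 1.021e+05, NC = 1.025e+05, C_R = -0.004269
#>   142 rest bout(s), 346.4 min total rest

sim$ground_truth$expected_AR
#> [1] 0.4615385
```

The fitted subject moved ~137 m per hour in the light and ~54 m in the
dark, giving a diurnality index of 0.44 — within Monte-Carlo noise of
the simulator's closed-form expectation of 0.46 for these parameters —
and essentially no crepuscular response (`C_R ≈ 0`, as these defaults
apply no transition boost). `coef(fit)` returns the six index
components; `plot(fit)` draws the 24 h profile with the dark phase
shaded; `summary(fit)` adds the hourly table and the exact time
accounting.

End-to-end runs are driven by a single config (see
`inst/extdata/demo_config.yaml`):

```r
res <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "zeitact"),
                    out_dir = "demo_out")
```

which simulates the bundled six-preset species set, writes per-subject
profiles, indices, rest bouts and the statistics table as CSV, and is
byte-for-byte reproducible given the config and seed. A thin CLI
wrapper lives at `inst/cli/zeitact.R`.

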