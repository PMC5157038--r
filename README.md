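# muresp

Quantification of movement-induced sensorimotor oscillatory responses
from EEG.

Repetitive voluntary movement modulates the mu rhythm recorded over the
sensorimotor cortex (channels C3/C4): the band-limited amplitude envelope
of its alpha (8–14 Hz) and beta (15–30 Hz) components dips before and
around each movement onset (event-related desynchronization) and rebounds
afterwards (post-movement synchronization). `muresp` is for clinical
neurophysiology and motor-control researchers who need that modulation
depth as a per-subject number: it implements band-limited envelope
extraction (zero-phase order-6 Butterworth band-pass, then either
rectify + 0.1 s moving average or a Hilbert amplitude-modulation
envelope), movement-anchored epoching with artifact and timing retention
rules (EOG < 300 µV, inter-movement duration within 0.5 s of the
designated interval), 60-epoch block averaging, and the normalized
amplitude-response statistic

    Amp_resp  = Amp_max − Amp_min                      (µV)
    PAmp_resp = 100 · Amp_resp / ((Amp_max + Amp_min)/2)   (%)

with `Amp_min` the response minimum in [−1.5, 0) s and `Amp_max` the
maximum in [0, 2.0) s around movement onset, plus the inter-hemispheric
laterality index

    LI = (PAmp_contra − PAmp_ipsi) / (PAmp_contra + PAmp_ipsi).

The statistical layer tests the movement-rate effect (inter-movement
intervals 3 s / 2 s / 1 s) with one-way ANOVA and Bonferroni-corrected
two-tailed post-hoc t-tests, and can recompute ANOVA F statistics
directly from published group means/sds. A seeded synthetic-EEG generator
with analytic ground truth (Gaussian-bump gain on constant-envelope
narrow-band carriers, pink noise, blinks, timing outliers) makes every
stage verifiable without recorded data. BrainVision
(`.vhdr`/`.eeg`/`.vmrk`) and EDF readers/writers are included.

## Worked example

```r
library(muresp)

sc <- scenario(imi = 2, n_triggers = 66, fs = 500,
               alpha = modulation_params("alpha", A_base = 15,
                                         d = 0.4, r = 0.2))
sim <- simulate_recording(sc, seed = 7)       # Recording + ground truth
q   <- quantify_recording(sim$recording)      # full single-run pipeline
q$summary[, c("channel", "band", "pamp_resp_mean")]
#>   channel band  pamp_resp_mean
#> 1 C3      alpha           65.0
#> 2 C4      alpha           62.1
#> 3 C3      beta            70.5
#> 4 C4      beta            62.5
sim$truth$expected$pamp_expected[1]
#> [1] 64.6
```

The generator promised a normalized amplitude response of 64.6 % (the
closed form `200(d+r)/(2+r−d)` corrected for the slight overlap of the
suppression and rebound bumps), and the pipeline recovers 62–70 %
across channels and bands; the laterality index of this hemispherically
symmetric scenario comes out at 0.022 (alpha). Note `PAmp_resp` is
invariant to the envelope method and overall scale, while `Amp_resp`
(µV) scales with both.

The `analysis/` directory holds the cohort-scale workflow as numbered
scripts — `01_simulate.R` (scenario bank, format round-trips, trigger
timing), `02_envelope.R` (method comparison, the 2/π relation),
`03_quantify.R` (60 recordings → per-subject PAmp/LI/retention tables),
`04_group_stats.R` (rate-effect ANOVA + post-hoc, and the
printed-summary ANOVA check) — each writing its tables under `results/`.

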