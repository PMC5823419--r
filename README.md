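# cmwbreath

Sleep respiratory-rate detection and apnea/hypopnea event extraction
from breathing-sound audio, using characteristic moment waveforms.

## What it does, and for whom

Screening for obstructive sleep apnea (OSA) normally requires
polysomnography; a far cheaper signal is the sound of breathing
recorded by a microphone near the nose. `cmwbreath` turns such a
recording (or a synthetic one from its built-in simulator) into:

* breath-cycle segment points and the inter-cycle intervals `dd(i)`,
* a per-minute respiratory-rate (RR) series,
* apnea (pause ≥ 10 s) and hypopnea events with estimated pause
  durations, and the apnea–hypopnea index (AHI) with its clinical
  severity band (5–15 mild, 15–30 moderate, ≥ 30 severe).

It is aimed at researchers in biomedical acoustics and sleep monitoring
who need a transparent, O(n), threshold-light baseline pipeline that
runs on whole-night recordings.

## The method

With `y(t)` the (normalized) recording, the pipeline computes:

1. **Amplitude-contrast reduction** — signed entropy transform
   `H(t) = -sign(y) |y| ln|y|`, then a piecewise cut
   `H_cut = a·H + sign(H)·b·av` where `|H| > av` (mean of `|H|`) and
   `c·H` elsewhere (`a = 0.4`, `b = 0.6`, `c = 1.5`), then the soft
   limiter `y_enh = H_cut (1 − l + l |H_cut|^N)` (`l = 0.85`,
   `N = 20`). Weak breathing cycles survive next to heavy ones.

2. **Time characteristic waveform (TCW)** — the sliding-window
   variance

   `c(t, δ) = ∫_{t−δ}^{t+δ} y(τ)² dτ − 2δ ȳ(t)²`,
   `ȳ(t) = (1/2δ) ∫_{t−δ}^{t+δ} y(τ) dτ`,

   an energy envelope computed with prefix sums (cost independent of
   `δ`).

3. **Characteristic moment waveform (CMW)** — the local second moment

   `I(t, δ, l) = ∫_{t−l}^{t+l} (τ−t)² c(τ, δ) dτ`,
   normalized `n(t, δ, l) = I(t, δ, l) / ∫_{t−l}^{t+l} c(τ, δ) dτ`,

   which peaks at sharp valleys of the TCW. Segment points are placed
   at prominent TCW minima (rest phases) validated by prominent CMW
   maxima, with every segmented interval required to contain breathing
   energy.

4. **Apnea analysis** — stable rate `RR_stable` (median of non-zero
   minutes, or user-supplied), threshold
   `T_RR = RR_stable − 10·RR_stable/60`, pause times
   `max(0, dd(i) − 60/RR_stable)`, event classification and AHI.

## Worked example

Simulate six minutes of breathing at 12 cycles/min with two inserted
pauses (15 s and 31 s), run detection, and score it:

```r
library(cmwbreath)

sched <- data.frame(start_s = c(100, 200), gap_s = c(15, 31))
sim <- generate_breathing(synth_spec(duration_s = 360, cycle_period_s = 5,
                                     amplitude_jitter = 2,
                                     apnea_schedule = sched, seed = 1))
det <- cmw_detect(sim$signal, pipeline_config(estimated_cycle_s = 5))
det
#> Breath detection over 360.0 s @ 4000 Hz (delta = 0.8 s, l = 0.1 s)
#>   62 breath cycles; RR per minute: 12 9 11 6 12 12
#>   RR_stable 11.5/min, T_RR 9.58/min, AHI 20.0 (moderate)

evaluate_success_rate(det$segmentation, sim$truth)
#> <rr_evaluation: 100.00% (62/62 matched within 1 s, 0 false positives)>

det$report$events
#>    type   start_s  pause_s
#> 1 apnea  98.88469 14.83036
#> 2 apnea 200.11744 31.23836
```

Reading the output: 62 cycle boundaries were found; minutes 2 and 4 —
the minutes containing the pauses — drop to 9 and 6 cycles, below the
threshold `T_RR ≈ 9.6`; the two recovered pause durations (14.83 s and
31.24 s) are within a quarter second of the inserted gaps, and both
exceed the 10 s clinical apnea criterion. The AHI of 20/h is high only
because this demonstration crams two apneas into six minutes.

`plot(det)` shows the processed signal, the TCW with segment points,
and the CMW.

## Command line

```sh
Rscript inst/cli/cmwbreath.R simulate --out rec.wav --truth truth.csv --duration 300 --seed 7
Rscript inst/cli/cmwbreath.R detect   --in rec.wav --out-prefix results/run1
Rscript inst/cli/cmwbreath.R evaluate --detected results/run1_boundaries.csv --truth truth.csv
```

Subcommands `simulate | preprocess | detect | evaluate`; a YAML config
file (`--config`) can set any `pipeline_config()`/`synth_spec()` field,
with flags overriding it.

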