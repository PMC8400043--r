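# sonouroflow

Acoustic uroflowmetry in R: from the sound of a voiding event to a predicted
urinary flowrate curve and a bladder-emptying health classification.

Clinical uroflowmetry measures the urinary flowrate `V(t)` with a weight
transducer (`V(t) = Ẇ(t)/ρ`, with `W` the collected urine weight and `ρ` the
urine density) and summarises it as Qmax, Qavg, voided volume, voiding time
and curve shape. The test is confined to the clinic, which distorts exactly
the behaviour it tries to measure. This package implements a non-invasive
alternative aimed at urologists and biomedical-signal researchers: the sound
radiated by the urine stream carries the same information, and a small
recurrent network can decode it.

The pipeline has four stages:

1. **Short-time spectral analysis** — mono recordings are analysed with a
   Hanning-windowed STFT (`N = 4096`, 25% overlap), calibrated to dB SPL
   re 20 µPa.
2. **Psychoacoustic features** — each frame is mapped to a Bark-scale
   excitation pattern; total loudness is the critical-band integral of
   Zwicker's specific loudness
   `N′ = 0.08 (E_TQ/E₀)^0.23 [(0.5 + 0.5 E/E_TQ)^0.23 − 1]`,
   `N = ∫₀²⁴ N′ dz` (sone), and roughness is
   `R = 0.3 f_mod ∫₀²⁴ ΔL(z) dz` (asper) with `f_mod = 70 Hz` and the
   masking depth `ΔL` capped at 50 dB, calibrated so that a 1 kHz, 60 dB
   tone 100% amplitude-modulated at 70 Hz gives exactly 1 asper.
3. **Sequence-to-sequence LSTM regression** — per-frame (loudness, roughness)
   vectors are mapped to the flowrate by a 5-unit LSTM cell
   (`f, i, o = σ(W [h, x] + b)`, `c_t = f∘c_{t−1} + i∘tanh(W_c[h,x]+b_c)`,
   `h_t = o∘tanh(c_t)`) with a one-neuron dense head, trained with Adam
   (batch 3, 40 epochs).
4. **Sequence-to-label LSTM classification** — flowrate curves, normalized to
   the unit square and resampled to 246 points, are classified by a 50-unit
   LSTM with a softmax head (`y = softmax(W h_T + b)`) into the three
   clinical morphologies: **A** bell-shaped (healthy, Qmax > 15 mL/s),
   **B** staccato (LUTS / impaired detrusor contractility, Qmax < 10 mL/s),
   **C** interrupted (obstruction, Qmax < 5 mL/s). Training data are
   augmented with bounded jitter, `V′(t) = |V(t) + A·rand(t)|`,
   `0 < A < 0.05·max V`, 100 copies per patient.

No clinical recordings ship with the package. A seeded generator
(`gen_cohort()`, `gen_flow_curve()`, `gen_weight_trace()`,
`gen_sound_features()`, `gen_am_tone()`) produces labelled voiding events —
flow archetypes, matched load-cell traces, co-varying feature series and
calibration tones — so the full pipeline is trainable and testable from code
alone.

## Worked example

```r
library(sonouroflow)

# a synthetic voiding event: flow archetype + noisy load-cell trace
flow    <- gen_flow_curve("bell", q_max = 22, voiding_time = 25, seed = 42)
weights <- gen_weight_trace(flow, noise_g = 0.5, seed = 42)

# flowrate from the weight trace, and its clinical summary
flow_hat <- flowrate_from_weight(weights)
voiding_metrics(flow_hat)
#>   voided_volume voiding_time q_max q_avg q_avg_flowing n_interruptions
#> 1          212.         23.9  23.2  8.85          9.89               0
label_pattern(flow_hat)[, c("label", "q_max", "n_interruptions")]
#>   label q_max n_interruptions
#> 1 A      23.2               0

# the roughness reference: 1 kHz, 60 dB SPL, 100% AM at 70 Hz -> 1 asper
median(roughness(gen_am_tone())$roughness)
#> [1] 1

# train the flowrate regressor on a synthetic cohort and evaluate held out
cohort <- gen_cohort(n_per_class = 10, seed = 1)
ts     <- build_training_set(cohort, task = "regression", seed = 1)
reg    <- train_flow_regressor(ts, seed = 1)
evaluate_flow_predictions(reg, ts)
#>   patient error_rate
#> 1 A06           3.52
#> 2 A08           3.85
#> 3 B08           3.13
#> 4 B09           2.75
#> 5 C02           6.52
#> 6 C03           6.33
```

The metrics table reads: this event voided 212 mL in 24 s with a peak flow
of 23 mL/s and no interruptions — a healthy bell-shaped curve, label A. The
`error_rate` column is the mean absolute prediction error as a percentage of
each event's measured maximum flowrate, on patients never seen in training.

`autoplot()` methods exist for spectrograms, flow curves, feature series and
fitted models; `tidy()`/`glance()` summarise fitted models. A thin command
line (`inst/cli/sonouroflow`) exposes the stages as subcommands
(`features`, `flow`, `label`, `augment`, `synth`, `train-reg`, `train-clf`,
`predict`, `classify`, `run`).

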