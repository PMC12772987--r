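---
title: "Estimating pediatric OSA severity from single-channel airflow: methods and design"
author: "apneaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pediatric OSA severity from single-channel airflow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneaflow)
```

## The problem

Pediatric obstructive sleep apnea (OSA) is diagnosed from the
apnea-hypopnea index (AHI): the number of apneas (at least 90% airflow
reduction) and hypopneas (30-90% reduction) per hour of sleep, scored by an
expert on a full polysomnogram. The clinical severity classes are no OSA
(AHI < 1 e/h), mild (1-5), moderate (5-10), and severe (>= 10), with all
boundaries closed on the left. apneaflow estimates the AHI from a single
overnight airflow channel (oronasal thermistor), the kind of signal a home
screening device can record, and augments the estimate with attribution maps
that show *where* in the signal the model found its evidence.

## Pipeline

1. **Preprocessing.** The raw airflow is resampled to 4 Hz, cut into
   consecutive non-overlapping segments of 5, 10, or 20 minutes (1200, 2400,
   or 4800 samples), and each segment is z-scored. Nothing else is done on
   purpose: no filtering or artifact rejection, so the model learns to cope
   with movement bursts and sensor disconnections. A trailing remainder
   shorter than one segment is dropped rather than padded, because z-scoring
   a padded tail would distort its amplitude statistics. A segment whose
   standard deviation is below 1e-8 (a flatlined disconnection) maps to all
   zeros.
2. **Per-segment regression.** A 1-D convolutional network estimates the
   number of respiratory events in each segment. Each of the `nBlocks`
   blocks is convolution (kernel 5, stride 1, same padding) -> batch
   normalization -> ReLU -> max-pool(2) -> dropout; a flatten layer and a
   single linear unit produce the scalar count. Training uses Adam at an
   initial learning rate of 0.001, batch sizes of 256/128/64 for 5/10/20-min
   segments, per-epoch shuffling, the Huber loss with delta 1, learning-rate
   decay by a factor of 2 after 10 epochs without validation improvement,
   early stopping after 30 stagnant epochs, and keeps the weights of the
   epoch with the lowest validation loss.
3. **Subject-level AHI.** A subject's per-segment predictions are averaged
   and mapped to events/hour by a univariate ordinary-least-squares
   correction fitted on training subjects only. The slope absorbs two
   factors at once: the events-per-segment to events-per-hour conversion
   (60 / segment minutes) and the inflation caused by events occurring only
   during sleep while segments cover the whole recording (total sleep time
   < total recording time). The corrected AHI is clamped at zero; severity
   follows the left-closed cutoffs.
4. **Evaluation.** Agreement is summarized by the two-way single-measure
   absolute-agreement ICC, RMSE, and Bland-Altman limits (mean difference
   +/- 1.96 SD); classification by the 4-class confusion matrix, unweighted
   Cohen's kappa, accuracy, and per-cutoff (1, 5, 10 e/h) sensitivity,
   specificity, accuracy, predictive values, and likelihood ratios. Ratios
   with empty denominators are flagged undefined instead of silently zeroed
   so cohort reports always render.
5. **Screening protocol.** Predicted AHI < 1: rule out OSA (with PSG advised
   if symptoms persist); 1-5: refer to PSG; 5-10: treat; >= 10: treat with
   follow-up. `psgReduction()` reports the fraction of the cohort that
   avoids a full PSG.

## Architecture presets and parameters

The full-scale architecture uses 7 blocks of 256 filters on 10-min segments
with dropout 0.1 — the configuration that wins validation-kappa model
selection on large clinical cohorts — but training it is a
workstation-days exercise. The package's working default is the **desk
preset**: 4 blocks of 16 filters on 10-min segments, dropout 0.1, at most 60
epochs. With a few hundred training segments and the prescribed batch size
there are only a handful of optimizer steps per epoch, so the validation
loss reaches its plateau around 50-60 epochs rather than the 300-epoch
ceiling a full-scale run would use; the cap is set just past that plateau
and the patience rules do the actual stopping.
All analyses, tests, and the acceptance script use the desk preset
on simulated cohorts of 80 training / 20 validation / 30 test one-hour
recordings; these sizes keep a full study under a few minutes of CPU time
while leaving enough signal for meaningful agreement statistics.
`selectConfiguration()` implements the validation-kappa grid search over
(segment length, depth, dropout) at any scale.

Choices the architecture description leaves open were fixed as follows:
max-pool size/stride 2 (canonical halving; 7 blocks reduce 2400 samples to
18 taps), same-padding convolutions (keeps lengths pooling-determined and
attribution alignment trivial), He-normal weight initialization, and
batch-norm epsilon 1e-5 with momentum 0.1 running statistics. Per-segment
predictions are deliberately not clamped — the correction absorbs any
offset — only the final AHI is.

## The airflow simulator

No public pediatric airflow corpus can ship with a package, so apneaflow
includes a simulator that defines the study conditions for every test:

- breathing is a sinusoid at 20-30 breaths/min with +/-10% per-breath
  frequency jitter and a slow amplitude envelope (period 30-120 s, depth
  0.1) plus additive Gaussian noise (SD 0.04 of baseline amplitude);
- apneas multiply the signal by a residual gain of 0.02-0.05 and hypopneas
  by 0.35-0.55, satisfying the >= 90% and 30-90% amplitude-reduction
  criteria against the adjacent baseline; 1-s cosine tapers immediately
  outside the annotated window create the abrupt onset/offset transitions
  attribution methods should find;
- event durations are 6-20 s, at least two breath cycles at the slowest
  rate; events are placed only during sleep, at least 10 s apart;
- artifacts (2/h by default) are high-amplitude bursts (3-6x baseline,
  2-5 s) or flatline disconnections (5-15 s), kept >= 35 s away from events
  so the amplitude bands around events stay measurable;
- wake (a fraction drawn from 0.1-0.2 per record) is placed as blocks at
  the start and end of the night plus one mid-night block; because events
  never occur in wake, the naive segment-mean estimate systematically
  overestimates the AHI — exactly the bias the linear correction exists to
  remove;
- every record is bit-reproducible from its seed, and cohort seeds derive
  deterministically from a base seed.

What the simulator does **not** emulate: realistic airflow morphology
(inspiratory/expiratory asymmetry, flow limitation), cardiorespiratory
coupling, desaturation or arousal physiology, sleep-stage architecture, and
vendor-specific sensor characteristics. Green tests therefore demonstrate
that the implementation is correct and that the pipeline recovers a known
ground truth under controlled conditions — not clinical performance on real
thermistor data, which depends on exactly the morphology the simulator
abstracts away.

## Attribution

**Grad-CAM.** For each block, the gradient of the scalar output with respect
to the post-ReLU feature maps is averaged over time to weigh each map; the
ReLU of the weighted sum is the block's heatmap. Feature maps are tapped
post-activation (standard Grad-CAM practice; the tap point is otherwise a
free choice). Because a single layer's resolution is coarse, heatmaps from
all blocks are min-max normalized (in that order: normalize, then resize,
then average — constant maps normalize to zero), linearly interpolated to
the input length, and averaged, giving a final map in [0, 1]. The scalar
regression output is the target; there is no class dimension.

**Deep-SHAP.** Attributions against a background set (by default 50
event-free training segments, quiet breathing as the reference state; an
all-zeros baseline is a one-line alternative). Multipliers are propagated
network-backwards per background and averaged: convolutions, inference-mode
batch-norm, and the head are linear and pass multipliers exactly; ReLU uses
the DeepLIFT rescale rule; each max-pool pair is rewritten as
`max(a, b) = a + relu(b - a)` so only linear maps and elementwise ReLUs
remain. This decomposition makes the completeness identity
`sum(phi) = f(x) - E_b f(b)` hold to machine precision (the only
approximation is the derivative fallback when an activation difference is
below 1e-9), and it is asserted every time an attribution is emitted, with
tolerance `1e-3 * max(1, |f(x) - E_b f(b)|)`.

`localizationScore()` quantifies the qualitative claim that the model
attends to events: mean relevance inside annotated event windows (padded by
5 s so onset/offset transitions count as inside) over mean relevance
elsewhere. On trained models both the Grad-CAM and |SHAP| medians across
event-bearing segments exceed 1.

## Numerical and design notes

- Resampling is rational-factor: zero-stuffing, a Hamming-windowed-sinc
  low-pass applied by FFT convolution, then decimation; non-rational rate
  ratios are approximated to 1e-6 relative by continued fractions. Sub-1 Hz
  tones keep their amplitude to well within 2%.
- Event-to-segment label assignment is by event onset, so an event spanning
  a boundary counts exactly once in any subject-level sum. Whether
  fractional assignment would help is untested (flagged for sensitivity
  analysis).
- The ICC variant is two-way single-measure absolute agreement — the
  standard choice for method-comparison studies — and kappa is unweighted;
  both choices are documented because the metric names alone do not pin
  them down.
- `fitCorrection()` requires non-degenerate predictor variance and at least
  two subjects; `icc()` refuses zero total variance; likelihood ratios with
  zero denominators surface as flagged `Inf`/`NA`.
- A 0-block model configuration is allowed: it is an exact linear model,
  used as a baseline and to verify the attribution engine against the
  analytic Shapley solution for linear models.
- Training determinism assumes single-threaded BLAS; with threaded BLAS
  results are equal only to floating-point reduction order.
- The EDF writer/reader implements the 16-bit EDF core (one channel, 1-s
  records) with a sidecar CSV for annotations; NSRR XML annotation dialects
  are out of scope.

## Known limitations

Segment-level supervision counts event onsets, so boundary-spanning events
blur labels slightly; the simulator's breathing model is a stand-in rather
than a claim of physiological fidelity; the full-scale preset is provided
but not routinely exercised; and confidence intervals for the agreement
metrics are not implemented.

There is also a practical data floor. With the desk preset, cohorts of 12
to 40 one-hour subjects (~70-240 segments) do not train into a
generalizing model — held-out segment correlation stays near zero however
long the optimizer runs — while 80 subjects (~480 segments) reliably do
(held-out segment correlation above 0.8 in the bundled study). Users
applying the pipeline to their own recordings should budget for at least
that much training data per configuration.

## A minimal session

```{r example, eval = FALSE}
seed <- 1L
set.seed(seed)
base <- simConfig(duration = 3600, seed = seed)
train <- simulateCohort(80, runif(80, 0, 20), base, "TR")
base@seed <- seed + 500000L
val <- simulateCohort(20, runif(20, 0, 20), base, "VA")
base@seed <- seed + 1000000L
test <- simulateCohort(30, runif(30, 0, 20), base, "TE")

pipe <- trainPipeline(train, val,
                      presetConfig("desk", segmentMinutes = 10),
                      trainConfig(10, seed = seed))
est <- estimateCohort(pipe$model, pipe$correction, test, 10)
diagnosticReport(est$trueAhi, est$ahi)
recommendScreening(est$ahi)
```
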