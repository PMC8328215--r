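---
title: "Delta-phase to ERP-amplitude coupling: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-phase to ERP-amplitude coupling: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segphase)
```

# The scientific question and the model

Sentence comprehension appears to operate under a time constraint of
roughly 2.7 s on multiword segments. If slow cortical oscillations are the
substrate of that constraint, then the *phase* of the delta-band
(< 4 Hz) EEG at the moment a segment can be closed should predict, on
single trials, whether segmentation happened — observable downstream as
the amplitude of a P600-like positivity when the chosen segmentation is
falsified by the incoming verb. `segphase` implements that inference
chain and a generator of synthetic EEG in which the coupling is true by
construction, so that every stage can be validated against ground truth.

The generator's trial model is deliberately minimal. Each trial contains:

* an ongoing delta oscillation `a_d * w_d(c) * cos(2*pi*f*t + psi)`, with
  per-trial phase `psi ~ Uniform(-pi, pi]` and a spatial weight map
  `w_d`;
* a downstream positivity: a Hanning bump at `verb_onset + 0.456 s` whose
  single-trial amplitude is
  `A = beta0 + beta_rate * 1[FAST] + kappa * cos(phi - phi0) + eps`,
  where `phi` is the delta phase at the segmentation point — the coupling
  the analysis is meant to recover;
* an uncoupled later negativity (a second Hanning bump at
  `verb_onset + 0.856 s`);
* `1/f^alpha` background noise, independent per channel, plus white
  sensor noise;
* a per-trial prosodic envelope proxy: a strictly positive syllable-rate
  modulation, time-compressed for FAST speech, with a contiguous
  zero-valued pause at the segmentation point when a boundary is present
  (pause defaults 214 ms FAST / 342 ms SLOW).

Two properties are load-bearing for inference and are asserted by tests:
phases are uniform (so the trial-shuffled surrogate null is exactly
exchangeable), and the positivity's amplitude — not the ongoing
oscillation itself — carries the coupling into the ERP window, because
the ERP branch of preprocessing high-passes at 1 Hz and thereby removes
the delta component from the single-trial amplitudes. Without that
high-pass, any voltage sampled after the segmentation point would
correlate with pre-segmentation phase trivially, for coupled and
uncoupled components alike; with it, the uncoupled negativity is a true
negative control.

## What the defaults mean

The defaults of `simulation_config()` are the package's reference study
conditions; they were chosen once, for realism, and the acceptance suite
runs against them.

| parameter | default | why |
|---|---|---|
| `delta_freq` | 0.37 Hz | one cycle = 2.7 s, the hypothesized segmentation window; configurable because the band, not the line, is the claim |
| `delta_amplitude` | 12 uV | slow-wave amplitudes at centro-parietal sensors |
| `coupling_strength` (kappa) | 4 uV | single-trial ERP modulations of a few microvolts |
| `rate_effect` | 4 uV | FAST-minus-SLOW positivity difference; strong, scalp-wide ERP effect |
| `baseline_amplitude` | 6 uV | P600-like base amplitude |
| `p600_latency`, `p600_width` | 0.456 s, 0.15 s | latency of the reported peak; a narrow positivity (the significant window of such effects spans tens of ms) |
| `neg_latency`, `neg_width`, `neg_amplitude` | 0.856 s, 0.26 s, -5 uV | the later broad negativity, uncoupled |
| `noise_sd`, `noise_exponent` | 6 uV, 1 | 1/f background dominating single-trial EEG |
| `sensor_noise_sd` | 2 uV | white measurement noise |
| `amp_noise_sd` | 1.5 uV | trial-to-trial evoked variability beyond the phase coupling |
| `boundary_pause_s` | 0.214 / 0.342 s | FAST / SLOW boundary pauses |
| event times | SLOW: segmentation point 2.7 s, verb 3.5 s; FAST: 1.782 s, 2.31 s | FAST = SLOW x 0.66 (the ratio of the two rate-manipulation factors); the FAST verb arrives before 2.7 s |
| map widths | delta 0.5, p600 0.5, neg 0.6 | after common-average referencing a montage retains only the *deviation* of a weight map from its mean; these widths keep the delta field spatially differentiated (so phase survives re-referencing at the map peak) and give the positivity a clear single-electrode peak with several positive neighbors |
| `snap_maps` | TRUE | component topographies peak exactly at an electrode, the way scalp ERP peaks are reported |

What the generator does *not* emulate: blink/muscle artifacts, phase
drift or nonstationarity of the delta rhythm (each trial's oscillation is
a pure sinusoid), entrainment of delta to the envelope, volume-conduction
head modeling (topographies are 2-D Gaussians on the layout disc), and
latency jitter of the evoked components. Passing tests therefore show
that the chain recovers coupling *when the generative assumptions hold*;
they do not show robustness to artifacts or to oscillatory
nonstationarity in real recordings.

# Signal conditioning

Filtering is zero-phase (forward–backward) Butterworth, designed in
second-order sections by bilinear transform of the analytic prototype: at
4 Hz on 100-Hz data a 10th-order design in expanded polynomial form is
numerically fragile, while the biquad cascade is exact and stable. The
two-pass amplitude response is the single-pass response squared, so the
gain at the cutoff is 0.5. Edges are handled by odd-reflection padding of
about three impulse-response lengths, and the column mean is removed
before filtering (a DC offset would otherwise excite a long start-up
transient under zero initial conditions).

Resampling applies an anti-alias zero-phase lowpass at 0.4 x the target
rate, then decimates exactly for integer ratios and uses cubic-spline
interpolation for non-integer ones (e.g. 250 to 100 Hz). Epochs follow a
half-open `[tmin, tmax)` convention at sample resolution — a -0.5..1.5 s
epoch at 250 Hz has exactly 500 samples — and events are stored in
seconds, converted to samples only at use.

The instantaneous phase is the argument of the FFT analytic signal, under
the cosine convention (phase 0 at the peak of a cosine). One numerical
point deserves emphasis: on a 6-s epoch, a 0.37-Hz sinusoid completes a
non-integer number of cycles, and the implicit periodicity of the FFT
then leaks enough to distort mid-epoch phase by up to ~0.26 rad. Each
trace is therefore extended on both sides by autoregressive (Burg)
extrapolation before the transform — an AR(2) continues a sinusoid
exactly; the default AR(3) adds a pole for residual offset — which brings
the worst-case mid-epoch error below 0.04 rad. Higher orders are avoided
deliberately: surplus poles of an oversampled smooth signal can sit
marginally outside the unit circle and blow up over a long extrapolation.
If an extension still misbehaves, the order is reduced, then the poles
are damped inward (phase-coherent, decaying), then constant padding is
the last resort.

# ERP statistics

The FAST-vs-SLOW contrast is tested with a spatio-temporal cluster-based
permutation test on the per-participant condition means in the 0.15–1 s
post-verb window: samplewise paired t statistics thresholded at
`qt(0.975, n - 1)` (the conventional default for this test family, which
the analysis descriptions it follows leave implicit), clustered under the
relation "same channel and adjacent samples, or same sample and
neighboring channels", with clusters spanning fewer than 3 distinct
channels discarded. The null distribution of the per-sign maximum cluster
mass is built from random sign flips of the participant difference maps —
the exchangeability a paired design affords — and each cluster's
Monte-Carlo p is `(1 + #(null >= mass)) / (1 + B)`, doubled for two-sided
control and capped at 1. An exhaustive mode enumerates all `2^n` sign
patterns for n <= 16 and is used as the exactness oracle in tests. The
"≥ 3 channels" rule is read literally (a cluster must contain three
distinct channels); the per-sample neighbor-count alternative is not
implemented.

The amplitude mask for the coupling analysis is the electrode and time
point *at which the ERP peaks* — the maximum |grand-average difference|
within the winning cluster, not the maximum |t|. At a dozen participants
the t map's denominator is a noisy SD estimate, and a low-variance
channel with a much smaller effect can out-t the true peak; the
amplitude localizer is both the natural reading of "where the ERP peaked"
and empirically far more stable. `extract_peak(by = "t")` retains the
alternative. Degenerate zero-variance cells are flagged and excluded from
cluster formation with a warning.

# The phase-amplitude test

Within participant, across trials, at every electrode and sample in the
-0.5..0 s pre-segmentation window, the circular–linear correlation
between delta phase and the single-trial amplitude at the ERP peak is
computed from the three Pearson correlations among `cos(theta)`,
`sin(theta)` and `x`; it equals `max_phi |cor(x, cos(theta - phi))|`, a
variational identity the tests exercise against a 10,000-point grid.
Coefficients are Fisher-z transformed and averaged across participants.

The null is a trial-reassignment surrogate: per permutation, one shuffle
of the amplitude vector per participant, applied identically across all
(channel, sample) cells so the spatial and temporal dependence of the
data survives into the null; the group null is the per-permutation
average of the participants' surrogate z. The comparison is one-sided
(`null >= observed`) because r is nonnegative by construction, p uses the
plus-one rule, and Benjamini–Hochberg FDR at q = 0.05 runs over all cells
of the window (no pooling across ERP masks). Alternatives the package
deliberately exposes rather than hides: amplitudes may be taken as
windowed means (`half_width > 0`) instead of the single peak sample, and
the per-participant z at the peak is reported alongside the group mean
(the group aggregation — mean z across participants against a matched
permutation null — is this package's definition; reporting a single mean
z leaves several aggregations defensible).

The preferred phase is estimated in closed form from the regression of
`x` on `(cos theta, sin theta)`. It is reported twice: at the FDR peak
cell, and referred to the locking event — at the peak channel, at the
sample nearest t = 0, combined across participants by a circular mean
weighted by each participant's correlation. The second number is the one
to compare with a generative `phi0`: at a pre-event peak cell the
oscillation's deterministic phase advance `2*pi*f*t` shifts the cell-level
estimate away from the coupling phase, and channels on the negative side
of an average-referenced topography see the oscillation sign-flipped
(phase shifted by pi) — both effects vanish at the event-referenced peak
channel.

# The coherence control

If delta phase merely entrained to prosody, the phase–P600 correlation
would be confounded by the acoustic differences between speech rates. The
control computes magnitude-squared coherence between the per-trial
stimulus envelope and the delta-band EEG at the peak electrode on a
segment of one full delta cycle (±1.5 s around the correlation peak),
treating trials as realizations with a single Hann taper each (~0.33-Hz
resolution, about 12 bins below 4 Hz), averages coherence over the 0–4 Hz
band excluding DC (the envelope's positivity would dominate the DC bin),
and compares FAST against SLOW with a tie-corrected signed-rank z (no
continuity correction; this is the statistic form reported for such
controls). In the generator delta phase is independent of the envelope by
construction, so the control should be — and in ≥ 90% of simulated runs
is — non-significant; no coherence bias correction is applied because
simulated trial counts are balanced by design.

Two analytic caveats found while testing and worth recording: the
coherence estimator is invariant to a *common* rescaling of either
signal but not to per-trial rescaling (trial weights change), and the
"fixed delay leaves coherence at 1" identity is exact only without a
taper (tapering breaks shift equivalence); `taper = "none"` exists for
such fixtures.

# Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → prep → ERP → phase → coherence. Stage
order is fixed — the ERP peak defines the amplitude mask — and a run with
no significant positive cluster stops with status
`"no-positive-cluster"` unless the configuration supplies a
`forced_peak`. All randomness descends from one master seed (participant
and surrogate seeds are drawn from it by documented `sample.int` splits),
so a configuration plus seed reproduces results byte for byte; a run
directory carries a config-hash manifest and per-stage caches so
completed stages are reused.

The test suite validates the chain at sizes chosen to keep a full run in
the tens of minutes on one core while leaving comfortable statistical
margins: type-I calibration on 200 null datasets (8 participants, 24
trials each, 10 channels, 500 permutations — the any-cluster rate must
sit inside the exact binomial 95% CI around 0.05); parameter recovery on
20 datasets of 12 participants x 240 trials (peak channel and latency,
FDR mask location, preferred phase within 0.3 rad); selectivity on 20
null-coupling runs; and a monotone dose–response over
kappa in {0, 1, 2, 4} uV with 20 seeds per level (8 participants x 160
trials each). The full-scale
reference analysis (10,000 permutations) is the default of the exported
functions; the demo profile used by `scripts/acceptance.R` runs 1,000.

# Known limitations

* The simulator's delta rhythm is a stationary sinusoid per trial;
  nothing here measures robustness to frequency drift or phase slips.
* Topographies are Gaussian on an abstract disc layout; no forward model,
  no re-reference to an estimated zero potential (the common average is
  used; with synthetic data carrying no head geometry, a leadfield-based
  reference has nothing to anchor to).
* The coherence control consumes a synthetic envelope; extracting a pitch
  envelope from audio is out of scope.
* `wilcoxon_signed_rank()` uses the tie-corrected normal approximation
  throughout; for fewer than ~10 pairs an exact test would be preferable
  (at n = 8 the approximation can differ from exhaustive enumeration by
  up to ~0.07 in p).
* Mixed-effects behavioral modeling, artifact preprocessing (ICA,
  bad-channel handling) and stimulus acoustics are intentionally outside
  the package: it begins at clean epoched EEG.
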