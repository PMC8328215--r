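# segphase

Does the phase of a slow (delta-band, < 4 Hz) EEG oscillation at the moment
a listener can close a multiword segment predict, trial by trial, the
amplitude of the P600-like positivity that appears downstream when that
segmentation turns out to be wrong? `segphase` implements the full
inference chain needed to ask that question — and a ground-truth simulator
to validate every link of it — in R.

The chain, in the order the pipeline runs it:

1. **Synthetic phase-coupled EEG** (`simulation_config()`,
   `generate_dataset()`): multi-participant recordings containing an
   ongoing delta oscillation with per-trial uniform random phase
   `phi_trial`, a downstream positivity whose single-trial amplitude is

   `A = beta0 + beta_rate * 1[FAST] + kappa * cos(phi_trial - phi0) + eps`,

   an uncoupled later negativity, 1/f background plus sensor noise, and a
   per-trial prosodic envelope proxy with an optional boundary pause. The
   true phases and amplitudes are returned as a ground-truth table.
2. **Signal conditioning** (`prep_participant()` and friends): common
   average reference; zero-phase Butterworth filtering in second-order
   sections (1-Hz two-pass 6th-order high-pass for the ERP branch, 4-Hz
   two-pass 10th-order low-pass for the phase branch); resampling to
   100 Hz; epoching around the disambiguating-verb onset (−0.5..1.5 s,
   baseline 0–150 ms) and around the segmentation point (−3..3 s);
   Hilbert instantaneous phase with autoregressive boundary extension.
3. **ERP statistics** (`cluster_permutation_test()`): spatio-temporal
   cluster-based permutation test of the FAST-vs-SLOW contrast in the
   0.15–1 s window (paired t maps, threshold `t_{0.975}`, participant-level
   sign flips, two-sided with ≥ 3-channel clusters); `extract_peak()`
   locates the electrode and time point where the positivity peaks.
4. **Phase–amplitude coupling** (`group_phase_amplitude_test()`): at every
   electrode and sample in the −0.5..0 s pre-segmentation window, the
   circular–linear correlation

   `r = sqrt((r_cx^2 + r_sx^2 - 2 r_cx r_sx r_cs) / (1 - r_cs^2))`

   between delta phase and the single-trial amplitude at the ERP peak,
   Fisher-z transformed, averaged over participants, and tested against a
   trial-shuffled surrogate null (10,000 permutations by default) with
   Benjamini–Hochberg FDR control; `estimate_preferred_phase()` recovers
   the coupling phase `phi0` in closed form.
5. **Prosody control** (`mscoherence_across_trials()`,
   `wilcoxon_signed_rank()`): magnitude-squared coherence between the
   stimulus envelope and the delta-band EEG at the peak electrode over a
   full delta cycle (±1.5 s), band-averaged over 0–4 Hz and compared
   between speech rates with a signed-rank test.

`run_pipeline()` chains all stages deterministically from one master seed,
with a manifest-driven run directory that caches completed stages. A thin
command-line wrapper lives at `inst/cli/segphase.R`
(`Rscript segphase.R [simulate|erp|phase|coherence|all] --config cfg.yaml
--out dir --seed N`).

## Worked example

```r
library(segphase)

cfg <- pipeline_config(
  sim = simulation_config(n_participants = 8, n_trials_per_condition = 40,
                          n_channels = 16, sampling_rate = 250,
                          coupling_strength = 4, preferred_phase = pi / 4,
                          seed = 1),
  erp = list(n_perm = 1000), phase = list(n_perm = 1000), seed = 1)
res <- run_pipeline(cfg)
res
#> pipeline_result: status = ok
#>   ERP positive-cluster peak: E03 at 0.440 s
#> phase_corr: 8 participants, 16 channels x 50 samples, 1000 permutations
#>   FDR mask: 322 cells (q = 0.05); peak E03 at -0.500 s, mean z = 0.222
#>   preferred phase: -0.272 rad at the peak cell, 0.857 rad at the locking event
#>   coherence control: Wilcoxon z = 1.400, p = 0.161
```

Reading the output: the FAST-vs-SLOW cluster test finds the simulated
positivity (cluster-level p ≈ 0.002) peaking at electrode E03 — the
simulated map's center — 0.44 s after verb onset (truth: 0.456 s, i.e.
within 2 samples at 100 Hz). Masked at that peak, delta phase before the
segmentation point correlates with single-trial amplitude (mean Fisher's
z at the peak cell ≈ 0.22, 322 FDR-significant cells, all inside the
−0.5..0 s window). The preferred phase at the peak cell sits earlier in
the cycle than the generative `phi0` because the peak cell precedes the
segmentation point (the oscillation advances by `2*pi*f*t` in between);
referred to the locking event it lands at 0.857 rad, within 0.08 rad of
the simulated `phi0 = pi/4 = 0.785`. The envelope–EEG coherence control
shows no FAST/SLOW difference (p = 0.16), as it should when delta phase
is independent of the envelope by construction.

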