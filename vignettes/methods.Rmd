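---
title: "Methods: laminar event detection, unit metrics, and coupling maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar event detection, unit metrics, and coupling maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hippomap)
```

This vignette documents the models and numerical choices behind each stage
of the pipeline: what is computed, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The probe lattice

The canonical map (`build_default_probe_map()`) is eight shanks at 300 µm
pitch, each carrying two columns of 64 electrode rows at 30 µm vertical
pitch (four 32-pixel frontend modules per shank, 14 µm square contacts,
27 µm column separation). Coordinates put `y = 0` at the topmost electrode
row, increasing toward the tip, and `x = 0` at shank 0's left column.
Channel ordering is shank-major, then row-major, then column; the columns
are vertically aligned (a staggered layout can be built with
`build_probe_map()` by editing coordinates, but is not the default).

Two accounting subtleties: the geometric column length of 64 rows at 30 µm
plus a 14 µm contact is 1904 µm, slightly short of the device's nominal
active recording length of 1924 µm; the nominal value is carried as map
metadata and used for the recording-span product (2141 × 1924 µm ≈
4.12 mm²). The 27 µm column separation is likewise chosen so the
edge-to-edge lateral span reproduces the printed 2141 µm.

## Sharp-wave ripple detection

The detector operates on a single pyramidal-layer channel:

1. Zero-lag band-pass, 80–250 Hz, as a **difference of Gaussians**: two
   Gaussian low-pass kernels with −3 dB points at the band edges,
   subtracted and renormalised to unit gain at the band centre. The
   symmetric FIR kernel has exactly linear phase (no group delay) and a
   structural DC zero.
2. The **normalisation envelope**: the band-passed signal is amplitude
   clipped at 4 SD (SD of the band-passed signal; whether the SD of its
   rectified version was meant is not decidable from the source methods,
   and this reading is flagged here), rectified, and low-passed at
   `mean(band)/p` with p = 3 cycles — 55 Hz for 80–250 Hz. Its mean and SD
   define the score scale; clipping keeps large events from inflating it.
3. The **detection envelope** is the same pipeline without clipping.
   Samples whose normalised score exceed 4 mark event cores; cores are
   expanded to where the score falls below 1 SD; events whose expansions
   overlap are merged.
4. **Minimum duration.** Events are discarded unless the span from the
   first to the last crossing of the detection threshold (4 SD) reaches
   15 ms. We apply the rule to this suprathreshold span rather than to the
   1 SD expansion deliberately: the envelope smoothing kernel alone
   stretches any detectable 10 ms burst beyond 15 ms at the 1 SD level, so
   the expanded-extent reading cannot reject sub-criterion bursts, and it
   also passes a steady trickle of threshold-grazing noise events
   (measured ≈ 4.5/min on the noise model). With the suprathreshold-span
   reading, 10 ms bursts are always rejected and the false-positive rate
   on pure noise is essentially zero, while 60 ms events at realistic SNR
   are kept. The reported event boundaries are still the 1 SD expansion,
   and the peak is the envelope maximum within them.

The envelope smoothing kernel is a Gaussian with its −3 dB point at the
cutoff, matching the Gaussian family of the band-pass. All thresholds act
on SD-normalised quantities, so the detector is invariant to amplitude
scaling of the input.

## Dentate spikes

Both channels (hilus and molecular layer) are band-passed 2–50 Hz with the
same DoG filter. Local maxima of the hilus-minus-molecular difference above
a 2 SD prominence screen (a configurable pre-criterion; the criterion
itself is the molecular rule) are candidates, subject to a 100 ms minimum
separation. A candidate passes when the mean molecular-layer LFP over the
event crest (±5 ms around the difference peak) is lower than its own mean
over the −36 to −16 ms baseline by more than 0.19 mV. The crest window is
intentionally tight: averaging over a wider window scales the measured
drop down by the pulse's shape factor, so a 0.30 mV deflection would be
reported as ~0.19 mV and the criterion would no longer track the
deflection amplitude. The reported peak time is the maximum of the
wide-band hilus LFP within the candidate window. Candidates whose baseline
window precedes the recording are skipped with a warning.

## Event-triggered averages and CSD

`event_triggered_average()` is the arithmetic mean of aligned snippets;
events whose padded window leaves the recording are dropped and counted.
The CSD along one shank column with uniform pitch `h` is the negative
second spatial difference, `−(V(i−1) − 2V(i) + V(i+1))/h²`, in arbitrary
units proportional to µV/µm² (tissue conductivity is not modelled, as no
value is available); sinks are negative. Boundary rows duplicate the edge
potentials (Vaknin padding) so the map spans all 64 rows — a conventional
choice, not one taken from the source. No spatial smoothing is applied
before differencing by default; a 3-point Hamming smoother is available
(`smooth = TRUE`).

## Unit metrics

Footprints are spike-triggered mean waveforms over a 1 ms-before to
2 ms-after window. Waveform work runs on the high-passed (> 300 Hz)
segment (`highpass_segment()`), as spike-sorting pipelines do; the slow
LFP otherwise tilts the waveform baseline and inflates trough-timing
variance.

- **Trough-to-peak** is measured on the peak-amplitude channel with
  parabolic sub-sample refinement; ties in peak-to-peak amplitude break to
  the lowest channel id.
- **The ACG fit** follows the triple-exponential convention,
  `max(c(exp(−(t−t₀)/τ_decay) − d·exp(−(t−t₀)/τ_rise)) +
  h·exp(−(t−t₀)/τ_burst) + r, 0)`, least-squares on the autocorrelogram
  expressed as a conditional rate (Hz), from a fixed deterministic start
  with box constraints (L-BFGS-B), so identical spike trains give
  identical fits. τ_rise of the fitted model is the rise-time statistic; a
  non-convergent fit yields NaN and the unit falls through to the
  waveform-only rule (classified pyramidal if the latency is long). The
  fit requires ≥ 500 spikes by default — below that the ACG is too noisy
  for a stable τ_rise.
- **Classification cascade**: narrow interneuron if trough-to-peak
  < 0.425 ms; else wide interneuron if τ_rise > 6 ms; else pyramidal.
- **Bursts** are maximal runs of ≥ 2 spikes with consecutive ISIs < 9 ms.
- **Peri-event histograms** are counts of spike−event lags divided by
  (number of events × bin width), in Hz; bins must tile the window
  exactly.

## Backpropagation

Within ±250 µm axially on the soma's shank, channels whose trough depth
exceeds 12% of the dominant trough contribute. Distance is axial only and
same-shank only — at 300 µm shank pitch a somatic footprint cannot
credibly span shanks. Trough times are refined to sub-sample precision by
cubic-spline interpolation around the minimum (at 20 kS/s the 50 µs sample
period would otherwise quantise delays coarsely relative to the 30 µm
pitch; 3-point parabolic interpolation leaves a periodic few-µs bias that
is visible at shallow slopes). Before timing, each waveform is low-passed
at 3 kHz — above the spike's spectral content — which roughly halves the
timing variance on weak channels.

Delays are re-referenced to the earliest trough, whose channel is reported
as the putative initiation site (ties break to the channel closest to the
soma, then the lowest id). Delay (ms) is regressed on absolute axial
distance from the soma (mm), separately above and below it, with a free
intercept and weights proportional to squared trough amplitude (trough
timing variance scales as 1/amplitude²). "Distinct slopes above and below"
is operationalised as ≥ 3 channels strictly per side. A side with slope
≤ 0.1 ms/mm is treated as non-propagating — apparent speeds above
10 mm/ms are indistinguishable from simultaneity at this timing
precision — and classification is ascending (above only), descending
(below only), curved (both), or undetermined.

## Spike–LFP coupling and coherence

Instantaneous phase is the analytic-signal phase of the LFP filtered in a
5 Hz-wide Gaussian band (implemented in the frequency domain, zero-phase;
positive frequencies doubled). The PLV is the resultant length
`|mean(exp(iφ))|` of phases looked up at the nearest sample to each spike.
Maps cover 30–200 Hz in 5 Hz steps — the step matching the stated
bandwidth — and are optionally smoothed by replacing each value with the
mean of its 2 × 2 lattice block (both columns × two adjacent rows), the
only contiguous 4-pixel neighbourhood on a two-column shank. Units need
≥ 200 spikes: the small-sample expectation of the null PLV is
`sqrt(pi/(4n))`, so maps from few spikes are dominated by bias. All spikes
are used (no rate-matched subsampling); subsample externally if states
must be compared at matched counts. Two properties of the null are worth
keeping in mind when reading maps. First, a 5 Hz-wide band decorrelates
over roughly 1/bandwidth ≈ 200 ms, so for units firing much faster than
the bandwidth the spike-phase samples are serially correlated and the
effective `n` is smaller than the spike count — null values inflate
accordingly. Second, the 99th percentile of the smoothed null map is
≈ 1.475/sqrt(n) (mean of four independent Rayleigh variates), so about 1%
of pixels of a genuinely uncoupled map sit above 1.5/sqrt(n) by
construction; treat that level as a per-pixel null quantile, not a hard
ceiling. On rows carrying a strong coherent oscillation, the four pixels
of a smoothing block see the same signal and smoothing does not reduce
the null there.

Coherence maps Gaussian-band-pass all channels (magnitude response centred
on the band midpoint, half-amplitude at the edges), then estimate
magnitude-squared coherence against the reference channel from
interval-averaged cross-spectra — each interval one mean-subtracted,
Hann-tapered segment — averaged over the band. Self-coherence is exactly
1; the estimator bias for independent signals is ≈ 1/(number of
intervals). `select_swr_intervals()` supplies up to 100 non-overlapping
1 s windows centred on ripple peaks, earliest first. Brain-state splits
enter as user-supplied interval sets; state detection is out of scope.

## The synthetic-data generator

`simulate_recording()` sums, per channel:

- **Background noise**: two independent frequency-domain band-limited
  Gaussian components rescaled to 16.45 µV RMS in 0.1–300 Hz and 6.67 µV
  RMS in 300–5000 Hz — the device's measured figures. The in-band spectrum
  is flat; no 1/f shaping, no shared spatial structure between channels.
- **Ripples**: a 150 Hz cosine under a Gaussian envelope
  (σ = duration/4, so ~95% of the event mass lies inside the nominal
  60 ms) on pyramidale rows, with a concurrent negative sharp wave
  (Gaussian in depth over radiatum rows, twice the temporal width) that
  produces the radiatum sink flanked by sources in the CSD. Ripple
  amplitude is parameterised as the in-band SNR: peak amplitude equals
  `ripple_snr` × SD of the 80–250 Hz band-passed background on the
  mid-pyramidale calibration channel (default 6). With the default
  noise this puts detection scores near 8 SD.
- **Dentate spikes**: a positive hilar Gaussian pulse (duration 40 ms by
  default) with an opposite-sign molecular-layer pulse whose amplitude is
  the `ds_mol_amp_mv` parameter (0.30 mV default, i.e. above the 0.19 mV
  criterion).
- **Gamma sources**: constant-frequency sinusoids with a random initial
  phase, confined to their laminar rows. A fixed-frequency oscillator
  makes the spike-phase ground truth exact; real gamma is
  amplitude-modulated and frequency-wandering, so PLV recovery here tests
  the estimator, not robustness to non-stationarity.
- **Units**: Poisson (or von Mises phase-locked, via the Best–Fisher
  sampler) spike trains with a 1.5 ms refractory, stamped as a biphasic
  template (Gaussian trough, 0.35 × trough positive peak at the
  configured trough-to-peak time; peak-to-peak 82 µV at the soma by
  default). Amplitude decays exponentially with Euclidean distance
  (length constant 60 µm default) and the trough time shifts linearly
  with axial distance at the configured ms/mm slopes — the
  backpropagation ground truth. Templates are evaluated continuously per
  spike, so sub-sample delays survive averaging.

Samples are kept in double precision in memory; `write_recording()`
quantises to signed 16-bit at 0.2 µV/bit. Everything is driven by one
seed: identical configs give bit-identical recordings.

What passing tests show, and what they do not: recovery on this generator
validates the estimators under known ground truth with Gaussian,
spatially independent noise and stationary oscillations. It does not
exercise electrode drift, correlated (1/f, spatially coherent) noise,
spike-sorting errors, or non-stationary gamma — conclusions about real
recordings still require the usual controls.

## Problem sizes and test design

The validation suite runs on reduced single-shank maps (4–32 rows at the
full 30 µm pitch; the geometry rules are identical to the full 1024-channel
map) and recordings of 20–60 s: event-detection recovery uses 60 s with 20
injected ripples; the backpropagation battery uses ~3000 spikes per unit
(30 s at 100 Hz) so that the slope estimator's standard error (~0.007
ms/mm) leaves a 3σ margin at the shallowest slope tested (0.2 ms/mm); PLV
calibration uses 10⁴ von Mises phases per κ, and the map-level null uses a
150 s, 1.25 kS/s segment with a 1.6 Hz unit — sparse relative to the 5 Hz
band width, so successive phase samples are effectively independent.
These sizes were chosen so each recovery statistic
has a comfortable margin relative to its tolerance while the full suite
stays convenient to run on a laptop.

## Known limitations

- The detector's duration rule and the dentate-spike crest window are the
  package's own readings of under-specified steps; both are parameters
  (`ripple_params()`, `ds_params()`) and can be changed.
- 1D column-wise CSD only; no inverse-CSD (kCSD) or ICA decomposition.
- The generator's laminar profiles are smooth Gaussians with free
  amplitudes; they reproduce the qualitative source–sink–source geometry,
  not quantitative current densities.
- Spike sorting, drift correction, and anatomical region assignment are
  inputs, not outputs, of this pipeline.
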