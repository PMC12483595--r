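---
title: "Detecting mycelial electrical activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mycelial electrical activity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycovolt)
```

## The measurement problem

A fungal mycelium growing across a pair of embedded differential electrodes
produces extracellular voltage fluctuations of microvolt order. A slow
24-bit logger digitises each electrode pair with a per-channel conversion
time of 60 ms, i.e. a sampling rate of $1/0.060 \approx 16.7$ Hz, over
experiments lasting days. Inside a Faraday cage the hyphal density at the
electrodes cannot be observed, so single-event ("action-potential-like")
characterisation is not attempted; instead the analysis works entirely in
the frequency domain:

1. **Clean**: missing samples (dropped conversions; the logger pausing when
   the plate is opened to add a chemical stimulus) are excised and the
   remaining samples concatenated.
2. **Visualise**: a short-time Fourier transform (STFT) with a four-term
   Blackman–Harris window of 1024 samples and 80% overlap; the squared
   STFT amplitude is the spectrogram. Non-inoculated channels show only a
   sub-1 Hz background; colonized channels additionally develop components
   above 1.5 Hz (most prominently near 2 Hz) once the mycelium bridges the
   electrodes, roughly four days after inoculation.
3. **Quantify**: for a 3-day window on either side of the induction event,
   each channel's one-sided power spectral density (PSD) is integrated over
   the analysed band to a single average power in V². Before integration
   the segment is low-pass filtered at 4 Hz and resampled to 8 Hz, since
   essentially all signal power lies below 4 Hz.
4. **Compare**: per-channel powers are averaged within condition groups,
   normality is checked with the Shapiro–Wilk test, groups are compared
   with Welch's *t*-test (no equal-variance assumption), and the effect is
   summarised as a percent change
   $\left(\bar P_{\text{treated}}/\bar P_{\text{control}} - 1\right) \times 100$.

The percent-change formula is not stated alongside the published
comparison table; it is adopted here because it reproduces all nine
printed rows of that table from their printed group means to within the
precision those means are printed at (see "Reproducibility limits" below).

## Spectral estimation choices

**Window.** The four-term Blackman–Harris taper (coefficients 0.35875,
0.48829, 0.14128, 0.01168) is generated in the periodic convention, peak
exactly 1 at sample $n/2$. Its −92 dB sidelobes make leakage from the large
sub-1 Hz background into the 1.5–8 Hz signature band negligible, which
matters more here than the wider main lobe.

**Frame geometry.** With window length $w$ and overlap fraction $v$, the
hop is $\mathrm{round}(w(1-v))$ (205 samples for the defaults) and a trace
of $N \ge w$ samples yields $\lfloor (N-w)/h \rfloor + 1$ frames. Frames
never wrap or pad: a segment shorter than one window is an error (or, in
group comparisons, the channel is excluded with a logged reason) rather
than being zero-padded, because padding biases the PSD.

**PSD normalization.** The published method says only that average power
is obtained "by integrating the PSD", without fixing a convention. The
estimator here is a Welch-averaged tapered periodogram using the same
Blackman–Harris/1024/80% framing as the spectrogram, scaled by the window
power gain $f_s \sum_k w_k^2$ and one-sided doubled, so that the integral
of the PSD over all frequencies equals the signal's mean square. That
variance identity fixes every constant; it is asserted in the tests (white
noise of variance $\sigma^2$ integrates to $\sigma^2$ within 10%; a unit
sinusoid's band power is 0.5 V² within 5%).

**Band integration.** A bin contributes to a band $[f_1, f_2)$ if its
centre lies in the half-open interval. Adjacent bands sharing an edge are
then exactly additive. The full analysed band after resampling is taken as
$[0, 4)$ Hz; the sub-bands $[0, 1.5)$ (background) and $[1.5, 8)$
(colonization signature, evaluated on pre-resample data) are available as
options.

**The published table's "Log10" caption.** The caption of the published
summary table mentions PSD values on a logarithmic scale, yet tabulates
linear-magnitude means (e.g. 3.44429×10⁻⁷). This package computes and
reports linear-scale means and treats the log mention as a display detail
of the original figures; no log transform is applied before averaging or
testing.

## Anti-alias filtering and resampling

The 4 Hz cutoff is exactly the Nyquist frequency of the 8 Hz target, where
an ideal brick-wall filter is unrealisable. The realised filter is a
linear-phase FIR low-pass (Hamming-windowed design) whose transition band
occupies the top `transition_fraction` (default 5%) of the cutoff: the
half-amplitude point sits at 3.9 Hz, the passband below 3.8 Hz is flat
within ±0.5 dB (the Hamming design's ripple is far smaller), and the stop
band beyond 4 Hz is attenuated by more than 40 dB; the tests assert those
bounds on generated tones. It is applied in the frequency domain using the zero-centred impulse
response, i.e. with exactly zero phase, because group delay would shift
event times used for segmentation. Edges are odd-reflection padded.

Resampling from $1/0.060$ Hz to 8 Hz is a rational factor: the package
finds the best rational approximation $p/q$ to the rate ratio (12/25 here,
exact) and resamples by spectral truncation at the new Nyquist frequency
in the same FFT pass — an exactly band-limited, zero-phase operation. The
realised rational factors, the achieved output rate and its relative error
(zero when $q$ divides the padded length, and logged if above $10^{-6}$)
are recorded in the `resample_info` attribute of the result, together with
the realised filter edges, so every run is auditable. FFT lengths are
padded to $q$ times a 5-smooth number, keeping the transforms $O(n\log n)$
for any segment length.

An alternative implementation would be a polyphase time-domain resampler;
the spectral route was chosen because it is exactly band-limited, exactly
zero-phase, and substantially faster in pure R for the multi-million-sample
segments these recordings produce.

## Cleaning and time bookkeeping

Missing-sample runs are removed, not interpolated, following the stated
analysis procedure. Two consequences are handled explicitly:

- Channels are kept aligned: an index missing in *any* channel is removed
  from *every* channel, so one compressed time base serves the whole set.
  Each removed run's original position and length is kept in a gap log.
- Times anchored to events (the induction time) are remapped onto the
  compressed time base, so a 3-day window "before induction" still ends at
  the induction event after cleaning. Segment windows clipped by more than
  1% of their nominal length raise a warning.

Cleaning happens before segmentation; a gap straddling the induction
boundary therefore shortens the neighbouring windows slightly instead of
shifting them, which for the 600-sample (~36 s) logger pause is a
negligible fraction of a 3-day window.

## The synthetic experiment generator

No raw recordings ship with the package; a seeded generator produces
multichannel experiments with the statistical structure the analysis
assumes, so the whole pipeline is exercisable end to end. The default
scenario mirrors the study design: 24 inoculated and 8 non-inoculated
channels, 10-day recordings, colonization onset at day 4 (with a half-day
amplitude ramp), chemical induction at day 7, and a 600-sample missing-data
gap at induction where the logger pauses.

Per channel the signal is a sum of:

- **Background drift** (all channels): a stationary AR(1) process with
  pole 0.98 at the acquisition rate, which concentrates its power below
  ~0.1 Hz — the simplest stationary model consistent with a "sub-1 Hz
  background". RMS 142 µV.
- **White noise floor** (all channels): 30 µV RMS.
- **Colonization signature** (inoculated channels only): a 2 Hz tone
  (804 µV peak) plus weak band-limited noise in 1.5–8 Hz (30 µV RMS),
  switched on at the colonization onset and modulated after induction by
  the treatment response.
- **Treatment response**: `none`, `full_suppression` (signature removed),
  `transient_dent` (amplitude halved for half a day), or
  `suppress_recover` (suppressed for 18 h, then a linear ramp back —
  the sodium-azide-like phenotype).

Amplitudes are calibration choices, not measurements: no absolute µV
spectra are published for these signals. They were fixed once so that
0–4 Hz segment powers land at the magnitudes the published table prints
(≈ 2×10⁻⁸ V² for controls, ≈ 3.4×10⁻⁷ V² for colonized channels before
induction, a ratio of order +1500%). A per-channel lognormal amplitude
jitter (sdlog 0.15 on each component) supplies between-replicate
biological variability; it keeps the pooled fungi-vs-control test's power
essentially 1 while making group variances non-degenerate.

Each channel draws from its own RNG stream seeded deterministically from
`(master_seed, role, index)`, so traces are reproducible independently of
generation order, and identical configurations produce byte-identical
recording files.

**What the generator does not emulate**: electrode electrochemistry and
solvent–electrode artifacts, slow nonstationary growth trends, any
biophysical membrane model, spatial correlation between neighbouring
electrode pairs, and amplitude spectra of real colonization signals beyond
the single tone + band-noise idealisation. Passing tests therefore show
that the *pipeline* recovers known structure at realistic magnitudes — not
that real mycelial signals look exactly like the synthetic ones.

## Scenario time scaling for tests

Scenario "days" are parameterised by `day_seconds`. Event *times* scale
with it while all *frequencies* stay in Hz, so spectral content, band
powers and test statistics are unaffected; only window lengths (hence PSD
averaging variance) shrink. The package's fast-test profile runs the
replicated statistical checks at 900 s days (power of the pooled
comparison: 100 replicates) and 225 s days (type-I error calibration: 500
replicates), sizes at which a 3-scenario-day analysis window still holds
dozens of Welch frames. The profile exists so the full suite runs on a
laptop in minutes; nothing in the checked statistics depends on the day
length beyond the window size entering the PSD averaging.

## Statistical conventions

- Welch's *t* with Welch–Satterthwaite degrees of freedom, two-sided
  p-values (sidedness is not stated in the published analysis; two-sided
  is the conservative default). Exact p-values are always reported, never
  truncated to 0.
- Shapiro–Wilk is a diagnostic, not a gate: a rejection attaches a warning
  to the comparison but does not switch to a nonparametric test, matching
  the published workflow, which reports none.
- Groups with a single replicate get a percent change but flagged test
  fields ("insufficient replicates"), the same way single-replicate
  control conditions are handled in the published table.
- No multiple-testing correction across conditions (none is applied in
  the published analysis).

## Reproducibility limits of the printed table

Recomputing the percent-change column from the *printed* group means
reproduces six of the nine rows to the printed three decimals. The three
large-ratio rows differ by 0.002–0.005, exactly the error band implied by
means printed at five to six significant figures — the original values
were evidently computed from unrounded means that are not published. The
package reports the achievable per-row tolerance alongside the recomputed
values (`check_published_percent_change()`), and its tests assert
agreement at that printed-precision bound.

## Degenerate inputs and tie-breaks

- All-missing channels error ("empty after cleaning"); segments shorter
  than one STFT window, or than the anti-alias filter, error with the
  required length in the message.
- Zero-variance groups: Shapiro–Wilk is flagged rather than run; the
  Welch test errors only if *both* groups are constant.
- A percent change against a non-positive control mean is an error.
- Implausibly large voltages (|v| ≥ 1 V) warn but do not error, since unit
  mistakes should be visible without blocking exploration.
- Band edges are half-open everywhere; the Nyquist bin belongs to no
  band starting at the Nyquist frequency.

## Known limitations

- The vendor's HDF5 export layout is not publicly documented; recordings
  are stored in this package's plain-text layout (metadata header + one
  column per channel), which round-trips values at 9 significant digits.
  No R reader for the vendor format is bundled.
- The generator's amplitude calibration targets the printed power
  magnitudes, not any measured spectrum; absolute powers from synthetic
  runs should be read as illustrative.
- Statistical checks on replicated synthetic experiments are inherently
  stochastic; they are run at fixed seeds with thresholds (detection in
  ≥ 90% of replicates; type-I error within [0.03, 0.07] at α = 0.05)
  chosen to be stable under reseeding.
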