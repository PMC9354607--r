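---
title: "Multifrequency intraoperative ECochG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifrequency intraoperative ECochG: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfecochg)
```

## The problem

During cochlear implantation the electrode array can be monitored with
electrocochleography (ECochG) recorded from the array's own most-apical
contact while an acoustic tone burst is played into the ear canal. The
cochlear microphonic (CM) — the outer-hair-cell receptor current, which
follows the stimulus waveform and inverts with its polarity — grows as the
contact approaches the stimulus frequency's tonotopic (characteristic
frequency, CF) place and is attenuated by intracochlear trauma. A drop of at
least 30% from a prior maximum during insertion is the conventional warning
sign.

A single 500-Hz monitoring stimulus is ambiguous: a drop can mean trauma, or
it can mean that the contact has simply advanced *past* the 500-Hz CF place,
which is expected in smaller cochleas with deep insertions. An alternating
250/500-Hz protocol resolves the ambiguity: trauma attenuates both
frequencies together, while CF crossing produces a dyssynchronous pattern —
a 500-Hz drop with a still-rising 250-Hz response, because the 250-Hz place
lies further apical and is essentially never reached by a 20-mm array.

This package implements the complete analysis chain for that protocol plus a
ground-truthed synthetic cochlea used to validate every stage.

## Signal model and CM extraction

Each insertion step presents one condensation and one rarefaction tone burst
per frequency (10 ms, 1-ms linear ramps; 14-ms epochs from 1 ms before
onset; 20 kHz sampling). The CM inverts with polarity, so the *difference
curve* `(condensation - rarefaction) / 2` isolates it while phase-invariant
components (summating potential, neural responses, common-mode artefact)
cancel exactly. The halving makes the result an estimate of the
single-response CM amplitude; without it every amplitude in the pipeline
would simply carry a factor of 2.

The "ongoing" analysis portion is taken from `onset + ramp + 1 ms settling`
to the start of the offset ramp, then truncated to a whole number of
stimulus cycles. With the insertion defaults that retains 3 cycles at 500 Hz
and 1 cycle at 250 Hz. Cycle alignment makes the rectangular-window DFT bin
at the stimulus frequency leakage-free, so `spectral_amplitude()` (scaled
`2|X_k|/N`) recovers pure-tone amplitudes exactly; no taper or zero-padding
is used, and the bin is the nearest bin rather than an interpolated
estimate. The settling millisecond excludes onset ringing; the cost is a
shorter window, which mainly matters at 250 Hz where only one cycle
survives a 10-ms burst — the physical reason longer bursts are preferred
for low-frequency monitoring.

A response is *significant* when it exceeds the noise-floor mean by 3
standard deviations, with the floor estimated from stimulus-free windows
passed through the identical pipeline (the recorded analogue of clamping
the sound tube). Amplitudes at or below the floor should be clamped to the
floor mean before dB conversion (`to_db()`, dB re 1 µV) to avoid taking
logs of near-zero values.

## Tonotopic geometry

Greenwood's human frequency–position map `F = 165.4 (10^{2.1 x} - 0.88)`
(with `x` the fraction of duct length from the apex) fixes where each
frequency lives along the basilar membrane. Two geometric conversions tie
this to an implanted cochlea:

* **Duct length from diameter.** The lateral-wall cochlear duct length is
  taken as the published affine regression `CDL = 4.16 D - 3.98` mm on the
  cochlear diameter `D` (round-window centre through the mid-modiolar axis
  to the lateral wall), the one geometric quantity routinely measured on
  postoperative CT.
* **Arc length to angle.** Angular insertion depth maps to lateral-wall arc
  length through the logarithmic spiral `s(θ) = 2.62 D ln(1 + θ/235)`. We
  deliberately did *not* use a linear angle↔length map normalised to 2.5
  turns: a linear map makes the CF-place *angle* a constant independent of
  cochlear size, which contradicts the central clinical observation that
  the same insertion angle crosses the 500-Hz place in small cochleas but
  not large ones. The logarithmic spiral also reproduces measured
  first-turn outer-wall lengths (22.4 mm at 360° for D = 9.2 mm, against
  reported values of 22.5 ± 1.2 mm).
* **Reference duct.** The Greenwood constants are calibrated on a ~35-mm
  duct. We treat a frequency's place as sitting a fixed *absolute* distance
  from the apex (`x × 35` mm) rather than a fixed fraction of each
  individual duct; with the fractional reading, cochlear size again cancels
  out of the angle. Under the absolute reading the 500-Hz place falls at
  ~378° in an 8.4-mm cochlea and ~447° at 10.1 mm, so a 396° insertion
  crosses it only in smaller cochleas — and the 250-Hz place (~485° and
  beyond) is never reached. This single mechanism generates the package's
  entire CF-crossing phenomenology, including the empirical
  "diameter < 9.5 mm and angle > 350°" risk rule implemented in
  `cf_crossing_risk()`.

## Excitation profile and synthetic recordings

The CM amplitude recorded at angular position θ for a stimulus with CF
place θ_CF is a two-sided exponential, rising with space constant 360°
on the basal side, peaking 10° basal of the CF place, and collapsing with
space constant 120° apically (3× steeper; the largest basal constant that
keeps the apical side under half-peak 90° beyond the CF place at this
ratio). The basal-of-peak offset reflects
that the recorded CM integrates outer-hair-cell drive over the basal tail
of the travelling wave; it also means the sweep-peak electrode moves basal
as soon as the contact truly passes the place, which keeps the sweep-based
crossing call and the geometric truth in exact agreement across the tested
geometry grid. Per-case peak amplitudes are log-normal with median 10 µV,
on the scale of reported CM amplitudes. Note that under this profile a
~400° insertion starts near 35% of its peak, so a case whose *starting*
amplitude should sit near the reported ~10 µV needs a per-case peak around
30 µV; at lower peaks the early trace runs close to the 1-µV single-sweep
noise floor and the 30% criterion fires on noise excursions — which is a
faithful property of the criterion at low signal-to-noise ratio, not a
detector artefact, and is the regime the worked examples avoid by setting
`peak_uv` explicitly.

Scripted trauma is a persistent multiplicative attenuation applied to both
frequencies from a given step onward; attenuation values above 1 model
recovery after repositioning. Recording noise is i.i.d. Gaussian per
sample. Its default standard deviation (~8.74 µV) is derived in closed
form so the single-sweep 500-Hz analysis noise floor is ~1 µV — the
expected DFT-bin amplitude of white noise after the halved difference curve
is `(σ/√2)·√(π/N)` with `N = 120` window samples — matching the floor
reported for this recording setup (and ~0.2 µV after 30-repetition
averaging in the electrode sweep, against ~0.3 µV reported).

An insertion is discretised into `n_steps = 200` uniform angular increments
(the per-presentation sampling of a continuous insertion); the recording
protocol's presentation rate is not standardised, so the step count is a
free parameter. Electrode sweeps record the 11 even contacts of a
22-electrode array, 30 repetitions per phase, 14-ms bursts in 18-ms epochs.
Sweep-burst ramps are linear rather than Blackman-shaped; the ongoing
window excludes the ramps entirely, so the envelope shape does not enter
the extracted amplitude.

What the generator does *not* emulate: reversible pressure effects that
resolve spontaneously, frequency-unequal trauma (the equal-attenuation
assumption is a modelling choice; the clinical evidence for synchrony is
qualitative), latency changes, neural components, electrode-position
artefacts, and hair-cell survival gradients. Green tests on synthetic data
therefore demonstrate internal consistency of the analysis chain and
correctness under the stated model, not clinical performance.

## Drop detection and classification

`detect_drops()` keeps a running maximum; an event opens when the amplitude
falls to ≤ 70% of it, tracks its minimum, and closes when the amplitude
recovers above the 70% bound. Recovery re-arms the detector, which is what
makes repeated drop/recovery cycles countable as separate events; the
criterion is applied to linear µV amplitudes, with dB reserved for
reporting magnitudes. The suite verifies the incremental detector against
an independent exhaustive enumeration on hundreds of random traces.

`largest_drop_db()` is deliberately *not* the largest event: it is the
global peak to the post-peak minimum, 0 if the trace ends on its maximum,
with ties broken to the earliest peak for determinism. It is computed over
all post-peak steps; restricting it to significant-response regions would
be a defensible alternative and can shrink the 250-Hz value in noisy
traces. `count_drops()` counts events whose absolute decrement strictly
exceeds 2 µV. Insertion patterns quantify the classic qualitative types
with a 20% tolerance: A (overall rise), B (early maximum then decline),
C (similar endpoints with an interior maximum); rules are tested in the
order C, B, A and a trace matching none is assigned the nearest rule under
a relative-violation score, with a warning.

`classify_drop_cause()` encodes the two-frequency paradigm: a 500-Hz event
is *trauma* if any 250-Hz event overlaps its span within ±2 steps,
*cf_crossing* if the 250-Hz amplitude has a non-negative least-squares
slope across the span, otherwise *indeterminate*. Synchrony is checked
first: under the generator's trauma model both frequencies drop together,
so the slope test only adjudicates events the 250-Hz trace does not
corroborate.

## Cohort layer

`lfpta()` averages the 125/250/500-Hz audiometric thresholds;
`lfpta_shift()` (post − pre) is the hearing-preservation outcome, positive
for loss. The cohort generator draws geometry per electrode type
(perimodiolar 9.2 ± 0.4 mm, 396.5 ± 40.2°; lateral wall 9.4 ± 0.6 mm,
294.1 ± 41.9°; angle–diameter correlation −0.52), scripts trauma at a
Poisson rate of 1.5 events per insertion with attenuations uniform on
[0.4, 0.9], and sets the LFPTA shift to
`7.1 + 0.37 × (largest 250-Hz drop, dB) + N(0, 10²)`. The intercept and
slope are the fitted values reported for this protocol; the residual of
10 dB HL reflects the broad audiometric spread seen clinically. (The
published per-patient correlation, slope, and drop scale are not jointly
consistent — matching all three simultaneously would require drop
magnitudes an order of magnitude larger than tabulated — so the generator
keeps tabulated-scale drops and treats the cohort-level correlation as an
output rather than a calibration target.) Per-frequency thresholds scatter
around the LFPTA with zero-sum jitter, so each case's shift is exact by
construction; the cohort runs at amplitude level (noiseless analytic
traces) so that 100-replicate recovery studies remain fast, with
`waveforms = TRUE` available for end-to-end checks.

The statistics mirror standard reporting: Pearson (or Spearman, for the
skewed lateral-wall subgroup) correlations, univariate OLS per feature with
no multiple-testing correction by default (a Benjamini–Hochberg flag is
provided), pattern type entering as indicators with Type A as reference,
two-sided α = 0.05 throughout. `pearson_filon_z()` implements the
Pearson–Filon (1898) statistic for comparing two overlapping dependent
correlations; the inter-predictor correlation `r23` is an explicit argument
because published reports typically omit it, and the test's type-I error is
validated by Monte-Carlo simulation at the study's sample size (n = 34).

## Numerical and degenerate-input choices

* Cycle-aligned rectangular windows make the FFT amplitude exact to
  rounding for pure tones (validated at 1e-9 relative tolerance).
* Scripted attenuations are recovered to 1e-6 where the excitation profile
  is locally flat; on a rising profile the trough at the trauma step also
  contains the tonotopic slope (~1% per step at 200 steps), which is a
  property of the measurement, not a detector error.
* Steps containing non-finite samples are excluded with a warning; missing
  sweep electrodes are skipped with a message; all-zero traces yield no
  events and a warning; `final_over_max()` on an all-zero trace is `NA`.
* Sweep-peak ties resolve to the more apical electrode, which is
  conservative toward "no crossing"; `largest_drop_db()` ties resolve to
  the earliest peak.
* Risk-rule thresholds are strict inequalities, so boundary geometries
  (9.5 mm, 350°) are not flagged.
* Problem sizes used by the validation suite: 200-step insertions, 10×10
  geometry grids, 100 replicate cohorts of 200 cases, 5000-replicate
  Monte-Carlo for the Pearson–Filon null, 1000-replicate noise-floor
  scaling runs.

## Known limitations

Only even electrodes are recorded, so CF-crossing resolution is two
contact positions; a crossing by less than one electrode spacing can be
invisible to the sweep while present geometrically. The equal-attenuation
trauma model cannot generate the rare dissociated patterns (e.g. basal
trauma sparing the apical place). The Greenwood-with-reference-duct
reading is one defensible choice among several published place-frequency
scalings; users fitting their own CT data may substitute a different
`cf_place_angle()` calibration. The cohort generator's event rate and
attenuation range are field-realistic choices, not fitted quantities.

## A worked example

```{r example, eval = FALSE}
g <- cochlear_geometry(diameter_mm = 8.6, apical_angle_deg = 430)
script <- event_script(data.frame(step_index = 80,
                                  attenuation_fraction = 0.5))
sim <- simulate_insertion(g, script = script, seed = 1,
                          excitation = excitation_params(peak_uv = 30))
trace <- build_insertion_trace(sim)
insertion_metrics(trace)
classify_drop_cause(trace)

sweep <- sweep_from_recordings(
  simulate_sweep(g, seed = 2, excitation = excitation_params(peak_uv = 30)))
crossed_cf(sweep, 500)
cf_crossing_risk(g$diameter_mm, g$apical_angle_deg)
```
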