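---
title: "Sleep spindle detection by continuous wavelet transform: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep spindle detection by continuous wavelet transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlecwt)
```

## The problem

Sleep spindles are bursts of 10–16 Hz oscillatory activity in NREM
sleep EEG, 0.5–2.5 s long, with a waxing–waning envelope. They come in
two flavours: slow spindles (around 11.5 Hz, frontally predominant)
and fast spindles (around 13 Hz, parietally predominant), and both
their frequency and the overall EEG amplitude vary strongly between
subjects and channels. A detector with fixed frequency bands and a
fixed amplitude threshold therefore misclassifies heavily in some
subjects. `spindlecwt` implements a detector that adapts on both axes:
its amplitude thresholds are derived per channel from the background
spectrum of the very signal being analysed, and its slow/fast
frequency boundaries can be adjusted per subject by comparing spindle
activity between a frontal and a parietal channel. Around the
detector, the package provides the agreement statistics used to
compare two spindle scorings and the classical twin-study machinery
(genetic variance analysis, intraclass correlations with a bootstrap
null) used to ask how heritable spindle parameters are.

## Detection model

### Working rate and preprocessing

All analysis runs at 100 Hz (time resolution 0.01 s); recordings at
higher rates are resampled by Fourier interpolation, which is exactly
band-limited and preserves in-band amplitudes. Two exclusion rules
clean the signal first:

* **Muscle artifacts.** The channel is band-passed to 19.8–45.5 Hz
  (−3 dB points) and the standard deviation is computed over 1-s
  windows stepped by 0.5 s. Any window with SD above 5.75 μV marks an
  exceedance; the exceeding fragment padded by 3 s on both sides is
  excluded, so a single bad window removes 7 s of signal.
* **Alpha runs.** Wake-like alpha trains (8–12 Hz) resemble spindle
  trains. After a 1.4 Hz high-pass, amplitude spectra on 4-s Hann
  windows (step 1 s) yield per-second mean amplitudes in the delta
  (2–4 Hz) and alpha (8–12 Hz) bands. A 15-s sliding window
  Hann-weights and averages the 15 per-second values of each band;
  the window is excluded whenever alpha activity exceeds 1.1 times
  delta activity. The Hann weighting makes the centre of the window
  dominate the comparison.

Masks are computed per channel on the whole recording and then
intersected with the sleep stages under analysis (stage 2, SWS, or
both), giving the "clean segments" on which everything else operates.

### Amplitude-adaptive thresholds

The basic threshold BT summarizes background amplitude in the 6–18 Hz
range: clean signal is band-passed (−3 dB at 5.5 and 18.2 Hz),
amplitude spectra are taken on non-overlapping 2-s windows (0.5 Hz
bins), log10-transformed, and the per-bin **median** over windows is
averaged over 6–18 Hz and back-transformed. The log transform and the
median make BT insensitive to transient bursts — doubling the signal
doubles BT, but injecting a single 2-s high-amplitude burst into ten
minutes of signal moves it by under 2%. The two detection thresholds
are fixed multiples: the spindle-activity threshold SA = 55·BT and
the spindle-peak threshold SP = 80·BT, so SP/SA ≡ 80/55 ≈ 1.45.

**Amplitude calibration.** This package calibrates its CWT envelopes
to signal amplitude (a pure tone of amplitude A yields a steady-state
envelope of A μV) and computes BT spectra as |FFT|/n. The 55×/80×
multipliers, however, presuppose a particular pairing of spectral and
CWT scale conventions that the method description leaves open — under
a literal |FFT|/n pairing SA would land several times above real
spindle envelopes. `basic_threshold()` therefore carries one
calibration constant (`scale`, default 0.3, exposed in
`spindle_config()` as `bt_scale`) fixed once against the package's
synthetic background model so that SA sits at roughly 2.3 times the
RMS of the background sigma-band envelope: comfortably above the
sustained excursions of spindle-free background, comfortably below
spindles standing three times above background. Users porting
thresholds from another implementation should recalibrate this one
constant rather than the multipliers.

### Wavelet and event rule

The detector convolves the signal with a complex Morlet wavelet,
$\psi(u) = \pi^{-1/4}\, e^{i 2\pi f_0 u}\, e^{-u^2}$ with $u = (t-b)/a$,
central frequency parameter $f_0 = 2$ and the scale-to-frequency map
$f = f_0 / a$. With $f_0 = 2$ the wavelet holds only a few
oscillations under its Gaussian envelope — about the shape of a short
spindle — trading frequency precision for the time localization the
event rule needs. The kernel is truncated where its envelope falls
below $10^{-6}$ of the peak and L1-normalized so the tone-to-envelope
calibration above holds at every frequency. An event is a maximal run
of samples where the envelope strictly exceeds SA; it is kept if the
run lasts at least 0.5 s and the envelope exceeds SP at least once
inside it. Ties break toward non-detection, events never cross clean-
segment boundaries, and no maximum duration is imposed.

### Individual frequency bands

When a frontal and a parietal channel are available, the slow and
fast ranges are fitted per subject (and separately per stage
selection, since slow spindles drift downward in SWS):

1. **Activity scan.** Envelopes are computed at 71 bins (9–16 Hz,
   step 0.1 Hz). Events detected on each bin's envelope are accepted
   for that bin only if the bin is *dominant* — the event's mean
   envelope there strictly exceeds its mean envelope at every other
   bin — giving per-bin accepted counts for the frontal channel
   (`vec_slow`) and the parietal channel (`vec_fast`).
2. **Comparison.** The 9-Hz bin is zeroed (it aliases everything
   below the grid), both vectors are smoothed twice with a 0.7 Hz
   moving average, and a relation vector is formed from the damped
   ratio of the two (half of the grand mean activity is added to both
   numerator and denominator so that sparse bins cannot explode the
   ratio; the construction is antisymmetric, positive where parietal
   activity dominates). The minimum of the relation vector gives the
   slow centre; its maximum above that, shifted to the nearest local
   maximum of the smoothed parietal vector within 1 Hz, gives the
   fast centre. The fast band spans the zero crossings of the second
   derivative of the smoothed parietal vector around its centre; the
   slow band extends up to the highest bin below the fast band where
   frontal activity still exceeds parietal, and down to where the
   relation vector has recovered to 60% of its minimum. Below the
   slow band, the highest bin where parietal activity exceeds frontal
   becomes `stop_detect`, the reference frequency at which activity
   is considered non-spindle. Bands are widened to at least 0.5 Hz.
3. **Fallback.** With fewer than 30 accepted spindles in either
   channel the estimate is unreliable and fixed bands are returned
   instead (slow 11–12.9, fast 13.1–15 Hz, stop 9 Hz), flagged as
   `fixed_fallback`. Montages without frontal/parietal coverage use
   user-fixed bands (default slow 11–12.9, fast 13.1–16 Hz).

### Scoring

Per-sample band envelopes are pointwise maxima over each band's 0.1 Hz
grid: `cwt_slow`, `cwt_fast`, their maximum `cwt_all`, and `cwt_stop`
at the single stop frequency. *All* spindles are events on `cwt_all`
whose mean exceeds the mean of `cwt_stop` over the event (rejecting
bursts that really live below the spindle range). *Fast* spindles are
maximal runs where `cwt_fast` is continuously above `cwt_slow` and
meets the event rule; *slow* spindles mirror this with the roles
swapped plus the stop comparison. The asymmetry — no stop test for
fast spindles — follows the method as published: the stop frequency
sits below the slow band, where it cannot discriminate fast events.
Because the slow/fast runs are defined by strict envelope dominance,
the two types can abut but never overlap.

Each event's amplitude and frequency come from the raw signal:
band-pass (−3 dB at 8.7 and 18.5 Hz), Hann window over exactly the
event fragment, zero-padding to 10 s (0.1 Hz spectral grid), and the
height and location of the maximum spectral peak in 9–16 Hz. The
spectrum is scaled as 2|FFT|/∑hann, so a tone of amplitude A filling
the fragment reports ≈ A. Summaries per channel/stage/type report
count, density (spindles per 30-s epoch, assigning each event to the
epoch containing its onset), mean duration, amplitude, frequency, and
the activity index count × mean amplitude × mean duration.

## Agreement statistics

Two scorings are compared on binarized timelines with 0.1-s bins (a
bin is positive if any event touches it), restricted to the epochs of
the analysed stage. Because most bins contain no spindle, the package
reports class-imbalance-aware statistics alongside sensitivity,
specificity and precision: Cohen's kappa, the Matthews correlation
(identical to the Pearson correlation of the binary vectors — a
property the test suite asserts to 1e-10), and the adjusted G-mean
$(\sqrt{\mathrm{sens}\cdot\mathrm{spec}} + \mathrm{spec}\cdot N_n)/(1+N_n)$
with $N_n$ the negative-class proportion, defined as 0 when
sensitivity is 0. Kappa values carry Landis–Koch labels (0–0.2
slight … 0.81–1 almost perfect). Event-level consensus uses a
minimum temporal overlap of 0.3 s with greedy one-to-one matching by
decreasing overlap; per-recording statistics are pooled with the
number of analysed epochs as weights.

## Twin statistics

Genetic variance analysis follows the classical two-estimator scheme
for MZ/DZ designs, computed on per-subject means over the two
recording nights. Prerequisites come first: Kolmogorov–Smirnov
goodness of fit to a normal distribution within each zygosity group
and a t-test of equal group means — unequal means would bias the
variance comparison, so the genetic test is then not run. An F′ test
of equal total variances (ratio of per-group total mean squares,
two-sided, Satterthwaite degrees of freedom) at α = 0.2 selects the
estimator: with equal totals the within-pair estimate
GWT = MSW(DZ) − MSW(MZ), tested one-sided by the MSW ratio with the
pair counts as degrees of freedom; with unequal totals the combined
estimate GCT = ½[(MSA(MZ)+MSW(DZ)) − (MSA(DZ)+MSW(MZ))], tested by the
corresponding composite F with Satterthwaite degrees of freedom. Under
the additive model both estimators have expectation ½σ²_g. No
multiple-testing correction is applied, matching the analysis this
package reproduces. Simulated at the study's group sizes (32 MZ, 14 DZ
pairs) the procedure's type-I error is 0.05 within simulation error; at
80% heritability its power is ≈ 0.7, bounded by the analytic power of
the MSW-ratio test at these degrees of freedom.

Intraclass correlations use the one-way random-effects form for
groups of two, (MSA − MSW)/(MSA + MSW): pair as the group for
within-pair resemblance (night-averaged values), subject as the group
for night-to-night stability. Significance comes from a bootstrap
null that deliberately breaks the pair structure: values are resampled
with replacement up to the original sample size, consecutive values
form pseudo-pairs, and sampling continues until exactly 1000
*positive* ICCs are collected; the 99th percentile of these is the
P = 0.01 threshold and their median is the resemblance expected by
chance. Smaller samples produce larger thresholds — the suite asserts
this monotonicity over n ∈ {14, 32, 64} pairs.

## The synthetic-data generator

No recordings ship with the package; `generate_recording()` emulates
the study conditions so every stage of the pipeline is testable
against known ground truth. The default 250 Hz signal contains:

* a pink-noise floor (1/f power, spectral shaping with random phases)
  of 7 μV SD — giving a spindle-free sigma-band (10–16 Hz) SD of
  about 1.9 μV, in the range of real S2 background;
* band-limited delta (0.5–4 Hz) of 25 μV SD in SWS, scaled by 0.5 in
  S2 and 0.25 elsewhere;
* two spindle trains with Hann (waxing–waning) envelopes: 11.5 Hz
  weighted 1.0 frontal / 0.2 parietal and 13.5 Hz weighted the other
  way, both 22 μV peak, 0.7–1.6 s, Poisson-placed at 3 events per
  30-s epoch in S2 and SWS with at least 0.5 s between events
  (uniform-gap placement; a genuinely infeasible density errors);
* 10 Hz alpha bursts (20 μV, 3 s, 0.5/min) confined to Wake/S1/REM
  epochs, and broadband 20–45 Hz EMG bursts (15 μV SD, 2 s, 0.5/min)
  in any stage.

Every planted event is returned with its true channel, onset,
duration, per-channel amplitude and frequency. The generator is
bit-reproducible from its seed. What it does *not* emulate: real
spindle envelope asymmetry, spindle–slow-oscillation coupling,
non-stationary background drift, eye-movement and electrode
artifacts, and realistic stage transitions. Passing tests on this
signal therefore demonstrate the pipeline's correctness and its
operating point under controlled SNR, not clinical-grade performance
on real polysomnography.

The twin generator draws the additive model directly: a genetic
component shared fully within MZ and correlated 0.5 within DZ pairs, a
shared-environment component per pair, a unique component per subject,
and independent night noise — so MZ/DZ ICC expectations (e.g. 0.8/0.4
for 80% heritability) are analytic and testable.

## Numerical choices

* FIR stages are linear-phase windowed-sinc (Hamming) designs whose
  ideal cutoffs are iterated until the measured −3 dB points match the
  specification within 0.05 Hz; filters are applied in one pass with
  group-delay compensation. 201 taps suffice for all pass-bands; the
  1.4 Hz high-pass uses 401 taps to resolve its transition.
* Sliding windows anchor at t = 0; trailing partial windows are
  dropped. Spectral band limits are inclusive.
* The event rule uses strict inequalities throughout; a single-sample
  tie splits a dominance run.
* All event times are seconds from recording start with half-open
  intervals [onset, offset); epochs are assigned by onset.
* Edge samples of each CWT envelope (one kernel half-support) are
  computed against zero padding and reported via an attribute;
  segments shorter than a kernel support are skipped.
* Degenerate inputs fail loudly rather than silently: zero signal in
  BT (log of zero), constant samples in the ICC bootstrap, empty
  stage selections.

## Problem sizes

The shipped tests exercise 10-minute two-channel recordings (the
band-adjustment scan processes 71 envelopes per channel in a few
seconds), 2000-replicate null simulations for the genetic test, and
bootstrap runs of 1000 positive ICCs; the whole suite completes in a
few minutes on one core. All pipeline stages (FFT-based filtering,
convolution and spectra) scale essentially linearly in recording
length and channel count.

## Limitations

The detector's absolute operating point on real data depends on the
`bt_scale` calibration discussed above; the shipped default is
calibrated to the synthetic background model, not to any clinical
dataset. The band-adjustment surrogate for the relation vector
matches the published construction's stated properties (sign,
damping, antisymmetry) but the original closed form was published
only graphically; `relation_vector()` isolates it for substitution.
The GCT composite test relies on Satterthwaite approximations that
are rough for very small DZ groups. EDF support covers continuous
EDF/EDF+ 16-bit recordings; discontinuous EDF+D files and proprietary
acquisition formats are out of scope.
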