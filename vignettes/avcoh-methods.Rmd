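---
title: "Methods: coherence analysis of audiovisual speech entrainment"
author: "avcoh package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherence analysis of audiovisual speech entrainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avcoh)
```

## The scientific problem

During natural conversation a listener sees the speaker's mouth move.
Mouth opening and closing is quasi-rhythmic at the syllable rate, and
low-frequency cortical oscillations can phase-align ("entrain") to it,
just as auditory cortex entrains to the acoustic amplitude envelope.
Because the lip aperture and the acoustic envelope of the same utterance
are themselves coherent in the 4-8 Hz syllable band, any apparent
lip-brain coupling may simply be auditory entrainment in disguise. The
analysis implemented here separates the two contributions and links the
residual, genuinely visual entrainment to comprehension behavior.

The chain is:

1. **Stimulus signals.** The lip-aperture area per video frame
   (extracted from binary mouth-region masks) and the wideband amplitude
   envelope of the speech waveform, both resampled to a common 250 Hz
   analysis rate.
2. **Source localization.** Frequency-domain beamforming (DICS-style
   spatial filters built from the sensor cross-spectral density and a
   leadfield) turns multichannel sensor recordings into voxel time
   series on a regular grid.
3. **Entrainment maps.** For each voxel and each integer frequency
   1-7 Hz, the magnitude-squared coherence between the band-pass
   filtered voxel series and the lip signal, and the partial coherence
   with the acoustic envelope conditioned out.
4. **Surrogate nulls.** The same maps computed against a 30-s
   circularly shifted lip signal estimate the chance level of the
   estimator with identical spectra.
5. **Group statistics.** Gaussian smoothing, dependent-samples
   sign-flip randomization t-maps with Benjamini-Hochberg FDR, ROI
   frequency profiles, and behavioral analyses (across-subject
   regression with a Z-difference contrast, Fisher-z correlation,
   median-split group test).

Because real MEG/MRI recordings for this paradigm are not publicly
deposited, the package ships a first-class synthetic-study generator
with closed-form ground truth; every stage is validated end-to-end on
data whose coupling structure is known exactly.

## Estimators

### Coherence and partial coherence

With Welch-averaged spectra over demeaned, Hann-tapered 1-s segments
overlapping by 0.5 s (1 Hz resolution),

$$C_{xy}(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1].$$

Partial coherence conditions a third signal $z$ out of both sides. With
coherency $R_{ab} = S_{ab}/\sqrt{S_{aa}S_{bb}}$,

$$C_{xy|z}(f) =
 \frac{|R_{xy} - R_{xz}R_{zy}|^2}{(1-|R_{xz}|^2)(1-|R_{zy}|^2)},$$

which equals the coherence of the per-frequency residuals of $x$ and
$y$ after projecting $z$ out (the test suite verifies this equivalence
against an independent residual-projection implementation to 1e-6).
Degenerate conditioners ($|R|^2 > 1 - 10^{-6}$) yield `NA` with a flag
rather than a clipped value.

Frequency-resolved maps follow the per-band convention: both series are
band-pass filtered at center ± 3 Hz (order-4 Butterworth, forward and
reverse, the low band edge clipped at zero so low centers become
low-pass designs) and the estimate is read off at the center frequency
bin. The estimator is biased upward for independent signals by roughly
1/M for M segments; surrogate maps carry exactly this bias, which is
why contrasts are always taken against them rather than against zero.

Known estimator properties worth keeping in mind:

* **Leakage at band edges.** The Hann taper's spectral kernel spans
  ±1 bin, so a 1-Hz bin blends content from its neighbors. When one
  signal has strong power just outside the band of interest (the lip
  signal's dominant 1-3 Hz components next to the 4-8 Hz syllable
  band), coherence at the band edge is diluted. Calibration checks
  therefore read band-interior bins.
* **No single-bin contrasts.** For the same reason a band-limited
  stochastic coupling can never produce a condition difference confined
  to exactly one 1-Hz bin; neighboring bins always carry a reduced
  image of the effect. Validation of "effect only at 4 Hz" profiles is
  done at the map level, while the time-series chain is validated by
  requiring the frequency of maximal condition contrast to equal the
  generator's coupling frequency.

### Surrogates

`surrogate_driver()` applies a circular shift (default 30 s). The shift
is circular rather than truncating so the amplitude spectrum and length
are preserved exactly; only the temporal alignment is destroyed. The
shift must exceed the coherence timescale of the signals, which for
speech-like drivers (correlation time well under a second) it does by
orders of magnitude.

### Beamforming

`dics_filters()` implements the unit-gain minimum-variance spatial
filter per voxel, $w = (l^\top C_r^{-1} l)^{-1} l^\top C_r^{-1}$, with
$C_r$ the real part of the sensor CSD at the analysis frequency plus
Tikhonov regularization (`reg_frac`, default 5 % of the mean diagonal).
The real part is used for filter computation (standard practice; the
complex CSD is retained for coherence estimation downstream).
Free-orientation leadfields are collapsed per voxel to the dominant
singular direction of the sensors × 3 gain block. Filters are computed
only at the analysis frequencies actually mapped (1-7 Hz), not over a
wider sweep.

Minimum-variance filters partially cancel *correlated* sources. The
synthetic generator therefore assigns distinct carrier phases to voxels
that couple to the same driver (see below); in real recordings the
analogous caveat is that two strongly coherent sources mutually shadow
each other in a beamformed map.

### Group statistics

Individual maps are smoothed with a 10-mm FWHM Gaussian kernel
(separable, reflective boundaries; constants are preserved exactly and
interior point masses conserve their integral). Dependent-samples
t-maps use a Monte-Carlo sign-flip null (default 500 randomizations,
per-voxel p as the rank of the observed |t| in its null, with the +1
correction) and Benjamini-Hochberg FDR at q = 0.05 via
`stats::p.adjust`. Note the granularity consequence: with 500
randomizations the smallest achievable p is 1/501, so BH thresholds
below that (small q with many voxels and few true effects) cannot be
crossed; raise `n_rand` when strong, sparse effects must survive FDR.

ROI profiles report the paired t per frequency with both an
uncorrected 0.05 line and a Bonferroni line over the tested
frequencies (the choice of correction for this secondary display is a
package decision; the map-level inference uses FDR).

For behavior, coherence values are variance-stabilized as
$z = \mathrm{atanh}(\sqrt{C})$ — coherence is a squared-correlation
analogue, so the square root precedes the arc-tanh; `fisher_z_coh()`
also exposes plain `atanh` for values already on a correlation scale.
The regression Z-contrast converts per-voxel slope t-values to standard
normal deviates through the t CDF and subtracts the two conditions'
Z-maps; the difference of two independent standard normals has variance
2, so the two-sided threshold at `p_thresh` on the unit scale is
conservative for a single map and its empirical null exceedance rate is
$2(1-\Phi(\Phi^{-1}(1-p/2)/\sqrt{2}))$ — the calibration test asserts
exactly this. In the median-split test, subjects exactly at the median
accuracy join the good-performer group; with accuracies discretized in
steps of 10 this rule produces the characteristic slightly unbalanced
splits.

## Stimulus signal processing

**Lip geometry.** Binary mouth masks (one per video frame, 25 fps
typical) are summarized by foreground area and the axis lengths of the
moment-matched ellipse (4·sqrt of the eigenvalues of the second central
moment matrix). Area is the analysis signal; for natural, roughly
fixed-shape apertures the minor (vertical) axis is nearly perfectly
coherent with area across 1-7 Hz, which the suite checks on synthetic
masks. Segmentation of raw video into masks is out of scope.

**Acoustic envelope.** The waveform is filtered into 8 bands spaced
equally on Greenwood's human cochlear map
$x(f) = \frac{1}{a}\log_{10}(f/A + k)$ with $A = 165.4$, $a = 0.06$,
$k = 0.88$, between 100 and 10 000 Hz. Each band receives the
zero-phase order-4 Butterworth band-pass response; band envelopes are
analytic-signal magnitudes, averaged unweighted, then anti-alias
resampled to 250 Hz. No amplitude compression is applied by default
(`compression = "log"` is available as a toggle).

Two numerical choices matter here. First, at audio rates the narrow low
bands (100-170 Hz at 48 kHz) make the recursive transfer-function
realization of an order-4 band-pass unstable in double precision, so
the package applies the exact squared-magnitude (forward-reverse)
Butterworth response in the Fourier domain — the same transfer
characteristic, unconditionally stable. Second, rate conversion is
FFT-based (spectral zero-padding upward; a brick-wall anti-alias cut at
0.45 × the target rate downward followed by interpolation of the then
heavily oversampled series); this preserves the mean exactly and maps
constants to constants.

## The synthetic study generator

The generator defines the study conditions under which the package is
validated. Coupling is injected with a closed-form target: a source
coupled to a driver at strength $C$ is
$\sqrt{C}\,s + \sqrt{1-C}\,n$ where $s$ is the band-limited driver
component (unit variance) and $n$ is spectrally matched independent
noise — the band-pass filtered, circularly far-shifted driver — so the
shared-to-noise ratio is $C/(1-C)$ at every in-band frequency and the
population coherence at the coupling frequency is exactly $C$.

* **Lip driver** (`gen_lip_driver`): 7-Hz low-passed Gaussian noise
  plus extra 1-4 Hz narrowband energy, shifted positive and scaled to a
  plausible aperture-area range (mean 4000 px², SD 600 px²). Its
  spectrum peaks in the 0-4 Hz range with >90 % of power below 7 Hz.
* **Acoustic envelope** (`gen_coupled_envelope`): target coherence with
  the lip driver inside 4-8 Hz (0.5 by default for congruent
  conditions, 0 for incongruent ones), plus band-stopped out-of-band
  noise, shifted nonnegative.
* **Sensors** (`gen_subject_sensors`): coupled voxels receive the
  driver component at the coupling frequency (4 Hz, half-width 1.5 Hz
  by default) mixed to the per-subject target coherence; all other
  voxels are unit-variance white noise; sensor data are the leadfield
  projection plus white sensor noise (SD 1). Voxels sharing a driver
  get staggered carrier phases (0, π/m, ...) so the beamformer does not
  cancel them against each other; magnitude coherence is unaffected.
* **Subjects and behavior**: each subject's realized coupling strength
  is drawn around the condition mean (SD 0.1) — this between-subject
  variability is what behavior can correlate with. Accuracy is
  `base + slope × coupling + noise`, clipped to [0, 100] and
  discretized to steps of 10 (scoring out of ten comprehension
  questions). Condition mean accuracies default to 85 / 77.7 / 83.4 /
  75.7 % for the all-congruent / all-incongruent / attended-congruent /
  attended-incongruent conditions, the published behavioral pattern for
  this paradigm, with a slope of 45 accuracy points per unit coherence
  and noise SD 10.
* **Leadfield** (`gen_leadfield`): random unit-norm gain columns over a
  regular 8-mm grid. This preserves the linear mixing structure the
  beamformer inverts but is *not* a physical head model: no volume
  conduction, no spatially correlated gains, no realistic noise
  covariance. Condition labels select which driver couples where;
  attention itself is not modelled.

What passing tests on these data do show: the estimators are calibrated
(recovered coherence equals the injected target), conditioning removes
common drive, surrogates sit on the estimator's bias floor, the
beamformer localizes and quantifies coupling through realistic mixing,
and the group statistics control their error rates. What they cannot
show: robustness to correlated sensor noise, head-model mismatch,
artifacts, or any property of real cortical dynamics.

## Validation problem sizes

The test suite and the acceptance script run at desk scale, chosen so
the full suite completes in minutes while keeping every estimate in its
asymptotic regime: 300-s signals for estimator calibration (≈600
Welch segments), 180-s recordings with 64 sensors / 200 voxels for the
20-seed beamformer recovery study, 90-s recordings for the
frequency-profile recovery, 20 subjects × 500 voxels × 200 replicates
for the FDR calibration, and n = 44 subjects for the behavioral
analyses (matching the published cohort size, with the
coherence-accuracy effect size set for a population correlation near
0.4). The reported behavioral linkage checks are three designed
simulations: sampling behavior of the correlation at that effect size,
Z-difference peak recovery under a strong designed slope at one voxel,
and median-split power at an injected group difference of 0.1 (SD
0.05).

## Known limitations

* Sine multitapers are provided as the multitaper option; Slepian
  (DPSS) tapers are not implemented.
* The Z-difference threshold treats each condition's Z-map as standard
  normal; spatial smoothing correlates neighboring voxels, so
  map-wide error control for this display is nominal, not exact.
* The surrogate is a single fixed shift, not a distribution of shifts;
  the group contrast against the surrogate map absorbs the residual
  variability.
* `gen_lip_masks` uses a fixed-eccentricity ellipse (0.8), which makes
  area and minor axis deliberately co-informative; it is a fixture
  generator, not a model of real articulators.
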