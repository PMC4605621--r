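---
title: "Source-filter analysis of koala vocalisations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-filter analysis of koala vocalisations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koalacall)
```

`koalacall` characterises the acoustic structure and information content of
koala vocal signals. This vignette is the package's own account of its
science: the generative model behind the synthetic data, the measurement
algorithms and the parameters that matter, the statistics stage, and the
design decisions taken where the design was genuinely open.

## The production model

Under source-filter theory a mammal call is a source signal (vocal-fold or
velar-fold vibration, or turbulent noise) filtered by vocal tract
resonances (formants). The package represents each of the three female
call classes accordingly:

* **Bellows** alternate exhalation and inhalation phases. Exhalations are
  modelled as Gaussian noise (the deterministic chaos every bellow
  contains); inhalations as a glottal/velar pulse train following the
  call's F0 contour (F0 near 31 Hz, so individual pulses are visible).
  Both phases pass through a cascade of six two-pole resonators at the
  formant targets (roughly 260–2630 Hz for females).
* **Snarls** are noise through six resonators (roughly 820–6240 Hz), with
  no fundamental.
* **Tonal rejection calls** are a harmonic source (amplitudes falling 6
  dB/octave) following the F0 contour, optionally with: an additive
  subharmonic stack at F0/2 or F0/3; amplitude modulation at a second
  frequency G0 (biphonation, modulation depth 0.55); and an additive noise
  stretch covering 45% of the call (deterministic chaos).

Broadband calls are synthesized at the modelling rate of their formant
band (twice the analysis ceiling: 6 kHz for bellows, 14 kHz for snarls)
and FFT-upsampled to the output rate, so a rendered call is an exact
all-pole source-filter process over its band. The broadband source is
coloured at −6 dB/octave (a leaky integrator at 50 Hz), the fall-off that
formant-analysis pre-emphasis classically assumes. Resonator bandwidths
default to 8% of the centre frequency; bellow inhalation pulses are placed
with sub-sample precision so the period is not quantized to the sample
grid.

### F0 contours

A call's F0 parameters are its mean, minimum, maximum and `sumvar` — the
cumulative absolute F0 change per second, the package's operational
definition of "amount of F0 modulation per second". The contour generator
realizes all four as a *base sweep* (dwell at the minimum, ramp, dwell at
the maximum, with the dwell split solved so the time-average equals the
drawn mean) plus a *sinusoidal vibrato* whose amplitude supplies the
residual modulation demand (a sinusoid of amplitude `a` and rate `f`
contributes `4·a·f` Hz of variation per second). Contours realize high
modulation rates as rapid shallow movement, not repeated full-range
swings; the vibrato rate is 8 Hz for tonal calls and 0.35 Hz for bellows,
chosen so each call type's pitch tracker can resolve the modulation it is
asked to measure.

Physics can bind: with a small F0 range, a short call, or a slow vibrato,
the demanded modulation may be unrealizable. The generator therefore
constructs the contour at parameter-realization time and **records what the
contour actually realizes** (min, max, sumvar) as the call's parameters, so
the feature table and the rendered audio always describe the same call.
The same principle constrains a few draws: bellow F0 extrema are kept
inside the measurable 10–100 Hz search range (floor 12 Hz, ceiling 95 Hz),
tonal minima above the 180 Hz search floor, and top formant draws below
each band's modelling Nyquist.

### Population structure

`population_spec()` holds per-call-type parameter means and SDs matching
the study population's descriptive statistics, with each SD split into a
between-individual share (default fraction 0.85; 0.3 for bellow source
features, which are not strongly individual) and a within-individual
remainder, so callers have stable signatures. F0 extrema are
parameterized as offsets from the call's mean (`gap_down`, `gap_up`),
which preserves `min ≤ mean ≤ max` and the configured marginal means.
Ages are uniform on 2–14 years; tonal-call F0 features shift by the
configured slopes (−37.23 Hz/yr for mean F0) around the cohort midpoint,
so the slopes act without moving the call-type means. Bellow parameters
take per-sex means (per-subject means of each sex), which makes the
zero-variance female and male formant spacings come out at 424.6 and
355.8 Hz. Draws are Gaussians truncated at physical bounds via the
inverse-CDF, so truncation costs no RNG draws and determinism is exact.

Three generator policies are worth knowing about because they deliberately
shape the joint distributions:

* **G0 placement.** Biphonation is rendered as amplitude modulation; its
  sidebands sit at `h·F0 ± G0`. If G0 falls near an integer fraction of F0
  the modulation is spectrally indistinguishable from subharmonics (at
  exactly F0/2 it *is* period doubling), so G0 draws are kept out of
  relative zones around F0·{1, 3/4, 2/3, 1/2, 1/3, 1/4}. Biphonation is
  drawn only for calls with mean F0 ≥ 550 Hz, below which no separable G0
  exists — consistent with the observation that biphonic calls are the
  higher-pitched squawks and screams.
* **G0 spread.** The study reports a mean G0 near 186 Hz with a 73–276 Hz
  range but no SD; the generator uses 45 Hz, truncated to 60–290 Hz.
* **Bellow modulation.** The printed bellow modulation rate (~58 Hz/s)
  exceeds what a 10–100 Hz pitch tracker can attribute to smooth contour
  movement; in real tracks much of it is period-to-period jitter at the
  tracker's resolution limit. The generator caps bellow sumvar at the
  contour-realizable rate, and the round-trip suite treats sumvar as the
  one feature recovered only coarsely (see below).

## Measurement

All measurement settings are per-call-type presets
(`call_type_preset()`): bellows use an F0 search range of 10–100 Hz and
formants to 3 kHz; tonal calls 180–2500 Hz and no formant analysis (their
sparse harmonics undersample the spectral envelope); snarls no F0 and
formants to 7 kHz. Durations are read from the waveform as the span of
short-term RMS above −25 dB re the call's peak.

**F0 tracking** (`track_f0()`) is normalized cross-correlation peak
picking: the signal is decimated to a rate suited to the search range,
band-limited to 1.5× the search ceiling (this removes formant ringing
that would otherwise offer spurious correlation lags, and broadens pulse
correlation peaks so swept contours remain trackable), and each frame
correlates a two-floor-period window against its lagged continuation.
Peak lags and peak heights are refined by parabolic interpolation — the
height refinement matters, because an integer-lag sample can sit well
below the true correlation peak when the period is not a whole number of
samples. Candidates are scored with an octave cost (0.12 per octave for
tonal calls, where amplitude-modulation lags can out-correlate the true
period; 0.02 for bellows, whose contours legitimately span octaves), the
final track is the best candidate path under an octave-jump transition
cost (dynamic programming), a median re-snap handles isolated outliers,
and a running 3-point median removes single-frame jitter. Voicing
requires a normalized peak of 0.45 (0.30 for bellows, whose swept
pulse-train frames correlate less tightly). Bellow contours are tracked
per inhalation segment — correlation frames must not straddle the splice
between segments — and the segment contours are stacked with unvoiced
separators so `sumvar` never spans a splice.

**Formants** (`measure_formants()`) follow the classic Burg recipe:
resample to twice the maximum formant (frequency-domain resampling — an
interpolation noise floor would bury the weaker formants), pre-emphasize
+6 dB/octave above 50 Hz, fit order-12 Burg AR models to 30 ms
Gaussian-windowed frames every 10 ms, convert pole pairs to frequencies
and bandwidths, discard candidates below 50 Hz or wider than 700 Hz, and
average over frames in which all six formants are found. The formant
spacing ΔF is the least-squares slope, through the origin, of the mean
formants on the odd-multiple predictor `(2i−1)/2` (the uniform
quarter-wave tube model); through-origin regression exactly reproduces
the study's printed spacings from its printed formant means.

**Nonlinear phenomena.** Chaos: the fraction of frames whose
harmonics-to-noise ratio (from the maximum normalized autocorrelation in
the periodicity search range) falls below 4 dB must reach 20%.
Subharmonics: the spectrum of 50 ms frames is probed at the low-order
inter-harmonic positions of F0/2 and F0/3 (orders m ≤ 5 — higher orders
are too weak to separate from modulation residue); a hit requires the
peak to stand 10 dB above the local floor *and* within 30 dB of its
flanking harmonics (so leakage over a near-silent floor cannot trigger),
in at least 3 consecutive voiced frames; frames whose F0 estimate is an
octave-type outlier are excluded; the ratio reported is the deepest
division found. Biphonation: the amplitude envelope (rectified, low-passed
at 400 Hz, kept below 0.75×F0 so rectification ripple is not mistaken for
modulation) must show a sharp spectral line in the 50–300 Hz band (10 dB
above the band's 90th percentile — broadband chaotic fluctuation has no
line), and G0 is the envelope pulse rate counted in a narrow band around
that line, required to agree with it within 15%.

## Statistics

The statistics stage consumes feature tables (calls × measures, with
metadata columns and `NA` for measures inapplicable to a call type;
analyses adopt the convention that an absent measure is zero, matching
how such tables are conventionally printed).

**Two-step clustering** (`two_step_cluster()`): agglomerative merging
under the log-likelihood distance
`d(a,b) = ξ_a + ξ_b − ξ_{a∪b}` with
`ξ_v = −N_v·[Σ_cont ½·ln(σ̂_k² + σ_vk²) + Σ_bin E_vk]`, where `σ̂_k²` is
the whole-table variance (a regularizer) and `E_vk` the category-proportion
entropy. The implementation is exact agglomeration (no pre-clustering
pass; at a few hundred calls the scalability device of the original
algorithm is unnecessary) with incremental sufficient statistics, checked
in the tests against a brute-force quadratic-time replay. Candidate
partitions at k = 2..6 are scored by the mean silhouette under the mixed
distance (Euclidean on z-scored continuous columns plus one unit per
binary mismatch; ties go to fewer clusters; singleton rows score 0). G0
is excluded from the clustering variables by default: it exists only when
biphonation is present, so a zero-filled G0 column alongside the
biphonation flag would double-weight one phenomenon and split the tonal
cluster along it.

**Discriminant analysis** (`discriminant_analysis()`): canonical functions
are eigenvectors of `W⁻¹B`; Wilks' Λ = Π 1/(1+λᵢ) with the χ²
approximation `−(n−1−(p+g)/2)·ln Λ` on `p(g−1)` df; the structure matrix
holds pooled within-group correlations between variables and canonical
scores. Classification uses linear discriminant scores with log-prior
offsets (priors proportional to group sizes by default), reported both by
resubstitution and by exact leave-one-out (full refit per held-out call).
Variables are standardized internally — every reported quantity is
invariant to that — because ΔF is an exact linear combination of F1–F6,
so the pooled covariance is singular by construction and is ridged
(λ = 10⁻⁶·trace/p) with a single warning. Leave-one-out rates are
compared to chance with the exact two-tailed binomial test
(point-probability method), both against 1/g (the convention used when
such rates are reported) and against the proportional-chance criterion
Σ priorᵢ²; both p-values are reported.

**MANOVA** (`manova_features()`): a single-predictor multivariate linear
model on per-subject mean measures (age as a covariate, sex as a
two-level factor), Wilks' Λ with Rao's F approximation, univariate
follow-up F tests, and effect directions (regression slope for age,
group-mean difference for sex). With one dependent variable the
multivariate test reduces exactly to the univariate F; with too few
subjects (n ≤ p+1) it is skipped with a warning and the univariate tests
are still returned. No multiple-testing correction is applied; all
univariate p-values are reported raw.

## What the synthetic data does and does not show

The generator emulates: three call classes with the study's parameter
means and SDs; stable individual signatures; age slopes on tonal F0;
male/female bellow differences; and the nonlinear-phenomena prevalences.
It does not emulate: recording-channel effects (noise, reverberation,
varying distance); the staccato introductory phase of bellows;
inter-feature correlations beyond the shared-individual structure;
F0-formant interaction; or perceptually realistic koala timbre. Passing
round-trip and recovery tests therefore demonstrates that the measurement
and statistics stages are correct and well calibrated on signals obeying
the stated production model — not that they would perform identically on
field recordings.

Default problem sizes mirror the analysed study design (12 callers × 8
bellows, 14 × 8 tonal calls, 6 × 5 snarls; a 20-male bellow cohort for
the sex contrast), and simulation-based tests use modest replicate counts
(50–100) with fixed seeds.

## Numerical choices and degenerate inputs

* Truncated-normal draws use the inverse CDF (no rejection loops), so a
  seed fixes every output exactly; `synthesize_call()` additionally uses
  the current RNG stream for its noise components.
* Resampling is frequency-domain with rational-ratio padding (both FFT
  lengths factor into small primes).
* The tonal chaos episode covers 45% of the call so that even the
  shortest calls (0.1 s) carry an episode comfortably above the
  detector's 20% frame fraction.
* Zero-variance table columns are rejected by the clustering stage;
  constant variables are reported as "not computable" by the univariate
  group tests rather than tested.
* Ties in cluster-count selection go to the smaller k; ties in merge
  costs resolve to the first pair in index order, making the
  agglomeration deterministic.

## Round-trip calibration and known limitations

The round-trip suite renders calls at the population defaults, re-measures
them, and compares against the generating parameters: duration within
10%, mean F0 within 5%, F0 extrema within 10%, formants and ΔF within 5%,
on at least 90% of a mixed batch; detectors score 100% on clean
single-phenomenon positives and 0% on clean negatives at default
thresholds. `sumvar` is asserted only loosely (within 30% where the
generating value is non-trivial): for very low-F0 calls the correlation
window inherently smooths modulation near the tracker's resolution, so
modulation-per-second is a tracker-relative quantity rather than a sharply
recoverable parameter. Calls combining several nonlinear phenomena can
defeat individual detectors in corner cases (a subharmonic stack plus
modulation near a quarter of F0 blankets the spectral reference
positions); the generator avoids those collisions, and on real data such
calls would need the visual inspection the original workflow used.
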