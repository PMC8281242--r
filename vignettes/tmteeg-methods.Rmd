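---
title: "Tablet TMT kinematics and EEG task PLS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tablet TMT kinematics and EEG task PLS: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmteeg)
```

# The problem

The Trail Making Test (TMT) asks a participant to link 25 encircled items in
ascending order with a stylus -- numbers only in part A, numbers alternating
with letters in the harder part B. Administered on a digitizing tablet during
EEG, the test yields two synchronized data streams per trial: a stylus
trajectory sampled at roughly 40 Hz, and a multichannel scalp voltage record
with triggers at every task-phase onset. `tmteeg` implements the full
analysis chain for such sessions:

1. **Kinematic segmentation** of the stylus speed time-course into *linking
   periods* (ballistic movements that connect two items) and *non-linking
   periods* (visual search and motor planning), and per-trial scoring
   (links, errors, seconds per link).
2. **Non-parametric behavioural statistics** comparing the two TMT parts.
3. **EEG preprocessing** (downsampling, band-pass, ICA artifact removal,
   mean-mastoid re-reference, epoching) and **Morlet wavelet band power**
   extraction masked by the behavioural segmentation.
4. **Task partial least squares (PLS)** on the resulting band-power
   features, with permutation and bootstrap inference.

Because no public recordings accompany this problem, the package's first
module is a synthetic-session generator whose statistical structure matches
what the analysis assumes. Every downstream stage is tested against that
generator's ground truth.

# The synthetic generator

## Stylus behaviour

A trial is a continuous-time alternation of pauses and linking strokes
through the item sequence:

* **Linking strokes** follow a straight line between item centres with a
  raised-cosine (Hann) speed bell, $v(u) = v_{pk}(1-\cos 2\pi u)/2$ --
  smooth acceleration to a single peak and symmetric deceleration, the shape
  seen in real linking movements. Each link's *average* speed is drawn
  log-normally (default meanlog $\log 284$ px/s, sdlog 0.3, matching
  published tablet-TMT magnitudes); its duration is distance/speed.
* **Pauses** have log-normal durations (default meanlog $\log 0.4$ s,
  sdlog 0.8, mean ≈ 0.55 s), reproducing the strong right skew of
  non-linking period distributions. During a pause the stylus stays pressed
  on the current item with a small AR(1) positional wander (step SD 0.05 px,
  pull-back 0.9) -- a resting stylus on a resistive touchscreen is
  essentially stationary up to quantization-level noise.
* **Part-B slowing** multiplies link and pause durations by configurable
  scales (default 1.25 each), emulating the higher cognitive demand of
  number-letter alternation. For a fixed seed the part-A and part-B layouts
  share coordinates, so part effects cannot arise from geometry.
* **Errors** are wrong-target links immediately followed by a correcting
  link (… 2→4, 4→3 …), at a default per-link rate of 0.01 -- young healthy
  adults average well under one error per trial.
* Timestamps are jittered uniformly by ±10% of the nominal 25 ms interval,
  since real tablet logging is only approximately 40 Hz.

The default display is 640 × 480 px with radius-20 stimuli and a minimum
centre separation of 60 px. With these defaults a typical part-A trial
completes in roughly 30 s of a 40 s block, with mean linking periods near
0.75 s and non-linking periods near 0.55 s -- the regime the analysis is
designed for.

## EEG

Each channel is $1/f$ background noise (spectral exponent 1, default RMS
5 µV) plus band-limited oscillators whose instantaneous amplitude follows
the behavioural condition of the current sample (baseline / non-link A /
non-link B / link A / link B), using the generator's own ground-truth link
masks. The default oscillator is a 10 Hz, 5 Hz-wide alpha source at 20 µV
RMS that halves during linking -- an idealized movement-related alpha
desynchronization. Oscillators project onto all scalp channels but not onto
TP9/TP10: the mastoids are chosen as reference sites precisely because they
are comparatively neutral, and a carrier present on them too would cancel
in the mean-mastoid re-reference. Optional stereotyped blink transients
(Gaussian bumps, SD 60 ms) load on the frontal channels.

EEG is simulated directly at 1000 Hz -- the pipeline's post-downsampling
rate -- with the option of 5000 Hz to exercise the decimation stage.

# Kinematics

Speed is the finite-difference displacement over the sample period,
assigned to pair midpoints. Pairs spanning a pen lift get speed zero and
are flagged, so lifted-gap interiors count as non-linking time. The chain
then follows the order: Sigma filter → low-pass → cubic-spline resampling
to 1000 Hz.

* **Sigma filter** (window 151 ms, cut 2 SD): within each centred time
  window, samples beyond 2 SD of the window mean are replaced by the mean
  of the window's non-outlier values; a window with no non-outliers falls
  back to its median (counted in an attribute). At the native rate the
  window spans ~6 samples.
* **Low-pass**: zero-phase Butterworth at 5 Hz — a 2nd-order design run
  forward and backward, i.e. a 4th-order zero-phase response. Zero phase
  keeps interval boundaries unshifted; the modest order matters too:
  sharper designs ring in the time domain at a few percent of each burst's
  peak, and those ringing lobes (tens of px/s beside a 500 px/s bell)
  masquerade as non-linking "noise" that the segmentation threshold must
  clear, clipping more of every bell's tails. With the gentler filter the
  pause noise floor stays at a few px/s and thresholds settle near 5 px/s.
  The series is odd-reflection padded before filtering because zero initial
  conditions would otherwise inject edge transients into a signal with a
  nonzero baseline.
* **Threshold segmentation**: the candidate threshold rises from 0 px/s in
  1 px/s steps until the number of supra-threshold excursions equals the
  expected link count. Excursions shorter than 50 ms are discarded and
  sub-threshold gaps shorter than 20 ms are merged, preventing noise-split
  links; both values are configurable. The count match must additionally
  hold for 3 consecutive steps: the manual procedure this automates
  accepted a threshold only when linking periods were *readily
  identifiable* as a consistent pattern, and the stability requirement
  rejects coincidental count matches at near-zero thresholds where noise
  excursions and merged links happen to balance.
* **Link scoring**: each linking period's target is the nearest stimulus to
  the stylus position at the period's end, within a capture radius of 1.5 ×
  stimulus radius; a link is correct when its target is the next unreached
  sequence item. Items crossed mid-link (no segmentation boundary there)
  are ignored. The capture-radius rule approximates the human "pause and
  turn" judgement; ends farther than the radius from every stimulus are
  flagged unresolved and counted conservatively among the errors.
* **Seconds per link (SPL)**: completion time (end of the final link if all
  24 correct links were made, otherwise the block duration) divided by the
  number of correct links.

Ground truth for a simulated trial includes the full raised-cosine bell of
every link, down to zero speed at its endpoints, while any positive
threshold necessarily clips the bell tails — mask recovery is bounded
below 1 by construction. Recovery is scored against the *visible* ground
truth (`visible_links()`): a final link cut by the block limit to a
fragment under 150 ms spends its whole fragment near zero speed, is
invisible to any threshold, and would not be counted by a human scorer
either. With the default generator, link counts are recovered exactly and
the temporal Jaccard overlap of the linking mask averages ≈ 0.95.

# Behavioural statistics

All tests are non-parametric, matching the strongly non-normal SPL and
period distributions: one-sample Kolmogorov-Smirnov (KS) against a
moment-matched normal for normality screening; Kruskal-Wallis across trial
numbers per part, followed (when significant) by Dunn's rank-based pairwise
z-tests with Šidák correction -- implemented directly, as no installed
package provides the rank-based Dunn procedure -- to flag leading trials
significantly slower than at least 4 later trials (habituation/learning
transients; under the intended data pattern this reduces to excluding
Trial 1 of each part, after which the trial effect is re-tested and absent);
Wilcoxon signed-rank tests on participant means and on per-participant
skewness between parts; two-sample KS on the pooled distributions; and
percentile bootstrap confidence intervals for histogram bin heights,
resampling participants (not trials, which are dependent within
participant) with 1000 resamples by default -- the resample count is a
convention, chosen to match the PLS resampling scale.

# EEG preprocessing

* **Downsampling** is anti-alias FIR filtering (cut-off at 80% of the
  target Nyquist) followed by integer decimation; trigger indices rescale
  with rounding to nearest.
* **Band-pass** is a windowed-sinc (Hamming) FIR, 0.1–100 Hz, applied with
  exact zero phase via FFT convolution and group-delay compensation with
  reflection padding. The order follows the low-edge transition width
  (default 0.1 Hz, ~33000 taps at 1000 Hz), so the recording must exceed
  the kernel length; the transition width is a parameter where a record is
  short or carries no drift.
* **Artifact removal** decomposes the recording with fast fixed-point ICA
  (`ica::icafast`) and removes components whose *artifact probability*
  exceeds 0.9. The scorer is pluggable; the default combines the frontal
  fraction of the mixing weights, component kurtosis, and the sub-5 Hz
  power fraction into a probability-like score that saturates for
  stereotyped blinks. A trained classifier could be substituted behind the
  same interface. ICA failure (e.g. rank deficiency) falls back to the
  identity with a warning rather than aborting a session.
* **Mean-mastoid re-reference** subtracts the TP9/TP10 average and drops
  both electrodes, leaving 30 analysis channels.
* **Epoching** cuts one segment per TMT trial from −10 s (the fixation
  baseline) to the block duration +2 s (edge-artifact guard), time 0 at the
  onset trigger: −10…42 s for part A, −10…62 s for part B. The first trial
  of each part is excluded by default, leaving 7 per part under the full
  design.

# Time-frequency analysis

Twenty complex Morlet wavelets span 0.1–50 Hz with geometric spacing
anchored exactly at both endpoints (adjacent ratio $500^{1/19} \approx
1.387$), all with 6 cycles, i.e. Gaussian time SD $\sigma_t = 6/(2\pi f)$.
Convolution is frequency-domain multiplication with analytic Gaussian
kernels of unit peak frequency response, making a fixed-amplitude sinusoid
read identical power at every centre frequency.

Wavelets are assigned to the five canonical bands (delta 0.3–4, theta 4–8,
alpha 8–13, beta 13–30, gamma 30–50 Hz) by containment; for each interior
boundary the single nearest wavelet (ties toward the lower frequency) joins
*both* adjacent bands, giving exactly four dual-membership wavelets and
slightly widened effective bands. The four wavelets below 0.3 Hz are
computed but excluded from band features: at 6 cycles their support exceeds
20 s, longer than the 2 s edge guard can protect, so their band-level
validity is not established.

Power is dB-normalized per channel and frequency against the mean power in
the −8…−1 s fixation window (trimming 2 s and 1 s from the 10 s fixation
against edge artifacts). Band-period features average the per-sample dB
values over the ground-truth (or estimated) linking and non-linking masks
within the performed duration, then over each band's wavelets, then over
trials — one value per condition × electrode × band per participant. The
masked averages are computed streaming one channel-wavelet pair at a time,
so the full channels × frequencies × time array is never materialized.

Two properties of this estimator are worth stating explicitly:

* Averaging *dB values* over time (a geometric mean of power) sits a few
  dB below the dB of the arithmetic mean for stochastic signals; the offset
  is common to the linking and non-linking features and cancels in their
  difference, which is the quantity the analysis interprets.
* Wavelet smoothing leaks power across period boundaries over a timescale
  of roughly $\sigma_t$. With period durations near 0.8 s and alpha-band
  $\sigma_t$ up to 136 ms, a halved-amplitude linking effect (analytic
  −6.02 dB) reads back biased toward zero by about 0.5 dB. The calibration
  experiment in the acceptance suite therefore uses a deliberate-pace
  cohort (~2.5 s periods, 60 s blocks, two trials per participant, six
  channels) in which the recovered alpha difference lies within ±0.7 dB of
  the analytic value; at default pace the residual boundary bias is a known
  limitation of period-masked wavelet power, not of the implementation.

# Task PLS

With feature rows stacked participants-within-conditions (X, column
mean-centred) and Y the one-hot condition indicator, the effect matrix
$E = X^\top Y$ is decomposed as $E = U S V^\top$. Columns of $U$ are
spatial saliences over electrode × band features, columns of $V$ are task
saliences over conditions, and LV $i$ explains $s_i^2/\sum_j s_j^2$ of the
cross-product variance (the squared convention is configurable). Column
centring makes $E$ proportional to condition-mean deviations -- the
standard task-PLS formulation; the full cohort gives the 64 × 150 design.

Inference is entirely resampling-based, with explicit seeds throughout:

* **Permutation test** (default 1000): condition labels are shuffled
  *within participant*, respecting the repeated-measures structure;
  $p_i = (1 + \#\{s_i^{perm} \ge s_i\})/(n_{perm}+1)$, so $p \ge
  1/(n_{perm}+1)$ always.
* **Bootstrap** (default 1000): participants are resampled with
  replacement, all four condition rows together; each resample's LVs are
  sign-aligned to the observed saliences (SVD signs are arbitrary, and
  unaligned resamples would inflate the SD). Bootstrap ratios (BSR) are
  bootstrap mean loadings over bootstrap SDs; zero-SD cells report signed
  infinity and are excluded from maps.
* **Contrast saliences**: for every condition pair, the paired differences
  of LV1 task-salience bootstrap resamples give a mean, SD and BSR. The
  source description of this step admits two readings (paired differences
  vs differences against permuted resamples); the paired-difference reading
  is implemented as the one that yields a well-defined stability measure,
  and the alternative is noted here.
* **Thresholded maps**: BSRs convert to two-tailed p-values through the
  standard normal tail, Benjamini-Hochberg FDR at $q = 0.05$ runs across
  all 150 electrode × band saliences of the LV jointly (the granularity at
  which maps are displayed), and surviving entries must additionally pass
  $|BSR| > 2$; everything else is zeroed.

Two-condition subtests (link B vs link A, etc., and the combined
link (A+B) vs non-link (A+B), whose features are elementwise sums across
parts) reuse the same machinery but suppress LV p-values and variance
explained, which are fixed by construction when only two conditions enter.

# Pipeline

`run_pipeline()` chains simulate → behavior → eeg → pls with a JSON
config merged over defaults; each stage consumes only the files of earlier
stages, so runs restart cleanly. Every output bundle carries the seed and a
hash of the scientific configuration (output paths excluded, so identical
parameters hash identically anywhere). The orchestration is exposed as R
functions rather than a shell executable: the package's users drive it from
R, and the functions compose with scripts where a shell entry point is
wanted.

# Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to exercise the full stack while staying desk-scale: 112
trials for segmentation recovery, 50 cohort replicates of 16 participants
for the behavioural direction (trial metrics taken from generator ground
truth there — segmentation recovery is established separately, and
re-segmenting 12800 trials would only re-measure it), 16 simulated EEG
participants (six channels, two 60 s trials each) for the time-frequency
calibration, 1000/1000 permutation/bootstrap resamples for the PLS
recovery run and 250 for the 20-replicate null calibration. All randomness flows from explicit seeds;
identical seeds give byte-identical session files.

# What passing tests do and do not show

The generator matches the *statistical structure* the analysis assumes:
bell-shaped bursts between right-skewed pauses, part-B slowing,
condition-locked band-limited oscillations on a $1/f$ background, triggers
at exact onsets. It deliberately omits much of real EEG: volume-conducted
correlated sources, non-stationary artifact mixtures, electrode drift and
impedance changes, muscle and line noise, and genuine within-participant
behavioural autocorrelation. Passing the suite therefore demonstrates that
the implementation is correct and internally calibrated -- effect sizes
injected in known units are recovered at the expected magnitudes and null
calibration holds -- not that any scientific conclusion transfers to real
recordings. The ICA scorer in particular is a simple statistical stand-in
behind the same interface a trained classifier would use.

# Known limitations

* Period-masked wavelet power is biased toward zero near period boundaries
  (quantified above); short linking periods exacerbate it.
* The capture-radius link scorer approximates, not replicates, human
  judgement of intentional targets.
* The threshold search inherits the manual procedure's assumption that a
  count-matching threshold exists; trials where no stable threshold matches
  raise an explicit segmentation error rather than guessing.
* Layouts are generated, not replicas of the standard TMT sheet, whose
  exact coordinates are not published; all geometry-dependent quantities
  are therefore internally consistent rather than form-identical.
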