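---
title: "Methods: spectral parameterization and decoding of resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral parameterization and decoding of resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(specdecode)
```

## The scientific question

Resting-state EEG power spectra carry candidate correlates of stable traits
(fluid and crystallized intelligence) and momentary states (sleepiness).
Because a raw ("total") power spectrum mixes two very different generators —
a 1/f-like aperiodic background and genuinely oscillatory activity — the
package analyses three signal families separately: total spectral power per
1-Hz bin, the periodic (peak) component after removing the aperiodic fit,
and the aperiodic parameters themselves (offset and exponent). The decoding
question is multivariate: can a score be predicted from the pattern of power
across all channels within one frequency bin?

Real multi-site resting-state cohorts of this kind are not freely
redistributable, so the package is built around a synthetic-cohort module
with known ground truth; every downstream stage is testable end to end.

## The spectrum model

All simulation and fitting uses the standard 1/f-plus-peaks form in log10
power,

$$\log_{10} P(f) \;=\; a \;-\; \chi \,\log_{10} f \;+\;
  \sum_k h_k \exp\!\left(-\frac{(f - c_k)^2}{2 w_k^2}\right) \;+\;
  \varepsilon,\qquad \varepsilon \sim N(0, \sigma_n^2),$$

with offset $a$ (log10 µV²/Hz), exponent $\chi$ (unitless), Gaussian peaks
with center $c_k$ (Hz), height $h_k$ (log10 power above the background) and
width $w_k$ (Gaussian SD, Hz), and spectral estimation noise
$\sigma_n$. The analysis grid is 0.5–30 Hz in 0.5-Hz steps (60 points),
the resolution of a 2-s FFT epoch; 1-Hz bins average consecutive pairs, so
the 1-Hz bin contains the 0.5- and 1.0-Hz grid values.

## Synthetic cohorts

`simulate_cohort()` draws per-participant spectra: offsets U(0.5, 2),
exponents U(0.8, 2), one alpha peak per participant (center ~ N(10, 0.8)
clipped to 8.5–12 Hz, height U(0.3, 0.8), SD U(1, 2) Hz), a theta peak for
a random 30%, small channel-level jitter, and log-power noise
(`noise_sd = 0.05` by default). Eyes-closed conditions get a +0.15 alpha
height boost. Behavioral marginals are chosen to look like a young student
sample: fluid scores are integers 0–20 with variance near 7, sleepiness
composites are built from two 7-point items through `build_sleepiness()`.
The default cohort (300 participants, 16 channels, 2 conditions) is small
enough for continuous testing; the 59-channel four-condition layout of a
multi-site study is available through `cohort_config()`.

Recordings, when needed, come from spectral shaping of white Gaussian
noise (`simulate_recording()`): the one-sided PSD of unit white noise is
flattened to the model target, so Gaussian spectral peaks become
narrowband-filtered Gaussian noise — non-phase-locked oscillations rather
than sinusoids. The shaped band extends slightly beyond the analysis band
(0.25–32 Hz) so Welch estimates at 0.5 and 30 Hz are not attenuated by
leakage from a hard band edge.

**Planted associations.** `plant_association()` rewrites each
participant's mean log band power $b_i$ over the named channels as
$b_i' = \mu_b + \sigma_b\,(r\, z_{s,i} + \sqrt{1-r^2}\, z_{b,i})$, where
$z_s$ are the standardized scores, and adds the shift uniformly inside the
band (or to the whole spectrum for aperiodic-offset associations). The
*band-mean* correlation therefore hits the target $r$; single 1-Hz bins
correlate lower because bin power carries variance orthogonal to the band
mean (peak-center and exponent variability). A planted band-level $r = 0.4$
typically yields per-bin decoding around $r \approx 0.2\!-\!0.35$ — worth
keeping in mind when reading power results. `target_r = 0` is exactly the
identity, which is how null cohorts are built.

**What the generator does not emulate:** volume conduction and channel
covariance from a head model, eye-blink/EMG artifact morphology (only the
three rejection criteria are exercised), non-stationarity within blocks,
and site/reference heterogeneity. Passing tests demonstrate the analysis
machinery is correct and calibrated, not that real-data effect sizes will
transfer.

## Preprocessing

* **Filtering.** Linear-phase Hamming-window FIR band-pass 0.5–30 Hz,
  applied forward and backward (zero phase) with edge padding. The
  transition half-width is ~0.4 Hz (about 4.1 s of taps), keeping the
  passband intact from 1 Hz while pushing 0.1 Hz and 40 Hz more than 20 dB
  down. Recordings shorter than three filter lengths are rejected.
* **Bad channels.** A channel is bad if |z| > 3 across channels on any of:
  log variance, median absolute amplitude, or absolute deviation of the
  channel mean from the grand mean. Identical channels produce no flags
  (zero spread ⇒ z = 0). A participant is dropped when more than four
  channels are bad.
* **Epoching.** 1-min blocks (each onset delayed by `delay_s`, default
  0.5 s — the delay after a block-onset tone is a free parameter) are cut
  into 2-s epochs every 1 s; partial trailing epochs are dropped, so a 60-s
  block yields 59 epochs.
* **Artifact criteria.** An epoch is rejected when any channel (1) exceeds
  a 50 µV/ms gradient between consecutive samples — stated per ms so the
  rule is sampling-rate independent; (2) spans more than 200 µV
  peak-to-peak in any sliding 200-ms window; or (3) spans less than 0.5 µV
  in any sliding 100-ms window (flatline). Windows advance sample by
  sample; rejection is whole-epoch (channels must stay aligned for the
  multivariate feature vector), and every rejection records its reasons.
* **Spectra.** Hamming-tapered FFT per epoch, one-sided PSD with window
  power compensation (division by the mean squared window), averaged over
  retained epochs in linear power; log10 is taken only downstream by the
  spectral fit. Integrated band power of a unit sinusoid equals A²/2 and
  band sums obey Parseval, which the tests assert.

## Spectral parameterization

`parameterize()` reimplements the standard fixed-mode
(no-knee) parameterization loop per channel:

1. plain least-squares line in (log10 f, log10 P);
2. peak extraction on the residual;
3. subtraction of the peak model, then a *robust* line re-fit: residuals of
   a first pass are floored at zero and only frequencies at or below the
   low-percentile threshold of the floored residuals are kept — i.e. the
   frequencies not elevated above the line — before re-fitting;
4. a final peak pass on the final residual.

The periodic spectrum is *defined* as log10(total) − aperiodic fit, so the
decomposition is conservative by construction. Peak detection iterates:
take the residual maximum, stop when its height drops below 2.0 residual
SDs (recomputed each iteration) or the absolute floor (default 0),
estimate the Gaussian SD from the half-height extent (falling back to twice
the grid step when unresolvable), clip the SD into [0.5, 6] Hz (half the
nominal [1, 12] width limits, which bound the 2·SD width), and subtract.
Numerical guards, chosen here because the published settings leave them
open:

* candidates whose centers lie within 1.0 Hz of the grid edges are
  discarded (boundary-artifact guard);
* a candidate whose immediate neighbours fall below half its height is
  treated as a one-point sampling spike, not an oscillation, and skipped —
  with 60 grid points the expected maximum of pure noise exceeds 2 SDs,
  so a literal threshold alone would hallucinate peaks on ~3 of 4 null
  spectra;
* all surviving peaks are refined jointly by bounded Levenberg–Marquardt
  least squares (centers within ±1.5 SD of their guess, heights ≥ 0, SDs
  within limits; ftol = ptol = 1e-8, ≤ 500 iterations); a singular fit
  keeps the iterative estimates.

On the package's recovery suite (offsets U(0.5, 2), exponents U(0.8, 2),
0–2 peaks, noise SD 0.02) median absolute errors are ~0.01 for the exponent
and ~0.02 for the offset.

## Decoding

Per frequency bin, scores are predicted from the channel pattern with a
linear ε-insensitive SVR,

$$\min_{w, b}\ \tfrac12\lVert w\rVert^2 + C \sum_i
  \max(0, |w^\top x_i + b - y_i| - \varepsilon),$$

with C = 1 and ε = 0.1 — common LIBSVM-style defaults, exposed in the
configuration; no internal tuning. Features and scores are standardized by
training-fold statistics (so ε is in score-SD units and constant columns
map to zero rather than being dropped); predictions are mapped back to the
raw scale. The solver is the package's own dual coordinate-descent
implementation of this exact objective (bias as an augmented feature,
deterministic shuffled sweeps, default 60-sweep cap) — profiling showed a
general-purpose kernel-SVM QP spends tens of milliseconds per fit at these
problem sizes, which the permutation suites (10⁵–10⁶ fits) cannot afford;
the test suite cross-checks the solver against LIBSVM (`e1071`) to
prediction correlation > 0.999.

Cross-validation is tenfold, repeated 10 times with re-randomized fold
assignment, stratified over five score quantile strata (plain random
available). Decoding performance per repetition is the Pearson r between
pooled out-of-fold predictions and the true scores (per-fold averaging is a
config alternative); repetitions are Fisher-Z averaged and transformed
back. Negative r values are reported as-is.

**Permutation inference.** Scores are permuted B times (1,000 at study
scale) and the full decode re-run per permutation, by default with 2 CV
repetitions instead of 10 — the null's quantiles are driven by the
permutation, not the repetition average, and the reduction was validated on
synthetic nulls. One-sided upper-tail p-values use the add-one rule
p = (1 + #{null ≥ r_obs}) / (1 + B), so p > 0 always.

**Cluster correction** thresholds per-bin p at α = .01 and keeps maximal
runs of ≥ 2 adjacent significant bins (thresholding, not cluster-mass
permutation — the simpler rule; users comparing to mass-based cluster
statistics should note the difference). **Meaningfulness** requires
observed r ≥ .20 in *every* condition (a sensitivity variant at .13 is a
parameter). **Group differences** on cluster-mean decoding use the
Fisher-z two-sample test
$z = (Z(r_A) - Z(r_B)) / \sqrt{1/(n_A-3) + 1/(n_B-3)}$ with Holm
correction across clusters.

## Statistics battery

* Sleepiness composites average the z-scores of the tiredness and
  exhaustion items. Standardization pools both timepoints by default: the
  pooled composite mean is ~0 while the pre/post level difference — the
  quantity the paired t test addresses — survives. (Within-timepoint
  standardization, available as an option, would force both means to zero
  and make the paired comparison vacuous.)
* Spearman rho is the Pearson correlation of average ranks; its 95% CI
  uses the Fisher transform with the Bonett–Wright standard error
  √((1 + ρ²/2)/(n − 3)) — chosen because it is accurate for rank
  correlations at these n and needs no resampling; p from the t
  approximation. Partial Spearman applies the first-order partial formula
  to ranks.
* Holm and Benjamini–Hochberg adjustments delegate to `stats::p.adjust`;
  the test suite verifies both against independent brute-force step-down /
  step-up implementations on an exhaustive grid.
* The outlier screen is one-sided (scores below mean − 3.3 SD), matching a
  floor-effect reading; two-sided is an option.
* Cohen's d for the pre/post sleepiness shift is d_av — mean difference
  over the average of the two SDs — with a normal-approximation CI using
  SE(d) = √(2(1−r)/n + d²/(2(n−1))). The variant is a config choice
  (d_z available) because printed effect sizes of this kind are often not
  exactly recoverable from summary statistics under any single variant.

## Reproducibility and problem sizes

Every stage draws its randomness from a child seed derived by a
deterministic string hash `seed_for(master, ...)`, so adding analysis
cells never perturbs existing ones, and two runs with the same
configuration and seed produce byte-identical result manifests (the
pipeline writes MD5 checksums of every output file).

The packaged validation suites run at deliberately modest sizes chosen to
keep the whole test run in the tens of minutes on one core while leaving
each property's statistical margin intact: null calibration pools one decoded bin's permutation p-value from each of
180 independent 300-participant null cohorts (cycling through all 30
bins), B = 500 permutations at 2 CV repetitions each, and requires the
Kolmogorov–Smirnov distance from uniform to stay below 0.1 — within one
cohort the per-bin p-values co-move through the shared participant-level
broadband power factor, so independent cohorts, not extra bins, carry the
information this bound needs;
the meaningfulness null check uses 20 four-condition cohorts at 2 CV
repetitions; cluster power uses 20 cohorts of n = 400 with a planted
band-level r = 0.4 alpha association, B = 199 and 1 permutation
repetition; artifact detection uses 150+ injected events (≥50 per
criterion). Study-scale settings (59 channels, four conditions, B = 1,000,
10 permutation repetitions) are configuration values, not code changes.

## Known limitations

* The spectral fit guarantees no bit-level agreement with any specific
  release of the reference Python toolbox; internal defaults not restated
  in published settings (e.g. proximity-based peak pruning) are replaced by
  the documented guards above.
* Cluster inference is threshold-based, not mass-based.
* The EDF I/O covers the plain 16-bit subset the package writes (equal
  sampling rate per channel, no annotations).
* Aperiodic fitting is fixed-mode only; spectra with a visible knee will
  bias the exponent.
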