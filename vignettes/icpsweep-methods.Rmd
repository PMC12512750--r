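---
title: "Methods: microwave sweep processing for noninvasive ICP estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microwave sweep processing for noninvasive ICP estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpsweep)
```

## The measurement model

A two-antenna microwave sensor on the scalp records, at every sweep of a
vector network analyser, four curves over a 2–6 GHz grid: magnitude (dB)
and phase (rad) of the reflection coefficient $S_{XX}$ and the
transmission coefficient $S_{XY}$. Rising intracranial pressure changes
the volume balance of brain tissue, blood and cerebrospinal fluid under
the antennas, which perturbs the effective dielectric profile and with it
the propagation of the microwave signal. The information-bearing
signatures are concentrated near the sensor's resonance: the depth,
frequency and phase of the resonant dip all track pressure.

`icpsweep` estimates pressure from those signatures in five stages:
cleaning and band selection, dataset-variant creation, per-sweep feature
extraction, correlation-ranked feature selection, and regression over a
fixed model catalogue. Each stage is a pure function of its inputs, its
configuration and a seed, so any stage can be re-run from its serialized
inputs and reproduce its outputs bit for bit.

## The phantom simulator

The reference experiments behind this pipeline were performed on a
head-phantom test bench whose raw data are not publicly available, so the
package ships a forward simulator (`simulate_trial()`) that reproduces the
*statistical structure* the pipeline assumes, with the protocol constants
of the bench:

* frequency grid 2–6 GHz at 2001 points (`freq_grid()`),
* sweep rate 3 Hz, invasive reference stream at 5 kHz,
* a trial = a flat pre-pump lead segment, then a linear filling ramp from
  0 to 60 mmHg driven by a dosing pump at 60 beats/min,
* additive Gaussian trace noise of RMS $5\times10^{-3}$ dB on magnitudes.

Six sensor profiles (A–F) are modelled as flat baselines carved by
Lorentzian dips at the sensors' published resonance frequencies and
depths (e.g. sensor A: $-35.3$ dB reflection dip at 3.565 GHz; sensor B:
$-65.87$ dB transmission dip at 3.604 GHz). Dip centres are snapped onto
the supplied grid so that the sampled minimum is exact. One printed pair
of constants is internally inconsistent: a 2001-point 2–6 GHz grid has
2 MHz spacing, on which 3.565 GHz is not representable; the profile
therefore resonates at the nearest representable bin (3.564 GHz on the
standard grid), one half-step from the nominal value.

Pressure couples into the sweeps through three linear channels
(`coupling_model()`): an amplitude offset $\alpha\,p(t)$ carried by a
Gaussian spectral bump centred at the resonance (width 50 MHz, matching
the analysis band so that the planted information lives where the band
selector looks), a resonance shift $\beta\,p(t)$ applied by
frequency-shifting the baseline curves, and a phase offset
$\gamma\,p(t)$. **The coupling magnitudes are synthetic.** The physical
mechanism is documented; its quantitative strength on a real head is not,
so the defaults ($\alpha = -0.05$ dB/mmHg, $\beta = 0.1$ MHz/mmHg,
$\gamma = 2\times10^{-3}$ rad/mmHg) were chosen once so that the planted
feature classes correlate with pressure at $|r| > 0.9$ under the default
noise floor — i.e. the simulator realizes the regime the reference
experiments report, rather than estimating bench physics. Consequences
for interpretation: passing the package's recovery tests demonstrates
that the *pipeline* extracts and ranks pressure-coupled structure
correctly and that its bookkeeping, splits and metrics are sound; it does
not validate the microwave sensing physics, drift, motion artefacts,
inter-subject variability or any other property of real measurements.

The pulsatile component of the reference trajectory is a zero-mean
sinusoidal beat superposed on the ramp, active only while the pump runs.
A beat waveform that is zero-mean *and* zero-valued at beat boundaries
was chosen deliberately: the trajectory then enters the pumping phase
continuously and terminates exactly at the 60 mmHg ramp target, and the
mean over any whole beat equals the ramp value at the beat centre (which
the alignment tests exploit).

## Input/output and synchronization

Trials serialize as one two-port Touchstone `.s2p` file per sweep
(dB/angle, GHz, written from the unwrapped internal phases), a reference
CSV (`time_s,p_mmHg,t_C`) and a YAML manifest holding sensor, placement,
grid and the trigger log. The reader accepts the dB/angle, linear
magnitude/angle and real/imaginary dialects and unwraps phases along
frequency on ingestion. Angles are written unwrapped rather than wrapped
to $(-180°, 180°]$: wrapping would discard the absolute $2\pi k$ offset,
which the fluctuation features of phase are sensitive to, and would break
the write–read identity that stage reproducibility relies on. Files from
instruments that wrap are still read correctly, since the reader unwraps
whatever it receives.

Each sweep's reference pressure is the mean of the reference stream over
one sweep period centred on the sweep's trigger timestamp. A window mean
(not nearest-sample lookup) reflects that the analyser integrates over
its acquisition interval, and it suppresses aliasing of the 1 Hz
pulsatile component sampled at 3 Hz.

## Preprocessing choices

*Cleaning.* Every data string (the temporal series of one frequency bin
of one channel) passes a Hampel filter — window 11 samples, threshold 3
scaled MADs, windows truncated at the series edges so the first and last
samples are screened too — followed by z-scoring; zero-variance strings
map to zeros instead of dividing by zero. The window and threshold are
implementation defaults: the procedure (outlier detection plus
normalization) is prescribed, its parameters are not. Raw (cleaned,
unnormalized) dB values feed the feature stage, since Pearson correlation
is affine-invariant and dB magnitudes keep features interpretable.

*Band selection.* For every bin, the temporal range (max − min across
sweeps) of the reflection magnitude is computed; the optimal frequency is
the bin maximizing that range, and the band is the closed ±50 MHz
interval around it, clipped to the grid. The nested MAX/MIN statistic in
the source description is ambiguous; the per-bin-range reading is the
default because it is defined for every input. The alternative reading —
the range of per-sweep minimum *values* grouped by their located bin — is
available as `optimal_frequency(..., variant = "located")` but is
undefined when no bin hosts repeated minima. Only the reflection channel
drives band selection, and the single resulting band is applied to all
four channels; ties everywhere break toward the lowest frequency.

*Time limiting.* The leading pressure-quiet segment is removed: onset is
the first sweep whose centred slope estimate of aligned pressure exceeds
0.1 mmHg/s (one-sided differences at the edges), and the record is kept
through the sweep where pressure first attains its maximum. Pre-onset
sweeps are retained separately as the quiet baseline for the differential
features. The 0.1 mmHg/s threshold is an implementation default, far
below the default ramp slope (~0.55 mmHg/s) and above slope noise at the
default trace-noise level.

## Dataset variants and splits

Each processed trial yields four overlapping variants — full record,
first 80 %, last 80 %, and middle 80 % (10 % to 90 %) — which stabilizes
correlation analysis against edge effects. Percentages apply to sample
counts with round-half-up; the middle variant spans
`[round(0.1N)+1, round(0.1N)+round(0.8N)]` so all three partial variants
retain exactly `round(0.8N)` sweeps. Twenty-five trials per sensor
(5 placements × 5 repeats) therefore produce 100 variants and, with 12
feature classes each, 1200 feature records per sensor.

Train/test/validation splitting is by whole trials, never by samples:
sweeps within a trial are strongly autocorrelated, and sample-level
splits would leak. Proportions 80/10/10 use largest-remainder rounding
with every role guaranteed non-empty from three trials up; the evaluation
stage independently refuses any test trial that participated in training.

## Feature definitions

Level 1 features are extrema (with located frequencies) and trapezoidal
AUC of the four band-limited channel curves. Level 2 applies the same
descriptors to derived quantities whose exact bench definitions were not
available; the package adopts standard-literature forms, implemented as
documented, swappable functions:

* **MDM$_D$** — per sweep and bin, the symmetric two-port dB-magnitude
  matrix minus the element-wise mean of the baseline frames (the last ≤5
  pre-onset sweeps when available, else the first 5 sweeps), reduced per
  bin by the Frobenius norm scaled by $1/\sqrt2$, which equals
  $\sqrt{\Delta S_{XX}^2 + \Delta S_{XY}^2}$ — so a step of $d$ dB
  confined to one measured channel maps to exactly $|d|$.
* **RMS-MDM** — the RMS of the MDM$_D$ curve over the band, per sweep.
* **GDD** — group delay $\tau(f) = -(1/2\pi)\,d\phi/df$ by central
  differences on the unwrapped phase, minus its band mean; the scalar
  feature is the AUC of $|\tau - \bar\tau|$. Linear phase (constant
  delay) maps to zero exactly.
* **PerAF** — $100 \cdot \mathrm{mean}|x - \mu| / |\mu|$ with $\mu$ the
  band mean; positive-scale-invariant, masked (NA) when $\mu = 0$.

All per-sweep descriptors are computed over the *frequency* axis within
the optimal band, producing per-sweep time series correlatable with
pressure — this resolves the source's silence on the axis of AUC/PerAF.
The 12 classes are `a`/`b` = band minima of $|S_{XX}|$/$|S_{XY}|$,
`c`/`d` = their AUCs, `e`/`f` = AUC of |GDD| of the two phases, `g` = AUC
of MDM$_D$, `h` = a 5-sweep moving AUC over *time* of RMS-MDM (the time
window distinguishes `h` from `g`, which are otherwise near-duplicates),
`i`–`l` = PerAF of the four channels.

## Selection and regression

Each (trial, variant, class) series is Pearson-correlated with its
synchronized pressure; p values come from the t transform with $n-2$
degrees of freedom. Strength bins follow the conventional boundaries on
$|r|$ (0.8, 0.6, 0.4, 0.2), with boundary values falling in the lower
bin. The Ordered Selection Scheme sorts classes by score — the mean of
$|r|$ across a class's series — and keeps those strictly above the 0.8
threshold. A significance gate excludes classes whose median p value
reaches 0.001; the source states both 0.001 and 0.05 in different places,
so the stricter level is the default and the gate is configurable
(`sig_level`, `NULL` disables). No multiple-testing correction is
applied, deliberately mirroring the reference analysis; this is a known
limitation.

The regression catalogue fixes 25 presets across seven families. Exact
parity with the reference implementation's internals is not claimed;
hyperparameters that were never printed are fixed at documented defaults
(SVM cost 1 and ε 0.1 with MATLAB-style kernel scales
$\sqrt P/4, \sqrt P, 4\sqrt P$; trees with leaf sizes 4/12/36; boosting
with 150 rounds at learning rate 0.1; bagging with 200 trees; GP noise SD
0.1 on standardized targets with median-heuristic length scales; single-
layer networks via `nnet` with weight decay $10^{-3}$; two- and
three-layer 10-unit networks via an in-package BFGS-trained MLP; kernel
presets via a 100-dimensional random Fourier feature expansion feeding a
linear SVM or least squares). The Gaussian-process presets share one
exact posterior-mean solver because two of the four required kernels
(Matérn 5/2, rational quadratic) have no native implementation in the
available GP package — which instead serves as an independent
cross-check of the squared-exponential route in the tests. $R^2$ is
computed on the evaluated set against its own mean; a zero-variance
target is reported as $R^2 = 0$ with a degeneracy flag. Model selection
takes the lowest validation RMSE (ties: lower MAE, then catalogue
order). Prediction throughput is logged but never used for selection or
acceptance, being hardware-dependent.

## Numerical conventions

Magnitudes are processed in dB throughout; phases are radians internally,
unwrapped along frequency before any phase-derived computation, degrees
only in Touchstone files. Fractions of sample counts round half up.
Ties in every argmin/argmax break toward the lowest frequency. Degenerate
inputs fail loudly with typed conditions (`icp_degenerate_input`,
`icp_invalid_config`, `icp_leakage_error`, ...) rather than returning
silent defaults. All randomness — simulation noise, split permutations,
CV folds, stochastic fits — derives from explicit integer seeds, and
identical configurations reproduce identical outputs.

## Problem sizes used by the packaged checks

The test suite exercises the complete six-sensor campaign bookkeeping
(6 × 25 trials, 100 variants and 1200 feature records per sensor) on
reduced per-trial sweep counts — 12 s trials (36 sweeps) on a 201-point
grid with a 150 Hz reference stream — which preserves every count the
protocol fixes while keeping each trial small. Parameter-recovery checks
run the full 25-preset catalogue on one sensor's campaign (the Ds₁
matrices, validation-set model selection) and a three-preset
cross-family subset on the remaining five sensors; the five-fold
trial-level CV path is exercised separately on a compact fixture. These
sizes are the package's own verification policy: they are large enough
to pin the invariants and planted-signal recovery, and deliberately far
from a bench-scale electromagnetic study.

## Known limitations

* The simulator is a statistical stand-in: linear couplings, stationary
  Gaussian trace noise, no drift, no motion, no temperature dependence of
  the dielectrics, no inter-subject geometry variation.
* Adopted Level 2 formulas (MDM, GDD, PerAF) follow standard literature
  definitions, not a verified bench implementation.
* Correlation-based selection is univariate; jointly informative but
  marginally weak features are invisible to the OSS by construction.
* Reported phantom-bench performance figures from the reference
  experiments are not reproducible without the original measurements and
  are not asserted anywhere in this package.
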