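---
title: "Difference compressed sensing for serial 2D NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference compressed sensing for serial 2D NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsnmr)
```

## The problem

Serial 2D NMR experiments — variable-temperature, variable-pressure, or
titration series — need many spectra of the *same* system under slightly
different conditions. Acquiring each 2D spectrum at full Nyquist sampling of
the indirect dimension takes hours, so non-uniform sampling (NUS) with
compressed-sensing (CS) reconstruction is attractive. CS works when the
spectrum is sparse: reliable recovery of $N$ spectral points needs roughly

$$M \sim K \log(N/K)$$

sampled points, where $K$ is the number of significant points. Crowded
spectra of intrinsically disordered proteins are *not* sparse, so plain CS
needs a large $M$ and saves little time.

Difference compressed sensing (DCS) exploits the redundancy of a series.
Given a fully sampled reference signal $f_A(t_1, t_2)$ and an undersampled
target $f_B^{NUS}(t_1, t_2)$, the reference is restricted to the target's
sampling schedule and subtracted:

$$f_{diff}^{NUS} = f_B^{NUS} - f_A^{NUS}.$$

Peaks that did not change between the two measurements vanish from the
difference, so its spectrum is far sparser than either original and
reconstructs well from few points. After reconstruction the conventionally
processed reference spectrum is added back:

$$S_B^{rec}(\omega_1, \omega_2) = S_{diff}^{rec}(\omega_1, \omega_2) + S_A^{full}(\omega_1, \omega_2).$$

The subtraction doubles the noise variance ($\sqrt{2}$ amplification of the
noise amplitude), so DCS wins when the difference is sparse (few peaks
changed, low $M$) and loses to plain CS when many peaks changed or the data
is noisy — the two methods are complementary, and both are provided here
behind the same processing conventions so they can be compared on identical
schedules.

## Processing conventions

All routes (plain FT, CS, DCS) share one set of conventions, so identities
like "DCS of an unchanged target equals the reference spectrum *exactly*"
hold to the last bit:

* **Quadrature**: one complex value per $t_1$ increment (States-equivalent);
  a NUS "point" is one complex increment.
* **Apodization**: cosine-squared over the acquired points in both
  dimensions (configurable; `"none"` for diagnostics).
* **First-point scaling**: the $t = 0$ sample is halved in each transformed
  dimension. Besides the usual baseline-offset correction, this makes the
  one-sided FT and the virtual-echo FT agree exactly (see below).
* **Zero filling**: 2x in both dimensions by default.
* **Frequency axes**: index 1 sits at $+SW/2$ relative to the carrier and
  frequency decreases with index; ppm values come from the carrier and base
  frequency.
* **Phasing**: synthetic data is generated with zero phase, so real parts
  are absorptive. Phase-correction parameters for measured data are accepted
  as inputs; automated phasing is out of scope.

## Reconstruction: IST with virtual echo

Each $\omega_2$ column of the direct-dimension-transformed interferogram is
reconstructed independently by iterative soft thresholding (IST):

1. symmetrize the measured column by conjugate time reversal (*virtual
   echo*): $v[-t] = \overline{v[t]}$ on a circular grid, $t = 0$ stored
   once. The spectrum of the symmetrized signal is exactly real and sparser
   (absorptive, no dispersive component), and on full sampling equals twice
   the conventional FT with the first point halved — which is why the
   first-point convention above makes the two routes coincide;
2. iterate: FFT the current estimate, soft-threshold the spectrum at
   $\tau_k$, inverse FFT, restore measured points to their measured values;
3. return the transform of the final data-consistent estimate, so measured
   points are honored exactly and no soft-threshold amplitude bias is
   carried into the output.

Points beyond the acquisition window are known to be zero (zero filling)
and are held fixed; only the schedule gaps are inferred. At full sampling
there is nothing to infer and the output *equals* the conventional FT.

**Threshold schedule.** $\tau_k = \rho^k \max|X_0|$ per column, with
$\rho = 0.96$ and 200 iterations by default, i.e. the final threshold is
$\approx 3 \times 10^{-4}$ of the initial spectrum maximum. The decay depth
matters: stopping at a few percent of the maximum (e.g. $\rho = 0.99$ over
200 iterations, which stops at 13%) suppresses weak peaks and biases
heights by over 10% on a three-peak test column, while $\rho = 0.96$
recovers them to $\sim$0.1%. Both $\rho$ and the iteration count are
configurable (`recon_config()`), and a `fixed_fraction` schedule is
available for experimentation.

**Noise behavior.** A deeply decayed threshold means pure measured noise is
explained sparsely: on signal-free data the reconstruction concentrates
part of the noise into isolated single-point spikes of up to roughly twice
the full-data noise maximum, while the overall noise energy is *not*
amplified. A noise-capped threshold would avoid the spikes but measurably
biases peak heights, which are the quantity of interest here; real peaks
are distinguishable from the spikes by their multi-point lineshape.

## Reference alignment

Small condition differences (sample change, dilution, temperature drift)
shift peak positions and change linewidths between reference and target,
which would leave residual dipole-like features in the difference. Before
subtraction the reference is aligned to the target by brute-force grid
search on the first $t_1$ increments: over integer direct-dimension point
shifts $\Delta\omega_2$ (default $-10 \ldots +10$ on the processed grid)
and Gaussian broadenings $\sigma$ (default $0 \ldots 5$ Hz in 0.25 Hz
steps, the standard deviation of the frequency-domain kernel, also
reported as FWHM), minimizing the $\ell_2$ residual between the corrected
reference and the target. Broadening is applied as a time-domain Gaussian
envelope $\exp(-2\pi^2\sigma^2 t_2^2)$ — exactly equivalent to
frequency-domain convolution — and the shift as a time-domain linear phase
ramp, so search and application are numerically identical operators and a
constructed shift/broadening pair is recovered exactly.

Two policy choices:

* **Amplitude is not fitted.** A global amplitude factor (e.g. dilution:
  adding 65 uL of ligand to a 585 uL sample gives 585/650 = 0.9) is applied
  deterministically when declared, never estimated from the data. Fitting
  it would let genuine intensity changes — the very signal being studied —
  leak into the correction.
* **One correction per series.** `dcs_reconstruct_series()` estimates the
  correction once, from the lowest-temperature pair, and reuses it. At high
  temperatures many peaks have genuinely lost intensity, and a per-spectrum
  fit then inflates $\sigma$ to shrink the reference toward the weaker
  target, destroying difference sparsity. The low-temperature pair is the
  most similar one and determines the instrumental (not biological) part of
  the mismatch best.

With only a short direct-dimension acquisition the $\sigma$ estimate is
intrinsically ill-determined (a 1 Hz Gaussian envelope is invisible over
11 ms), which is why the synthetic generator defaults to an 88 ms direct
acquisition; on real data the full acquisition time serves the same role.

## Sampling schedules

Poisson-gap schedules with sinusoidal gap weighting: the gap after a sample
at position $t$ is drawn from a Poisson distribution with mean
$\lambda \sin(\pi t / 2N)$, so gaps grow toward late evolution times where
the signal has decayed. $\lambda$ is adjusted iteratively until exactly $M$
points land on the grid (a draw that overruns restarts rather than being
clipped, preserving the gap statistics), and index 0 is always sampled.
Nested subsets for DCS (`nest_schedule()`) re-run the Poisson-gap draw on
the parent's ordinal positions, so the target schedule is a subset of the
reference schedule — the nested-schedule rule that `difference_fid()`
enforces.

## The synthetic series generator

`hsqc_series_spec()` emulates the kind of data the method is designed for:
a ~100-peak amide-region HSQC of a disordered, N-terminally membrane-
anchored protein, measured 15 times from 15 to 43 degC in 2 degC steps,
with a matched reference series (no ligand) and target series (with
ligand). Defaults:

* grids: 256 complex points indirect (SW 2.7 kHz), 256 complex points
  direct (SW 2.9 kHz, 88 ms);
* target/reference perturbations: +2 processed-grid points direct-dimension
  shift, 1 Hz Gaussian broadening, global amplitude 0.9 (dilution);
* per-residue relative-intensity sigmoids
  $y = y_{scale}(1 - \tanh(x_{scale}(x - x_{shift})))/2 + y_{shift}$ in
  three sequence blocks: an N-terminal quarter already partially bound at
  15 degC ($y(15) \approx 0.55$-$0.85$, transitions 22-28 degC), a core
  half starting at $y \approx 1$ with transitions rising 24-34 degC along
  the sequence, and a C-terminal quarter with shallow near-linear profiles
  ($x_{scale} \le 0.06$, designed to be caught by the "linear" filter);
* complex Gaussian noise calibrated in closed form to a target spectral
  signal-to-noise ratio (default 100), using the fact that the spectral
  noise sd is $\sigma_t \lVert w_1 \rVert \lVert w_2 \rVert$ under the
  package FT conventions.

What it does *not* emulate: chemical exchange dynamics, relaxation
dispersion, temperature-dependent chemical-shift drift in the indirect
dimension, lineshape distortions, or realistic liposome physics. Passing
tests on this generator therefore demonstrate the signal-processing
pipeline (sampling, reconstruction, alignment, curve analysis), not the
biology; measured data additionally needs phase correction and assignment,
which are taken as inputs.

## Series analysis

Peak heights are window maxima (default +-1 point; the series pipeline
uses +-3 to accommodate the inter-series shift) at assigned positions.
Relative intensity is $I_{rel} = h_{target}/h_{ref}$ per temperature,
flagged invisible when either height falls below 3x the spectrum noise sd
(estimated from a declared signal-free region, by default the corner 10%
of each axis). Profiles are fitted with the bounded sigmoid above
(Levenberg-Marquardt with box constraints: $0.05 < x_{scale} < 0.8$,
$20 < x_{shift} < 40$ degC, $y_{scale}$ within half to twice the observed
range, $y_{shift}$ within $\min(y) \pm 0.1$; starting values
$x_{shift} = $ median temperature, $x_{scale} = 0.3$,
$y_{scale} = $ range, $y_{shift} = \min(y)$).

Four rejection filters, applied in order:

1. fewer than six visible points (`too_few_points`);
2. $x_{scale} \le 0.08$ — only the near-linear middle of the sigmoid was
   seen (`linear`);
3. the second and penultimate visible points differ by less than a factor
   of two — a transition too small to quantify (`small_transition`); the
   "last-but-one point on both sides" is read literally as the second and
   penultimate visible points, ratio larger/smaller;
4. relative fit residual $\lVert y_{fit} - y \rVert / \lVert y \rVert$
   above 0.1 (`poor_fit`), the same normalization as the reconstruction
   quality metric.

Reconstruction quality across a peak list is summarized by the normalized
residual $\lVert h_{rec} - h_{full} \rVert_2 / \lVert h_{full} \rVert_2$.

## Numerical choices and degenerate inputs

* Zero-filled region fixed at zero during IST; convergence declared at a
  relative estimate change below $10^{-6}$, capped at `n_iterations`.
* Alignment tie-break: the first grid point attaining the minimum wins,
  with $\sigma = 0$, $\Delta\omega_2 = 0$ searched first, so an exact match
  returns the identity correction.
* A flat profile (zero y range) gets a tiny floor on the $y_{scale}$
  bounds to keep the optimizer's box valid; optimizer failures return
  status `poor_fit` with diagnostics instead of erroring.
* All-zero reconstruction input returns all zeros (thresholding never
  divides by a zero maximum).
* Degenerate schedules: $M = N$ short-circuits to the full grid;
  $M > N$ or $M < 1$ are rejected.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations are sized so a complete
run takes a few minutes on one core, which the package treats as its
standard desk-scale configuration: single-column recovery studies at
$N = 256$ over 20 schedules; head-to-head DCS/CS comparisons on a 50-peak
2D system (256 x 32 complex points) over 20 noise/schedule realizations
per sampling level; and the full end-to-end series at the generator
defaults above (15 temperatures, 100 peaks, 256 x 256). Larger grids
change none of the code paths.

## Known limitations

* The IST variant is this package's own; established NUS processing
  programs do not document their exact internal threshold trajectories, so
  residuals on measured data may differ in detail from reconstructions made
  with other software, even at matched iteration counts.
* Only the direct dimension is aligned; indirect-dimension drift between
  series members is not corrected.
* Sub-point (fractional) shifts are not searched by default, though the
  operators support them.
* The Varian and NMRPipe readers cover the subsets needed to ingest plain
  2D data (they are exercised against files written by this package);
  Bruker data and exotic header variants are out of scope.
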