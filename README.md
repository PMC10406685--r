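# dcsnmr — difference compressed sensing for serial 2D NMR

Serial 2D NMR experiments (variable-temperature series, titrations,
pressure ramps) acquire many spectra of the same system under slightly
different conditions. Non-uniform sampling (NUS) of the indirect dimension
with compressed-sensing (CS) reconstruction saves time only when the
spectrum is sparse — and crowded spectra of intrinsically disordered
proteins are not. `dcsnmr` implements **difference compressed sensing
(DCS)**: instead of reconstructing the undersampled target spectrum B
directly, it reconstructs the *difference* between B and a matched,
(nearly) fully sampled reference A, which is far sparser because unchanged
peaks cancel, and then adds the reference spectrum back:

    f_diff^NUS(t1,t2) = f_B^NUS(t1,t2) − f_A^NUS(t1,t2)
    S_B^rec(ω1,ω2)    = S_diff^rec(ω1,ω2) + S_A^full(ω1,ω2)

Since CS needs M ~ K·log(N/K) samples for K significant points, shrinking K
shrinks the number of indirect-dimension increments that must be measured.
The price is a √2 noise amplification from the subtraction, so DCS and
conventional CS are complementary: DCS wins at low sampling levels when few
peaks change, CS wins on noisy data or when most of the spectrum changes.
The package provides both behind identical processing conventions, plus the
downstream variable-temperature analysis: per-peak relative intensities
I_rel = h_target/h_ref, bounded sigmoid fits

    y = y_scale · (1 − tanh(x_scale · (x − x_shift))) / 2 + y_shift

whose `x_shift` is the per-residue transition ("melting") temperature,
rejection filters for non-sigmoidal profiles, and the normalized
peak-height residual ‖h_rec − h_full‖₂ / ‖h_full‖₂ as reconstruction
quality metric.

What's inside:

* `hsqc_series_spec()` / `generate_series()` — synthetic HSQC temperature
  series (matched reference/target pairs with per-residue sigmoids, dilution,
  inter-series shift/broadening, calibrated noise);
* `poisson_gap_schedule()` / `nest_schedule()` / `undersample()` —
  sinusoidally weighted Poisson-gap NUS schedules, nested subsets (the
  target schedule must be a subset of the reference schedule), artificial
  undersampling;
* `ft2d()`, `direct_ft()`, `cs_reconstruct_2d()`, `ist_reconstruct()`,
  `virtual_echo()` — conventional processing and column-wise iterative
  soft thresholding with virtual echo;
* `align_reference()`, `apply_correction()`, `difference_fid()`,
  `dcs_reconstruct()`, `dcs_reconstruct_series()` — the DCS pipeline,
  including the brute-force direct-dimension alignment (integer point
  shift + Gaussian line broadening) that maximizes difference sparsity;
* `relative_intensity()`, `fit_sigmoid()`, `filter_fits()`,
  `transition_table()`, `normalized_residual()` — series analysis, with
  broom-style `tidy()`/`glance()` on fits and `autoplot()`/`plot_*()`
  figures;
* readers/writers: internal JSON+binary series container, a minimal
  NMRPipe 2D dialect, Varian/Agilent fid directories, plain-text
  "nuslist" schedule files;
* a command-line interface: `inst/cli/dcsnmr` with subcommands
  `simulate | schedule | reconstruct | dcs | analyze | report`.

## Worked example

A 20-peak synthetic titration series, sampled at 32 of 128 indirect points
and reconstructed by DCS against the fully sampled reference:

```r
library(dcsnmr)
library(dplyr)

spec   <- hsqc_series_spec(n_peaks = 20, n1 = 128, seed = 1)
series <- generate_series(spec)
peaks  <- tibble::tibble(label = spec$peaks$label,
                         omega1_ppm = hz_to_ppm(spec$axis1, spec$peaks$f1),
                         omega2_ppm = hz_to_ppm(spec$axis2, spec$peaks$f2))

sched <- poisson_gap_schedule(128, 32, seed = 1)
recs  <- dcs_reconstruct_series(series$target, series$reference,
                                schedule = sched, amplitude_scale = 0.9)
attr(recs[[1]], "correction")
#> <alignment_correction> shift +2 points, broadening 3.75 Hz (FWHM 8.83 Hz),
#>   amplitude x0.9, residual 226.5

full_ref <- lapply(series$reference, ft2d)
ri   <- relative_intensity(recs, full_ref, peaks, window = 3)
fits <- filter_fits(fit_series(ri), ri)
transition_table(fits, accepted_only = TRUE)
#> # A tibble: 13 × 4
#>    label   residue x_shift status
#>  1 R002N-H       2    23.6 accepted
#>  2 R003N-H       3    24.8 accepted
#>  3 R004N-H       4    25.9 accepted
#>  ...
#> 12 R014N-H      14    33.4 accepted
#> 13 R015N-H      15    33.8 accepted

h_rec  <- peak_heights(recs[[1]], peaks, window = 3)$height
h_full <- peak_heights(ft2d(series$target[[1]]), peaks, window = 3)$height
normalized_residual(h_rec, h_full)
#> [1] 0.05207765
```

The alignment found the generator's +2-point inter-series shift; the
transition temperatures rise along the sequence exactly as programmed into
the generator (shallow C-terminal profiles are filtered out as `linear`);
and at a 4x undersampling the DCS peak heights sit within ~5% (l2 sense) of
the fully sampled transform.

The same pipeline from a shell (the launcher installs to
`<library>/dcsnmr/cli/dcsnmr`; alias it as `dcsnmr` or call it with
Rscript):

```sh
dcsnmr=$(Rscript -e 'cat(system.file("cli", "dcsnmr", package = "dcsnmr"))')
$dcsnmr simulate --out sim --seed 1 --n-peaks 20 --n1 128
$dcsnmr schedule --n 128 --m 32 --seed 1 --out sched.txt
$dcsnmr dcs --reference sim/reference --target sim/target \
            --schedule sched.txt --amplitude-scale 0.9 --out rec
$dcsnmr analyze --reference sim/reference --target rec \
                --peaks sim/peaks.tsv --out analysis
$dcsnmr report --analysis analysis --out figs
```

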