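# Synthetic 2D NMR series generator.
#
# Signal model: a sum of exponentially damped complex sinusoids,
#   f(t1, t2) = sum_k A_k exp((2i*pi*f1_k - R2_1k) t1) exp((2i*pi*f2_k - R2_2k) t2)
# plus additive complex Gaussian noise.  Frequencies are Hz offsets from the
# carrier; decay rates R2 are s^-1; times run 0, 1/SW, 2/SW, ...

#' Generate a 2D FID from a peak table
#'
#' @param peaks data frame with columns `f1`, `f2` (Hz offsets from the
#'   carrier), `r2_1`, `r2_2` (decay rates, s^-1) and `amplitude`.
#' @param axis1,axis2 [axis_meta()] for the indirect and direct dimension.
#' @param noise_sigma standard deviation of the real and imaginary noise
#'   components, absolute units.
#' @param seed integer seed (noise is deterministic given the seed); `NULL`
#'   uses the current RNG state.
#' @param temperature,label metadata attached to the result.
#' @return a fully sampled [nmr_fid()].
#' @export
generate_fid <- function(peaks, axis1, axis2, noise_sigma = 0, seed = NULL,
                         temperature = NULL, label = "") {
  stopifnot(is.data.frame(peaks), noise_sigma >= 0)
  need <- c("f1", "f2", "r2_1", "r2_2", "amplitude")
  if (!all(need %in% names(peaks))) {
    abort_dcs(paste("peak table needs columns:", paste(need, collapse = ", ")),
              "dcsnmr_input_error")
  }
  if (any(abs(peaks$f1) > axis1$spectral_width / 2) ||
      any(abs(peaks$f2) > axis2$spectral_width / 2)) {
    abort_dcs("peak frequency outside +/- spectral_width/2 of the carrier",
              "dcsnmr_input_error")
  }
  n1 <- axis1$n_points; n2 <- axis2$n_points
  t1 <- (seq_len(n1) - 1) / axis1$spectral_width
  t2 <- (seq_len(n2) - 1) / axis2$spectral_width
  # n1 x K and K x n2 factor matrices; matrix product sums over peaks
  e1 <- exp(outer(t1, complex(real = -peaks$r2_1, imaginary = 2 * pi * peaks$f1)))
  e2 <- exp(outer(complex(real = -peaks$r2_2, imaginary = 2 * pi * peaks$f2), t2))
  dat <- e1 %*% (peaks$amplitude * e2)
  if (noise_sigma > 0) {
    noise <- with_seed(seed, {
      complex(real = stats::rnorm(n1 * n2, sd = noise_sigma),
              imaginary = stats::rnorm(n1 * n2, sd = noise_sigma))
    })
    dat <- dat + matrix(noise, n1, n2)
  }
  nmr_fid(dat, axis1, axis2, temperature = temperature, label = label)
}

#' Sigmoidal intensity model
#'
#' The hyperbolic-tangent melting curve used throughout the package:
#' `y = y_scale * (1 - tanh(x_scale * (x - x_shift))) / 2 + y_shift`.
#' `x_shift` is the transition temperature; `x_scale` sets its steepness.
#'
#' @param x temperature (degrees Celsius).
#' @param x_scale,x_shift,y_scale,y_shift curve parameters.
#' @return numeric vector of relative intensities.
#' @export
sigmoid_curve <- function(x, x_scale, x_shift, y_scale, y_shift) {
  y_scale * (1 - tanh(x_scale * (x - x_shift))) / 2 + y_shift
}

#' Specification of a synthetic variable-temperature HSQC series
#'
#' Describes a matched pair of series: a reference (unperturbed, e.g.
#' protein without liposomes) and a target (perturbed, e.g. with liposomes)
#' measured over the same temperatures.  Target peak amplitudes follow a
#' per-peak sigmoid of temperature relative to the reference; the target
#' additionally carries a direct-dimension frequency shift, extra Gaussian
#' line broadening and a global amplitude (dilution) factor relative to the
#' reference.
#'
#' @param peaks data frame with the [generate_fid()] columns plus
#'   `label`, `x_scale`, `x_shift`, `y_scale`, `y_shift`.
#' @param axis1,axis2 [axis_meta()].
#' @param temperatures strictly increasing vector, degrees Celsius.
#' @param shift_points direct-dimension shift of the target relative to the
#'   reference, in processed-grid spectral points (grid of
#'   `2 * axis2$n_points` points; may be fractional).
#' @param broaden_hz extra Gaussian broadening of the target, Hz (standard
#'   deviation of the frequency-domain Gaussian kernel).
#' @param amplitude_scale global target/reference amplitude factor
#'   (dilution), default 0.9 (= 585/650 for a 585 uL sample + 65 uL
#'   ligand addition).
#' @param ref_slope fractional linear amplitude decline of the reference per
#'   degree Celsius (0 = temperature-independent reference).
#' @param noise_sigma additive complex noise sd, absolute units.
#' @param seed integer seed.
#' @return an object of class `series_spec`.
#' @export
series_spec <- function(peaks, axis1, axis2,
                        temperatures = seq(15, 43, by = 2),
                        shift_points = 0, broaden_hz = 0,
                        amplitude_scale = 0.9, ref_slope = 0,
                        noise_sigma = 0, seed = 1L) {
  stopifnot(is.data.frame(peaks), nrow(peaks) >= 1)
  need <- c("label", "f1", "f2", "r2_1", "r2_2", "amplitude",
            "x_scale", "x_shift", "y_scale", "y_shift")
  if (!all(need %in% names(peaks))) {
    abort_dcs(paste("series peak table needs columns:", paste(need, collapse = ", ")),
              "dcsnmr_input_error")
  }
  if (length(temperatures) < 1) {
    abort_dcs("temperature list must not be empty", "dcsnmr_input_error")
  }
  if (any(diff(temperatures) <= 0)) {
    abort_dcs("temperatures must be strictly increasing", "dcsnmr_input_error")
  }
  stopifnot(noise_sigma >= 0, amplitude_scale > 0)
  structure(list(
    peaks = tibble::as_tibble(peaks), axis1 = axis1, axis2 = axis2,
    temperatures = temperatures, shift_points = shift_points,
    broaden_hz = broaden_hz, amplitude_scale = amplitude_scale,
    ref_slope = ref_slope, noise_sigma = noise_sigma, seed = as.integer(seed)
  ), class = "series_spec")
}

#' @export
print.series_spec <- function(x, ...) {
  cat(sprintf("<series_spec> %d peaks, %d x %d grid, %d temperatures (%.0f-%.0f degC), noise %.3g, seed %d\n",
              nrow(x$peaks), x$axis1$n_points, x$axis2$n_points,
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              x$noise_sigma, x$seed))
  invisible(x)
}

#' Generate a matched reference/target series of 2D FIDs
#'
#' The reference series has temperature-independent peak amplitudes (or an
#' optional linear decline, `ref_slope`); the target series modulates each
#' peak's amplitude by its sigmoid of temperature ([sigmoid_curve()]) and a
#' global dilution factor, and carries the configured direct-dimension shift
#' and broadening relative to the reference.  Noise draws are deterministic
#' given the spec's seed.
#'
#' @param spec a [series_spec()].
#' @return list with elements `reference` and `target`, each a list of fully
#'   sampled [nmr_fid()] (one per temperature).
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  n2 <- spec$axis2$n_points
  t2 <- (seq_len(n2) - 1) / spec$axis2$spectral_width
  z2 <- 2L * n2 # processed-grid convention for shift_points
  # time-domain operators for the target perturbation: a linear phase ramp
  # shifts the spectrum by shift_points on the z2 grid; a Gaussian envelope
  # broadens lines (frequency-domain Gaussian convolution, sd broaden_hz)
  ramp <- exp(complex(imaginary = -2 * pi * spec$shift_points * (seq_len(n2) - 1) / z2))
  gauss <- exp(-2 * pi^2 * spec$broaden_hz^2 * t2^2)
  pert <- ramp * gauss

  t_mid <- spec$temperatures[1]
  seeds <- with_seed(spec$seed,
                     sample.int(.Machine$integer.max, 2 * length(spec$temperatures)))
  ref <- vector("list", length(spec$temperatures))
  tgt <- vector("list", length(spec$temperatures))
  for (i in seq_along(spec$temperatures)) {
    temp <- spec$temperatures[i]
    pk_ref <- spec$peaks
    pk_ref$amplitude <- pk_ref$amplitude * (1 + spec$ref_slope * (temp - t_mid))
    ref[[i]] <- generate_fid(pk_ref, spec$axis1, spec$axis2,
                             noise_sigma = spec$noise_sigma, seed = seeds[2 * i - 1],
                             temperature = temp, label = sprintf("reference_T%02d", i))
    pk_tgt <- spec$peaks
    pk_tgt$amplitude <- pk_tgt$amplitude * spec$amplitude_scale *
      sigmoid_curve(temp, pk_tgt$x_scale, pk_tgt$x_shift, pk_tgt$y_scale, pk_tgt$y_shift)
    f <- generate_fid(pk_tgt, spec$axis1, spec$axis2,
                      noise_sigma = 0, seed = NULL,
                      temperature = temp, label = sprintf("target_T%02d", i))
    if (spec$shift_points != 0 || spec$broaden_hz != 0) {
      f$data <- f$data * rep(pert, each = nrow(f$data))
    }
    if (spec$noise_sigma > 0) {
      noise <- with_seed(seeds[2 * i], {
        complex(real = stats::rnorm(length(f$data), sd = spec$noise_sigma),
                imaginary = stats::rnorm(length(f$data), sd = spec$noise_sigma))
      })
      f$data <- f$data + matrix(noise, nrow(f$data), ncol(f$data))
    }
    tgt[[i]] <- f
  }
  list(reference = ref, target = tgt)
}

#' Peak table and spec emulating a disordered-protein HSQC titration series
#'
#' A ~100-peak amide-region spectrum on a 256-point indirect grid and a
#' 15-step temperature series (15-43 degC in 2 degC steps).  Residues are
#' split into three behavioral groups along the sequence, mirroring an
#' N-terminally anchored membrane binder: an N-terminal block already
#' partially bound at the low-temperature end (reduced relative intensity,
#' low transition temperatures), a central membrane-binding region starting
#' near I_rel = 1 whose transition temperature rises along the sequence, and
#' a C-terminal tail with shallow, nearly linear profiles.  The direct axis
#' covers the amide strip (2.9 kHz at 256 complex points, i.e. an 88 ms
#' acquisition), so Hz-scale line-broadening differences are resolvable.
#'
#' @param n_peaks number of peaks (residues), default 100.
#' @param n1,n2 indirect / direct grid sizes.
#' @param sw1,sw2 spectral widths in Hz.
#' @param snr target signal-to-noise ratio (tallest reference peak height
#'   over the spectral noise sd); `Inf` for noiseless.
#' @param shift_points,broaden_hz inter-series perturbations, see
#'   [series_spec()].
#' @param seed integer seed (peak placement and noise).
#' @return a [series_spec()].
#' @export
hsqc_series_spec <- function(n_peaks = 100, n1 = 256, n2 = 256,
                             sw1 = 2700, sw2 = 2900, snr = 100,
                             shift_points = 2, broaden_hz = 1, seed = 1L) {
  ax1 <- axis_meta(n1, sw1, carrier_ppm = 118, base_frequency = 70.95)
  ax2 <- axis_meta(n2, sw2, carrier_ppm = 4.7, base_frequency = 700)
  pk <- with_seed(seed, {
    res <- seq_len(n_peaks)
    grp <- cut(res, breaks = c(0, 0.25, 0.75, 1) * n_peaks,
               labels = c("nterm", "core", "cterm"))
    frac <- res / n_peaks
    tibble::tibble(
      label = sprintf("R%03dN-H", res),
      f1 = stats::runif(n_peaks, -0.4, 0.4) * sw1,
      f2 = stats::runif(n_peaks, -0.4, 0.4) * sw2,
      r2_1 = stats::runif(n_peaks, 12, 25),
      r2_2 = stats::runif(n_peaks, 15, 30),
      amplitude = stats::runif(n_peaks, 0.6, 1.4),
      x_scale = ifelse(grp == "cterm",
                       stats::runif(n_peaks, 0.03, 0.06),
                       stats::runif(n_peaks, 0.25, 0.55)),
      x_shift = ifelse(grp == "nterm", 22 + 24 * frac,
                ifelse(grp == "core", 24 + 20 * (frac - 0.25),
                       stats::runif(n_peaks, 24, 32))),
      # unbound residues sit at I_rel ~ 1 at the low-temperature end; the
      # N-terminal block is already partially bound there
      y_shift = ifelse(grp == "nterm", stats::runif(n_peaks, 0.05, 0.15),
                ifelse(grp == "core", stats::runif(n_peaks, 0.05, 0.2),
                       stats::runif(n_peaks, 0.8, 0.9))),
      y_scale = ifelse(grp == "nterm", stats::runif(n_peaks, 0.5, 0.7),
                ifelse(grp == "core", 1 - y_shift,
                       stats::runif(n_peaks, 0.1, 0.2)))
    )
  })
  sigma <- if (is.finite(snr)) calibrate_noise_sigma(pk, ax1, ax2, snr) else 0
  series_spec(pk, ax1, ax2, temperatures = seq(15, 43, by = 2),
              shift_points = shift_points, broaden_hz = broaden_hz,
              amplitude_scale = 0.9, noise_sigma = sigma, seed = seed)
}

#' Noise level for a target spectral signal-to-noise ratio
#'
#' The spectral noise sd under the package FT conventions is
#' `sigma_t * ||w1|| * ||w2||` (apodization windows including the 0.5
#' first-point scaling), so the time-domain sd giving `snr` is computed in
#' closed form from the noiseless maximum spectrum height.
#'
#' @param peaks peak table as in [generate_fid()].
#' @param axis1,axis2 [axis_meta()].
#' @param snr desired max-height / noise-sd ratio.
#' @param apodization window kind, as in [ft2d()].
#' @return time-domain noise sd (per real/imaginary component).
#' @export
calibrate_noise_sigma <- function(peaks, axis1, axis2, snr,
                                  apodization = "cosine2") {
  fid <- generate_fid(peaks, axis1, axis2, noise_sigma = 0)
  h <- max(ft2d(fid, apodization = apodization)$data)
  w1 <- apod_window(axis1$n_points, apodization); w1[1] <- w1[1] * 0.5
  w2 <- apod_window(axis2$n_points, apodization); w2[1] <- w2[1] * 0.5
  h / (snr * l2(w1) * l2(w2))
}
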