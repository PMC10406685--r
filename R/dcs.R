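# Difference compressed sensing (DCS).
#
# Workflow: (optionally) align the reference A to the undersampled target B
# in the direct dimension, restrict A to B's schedule, take the difference
# FID, CS-reconstruct the difference (which is much sparser than B itself),
# and add the conventionally processed reference spectrum back:
#   S_B^rec = S_diff^rec + S_A^full.

#' Direct-dimension alignment correction
#'
#' Holds the correction that makes a reference spectrum maximally similar to
#' a target: an integer shift of the direct-dimension frequency axis (in
#' processed-grid points), a Gaussian line broadening (sd of the
#' frequency-domain kernel, Hz; implemented as a time-domain Gaussian
#' envelope) and a global amplitude factor.
#'
#' @param delta_points signed shift, processed-grid spectral points.
#' @param sigma_hz Gaussian broadening, Hz (>= 0).
#' @param amplitude_scale unitless multiplier (> 0).
#' @param objective_value residual l2 norm at the optimum (if known).
#' @return an object of class `alignment_correction`.
#' @export
alignment_correction <- function(delta_points = 0, sigma_hz = 0,
                                 amplitude_scale = 1,
                                 objective_value = NA_real_) {
  stopifnot(sigma_hz >= 0, amplitude_scale > 0)
  structure(list(delta_points = delta_points, sigma_hz = sigma_hz,
                 amplitude_scale = amplitude_scale,
                 objective_value = objective_value),
            class = "alignment_correction")
}

#' @export
print.alignment_correction <- function(x, ...) {
  cat(sprintf("<alignment_correction> shift %+g points, broadening %.3g Hz (FWHM %.3g Hz), amplitude x%.4g%s\n",
              x$delta_points, x$sigma_hz, 2 * sqrt(2 * log(2)) * x$sigma_hz,
              x$amplitude_scale,
              if (is.finite(x$objective_value))
                sprintf(", residual %.4g", x$objective_value) else ""))
  invisible(x)
}

# first-t1-increment direct-dimension spectrum of a FID (complex, desc axis)
first_increment_spectrum <- function(fid, zero_fill = 2L, apodization = "cosine2") {
  if (!is.null(fid$schedule) && fid$schedule$indices[1] != 0L) {
    abort_dcs("first increment (index 0) is not part of the schedule",
              "dcsnmr_schedule_error")
  }
  direct_ft(fid, zero_fill = zero_fill, apodization = apodization)$data[1, ]
}

#' Brute-force alignment of a reference to a target first increment
#'
#' Exhaustive grid search over integer direct-dimension point shifts and
#' discretized Gaussian broadenings, minimizing the l2 norm of the residual
#' between the corrected reference first-increment spectrum and the target
#' first-increment spectrum.  Broadening is applied as a Gaussian envelope
#' on the time-domain signal (equivalent to convolving the spectrum with a
#' Gaussian of sd `sigma` Hz); shifting is a circular shift on the processed
#' frequency grid (equivalent to a time-domain linear phase ramp).
#'
#' @param reference,target [nmr_fid()] objects on the same direct-dimension
#'   grid; their first t1 increments are compared.  (Any sampling state; the
#'   first increment is always measured.)
#' @param shift_range integer candidate shifts in processed-grid points
#'   (default -10:10).
#' @param sigma_range candidate broadenings in Hz (default
#'   `seq(0, 5, by = 0.25)`).
#' @param amplitude_scale fixed amplitude factor applied to the reference
#'   during the search (not fitted; supply e.g. a dilution factor).
#' @param zero_fill,apodization direct-dimension processing, as in
#'   [direct_ft()].
#' @return an [alignment_correction()] minimizing the residual.
#' @export
align_reference <- function(reference, target,
                            shift_range = -10:10,
                            sigma_range = seq(0, 5, by = 0.25),
                            amplitude_scale = 1,
                            zero_fill = 2L, apodization = "cosine2") {
  if (length(shift_range) < 1 || length(sigma_range) < 1) {
    abort_dcs("empty search grid", "dcsnmr_input_error")
  }
  if (reference$axis2$n_points != target$axis2$n_points ||
      reference$axis2$spectral_width != target$axis2$spectral_width) {
    abort_dcs("reference and target must share the direct-dimension grid",
              "dcsnmr_shape_error")
  }
  n2 <- reference$axis2$n_points
  z2 <- as.integer(zero_fill) * n2
  t2 <- (seq_len(n2) - 1) / reference$axis2$spectral_width
  w2 <- apod_window(n2, apodization); w2[1] <- w2[1] * 0.5

  row_a <- reference$data[1, ] * amplitude_scale
  row_b <- target$data[1, ]
  spec_b <- Re(fft_to_desc(stats::fft(c(row_b * w2, complex(z2 - n2)))))

  best <- alignment_correction(objective_value = Inf)
  shift_range <- as.integer(round(shift_range))
  for (sigma in sigma_range) {
    env <- exp(-2 * pi^2 * sigma^2 * t2^2)
    spec_a <- Re(fft_to_desc(stats::fft(c(row_a * env * w2, complex(z2 - n2)))))
    for (d in shift_range) {
      # positive d moves features of A toward larger index (lower frequency)
      shifted <- if (d == 0) spec_a else
        spec_a[((seq_len(z2) - 1L - d) %% z2) + 1L]
      obj <- l2(shifted - spec_b)
      if (obj < best$objective_value) {
        best <- alignment_correction(d, sigma, amplitude_scale, obj)
      }
    }
  }
  best
}

#' Apply an alignment correction to a FID
#'
#' Direct-dimension frequency shift (time-domain linear phase ramp on the
#' processed-grid convention used by [align_reference()]), Gaussian
#' time-domain envelope, and scalar amplitude multiplication, applied
#' uniformly to every t1 row.  A zero correction returns the input
#' unchanged.
#'
#' @param fid an [nmr_fid()] (any sampling state).
#' @param correction an [alignment_correction()].
#' @param zero_fill processed-grid convention for the point shift (must
#'   match the value used in the search; default 2).
#' @return corrected [nmr_fid()]; the correction is recorded in
#'   `attr(, "correction")`.
#' @export
apply_correction <- function(fid, correction, zero_fill = 2L) {
  stopifnot(inherits(fid, "nmr_fid"), inherits(correction, "alignment_correction"))
  out <- fid
  n2 <- fid$axis2$n_points
  z2 <- as.integer(zero_fill) * n2
  if (correction$delta_points != 0 || correction$sigma_hz != 0 ||
      correction$amplitude_scale != 1) {
    t2 <- (seq_len(n2) - 1) / fid$axis2$spectral_width
    op <- rep(correction$amplitude_scale + 0i, n2)
    if (correction$delta_points != 0) {
      op <- op * exp(complex(imaginary = -2 * pi * correction$delta_points *
                               (seq_len(n2) - 1) / z2))
    }
    if (correction$sigma_hz != 0) {
      op <- op * exp(-2 * pi^2 * correction$sigma_hz^2 * t2^2)
    }
    out$data <- out$data * rep(op, each = nrow(out$data))
  }
  attr(out, "correction") <- correction
  out
}

#' Difference FID between an undersampled target and its reference
#'
#' Restricts the reference to the target's sampling schedule (the
#' nested-schedule rule: the target schedule must be a subset of the
#' reference schedule, or the reference must be fully sampled) and subtracts:
#' `f_diff = f_B^NUS - f_A^NUS`.
#'
#' @param fid_b_nus target [nmr_fid()] (schedule attached, or fully
#'   sampled).
#' @param fid_a reference [nmr_fid()] (fully sampled, or sampled on a
#'   superset of the target's schedule).
#' @return an [nmr_fid()] of the difference, carrying the target's schedule
#'   and temperature.
#' @export
difference_fid <- function(fid_b_nus, fid_a) {
  stopifnot(inherits(fid_b_nus, "nmr_fid"), inherits(fid_a, "nmr_fid"))
  if (fid_a$axis1$n_points != fid_b_nus$axis1$n_points ||
      fid_a$axis2$n_points != fid_b_nus$axis2$n_points) {
    abort_dcs("reference and target grids differ", "dcsnmr_shape_error")
  }
  idx_b <- if (is.null(fid_b_nus$schedule)) 0:(fid_b_nus$axis1$n_points - 1L)
           else fid_b_nus$schedule$indices
  if (is_fully_sampled(fid_a)) {
    rows_a <- fid_a$data[idx_b + 1L, , drop = FALSE]
  } else {
    pos <- match(idx_b, fid_a$schedule$indices)
    if (anyNA(pos)) {
      abort_dcs("target schedule is not a subset of the reference schedule (nested-schedule rule)",
                "dcsnmr_schedule_error")
    }
    rows_a <- fid_a$data[pos, , drop = FALSE]
  }
  nmr_fid(fid_b_nus$data - rows_a, fid_b_nus$axis1, fid_b_nus$axis2,
          schedule = fid_b_nus$schedule,
          temperature = fid_b_nus$temperature,
          label = "difference")
}

#' Difference compressed sensing reconstruction
#'
#' Reconstructs an undersampled target spectrum B from a matched reference
#' A: optional direct-dimension alignment of A to B, difference FID,
#' CS reconstruction of the difference, and add-back of the conventionally
#' processed reference spectrum.  If the reference is itself undersampled
#' (on a superset schedule) it is CS-reconstructed instead of Fourier
#' transformed before the add-back.
#'
#' @param fid_b_nus target [nmr_fid()] (NUS).
#' @param fid_a reference [nmr_fid()] (fully sampled, or NUS on a superset
#'   schedule).
#' @param config a [recon_config()]; used for both branches so the
#'   difference spectrum and the reference spectrum share processing.
#' @param auto_align estimate the alignment correction from the first
#'   increments (default `TRUE`).  Ignored if `correction` is supplied.
#' @param correction an [alignment_correction()] to apply to the reference
#'   (overrides `auto_align`).
#' @param amplitude_scale fixed reference amplitude factor (e.g. dilution)
#'   used when `auto_align` builds the correction.
#' @param shift_range,sigma_range search grids for [align_reference()].
#' @return an [nmr_spectrum()] with provenance `"dcs_rec"`.  Attributes:
#'   `difference_spectrum` (the reconstructed difference,
#'   provenance `"difference"`), `reference_spectrum` (S_A after
#'   correction), and `correction`.
#' @export
dcs_reconstruct <- function(fid_b_nus, fid_a, config = recon_config(),
                            auto_align = TRUE, correction = NULL,
                            amplitude_scale = 1,
                            shift_range = -10:10,
                            sigma_range = seq(0, 5, by = 0.25)) {
  stopifnot(inherits(fid_b_nus, "nmr_fid"), inherits(fid_a, "nmr_fid"))
  if (is.null(correction)) {
    correction <- if (auto_align) {
      align_reference(fid_a, fid_b_nus,
                      shift_range = shift_range, sigma_range = sigma_range,
                      amplitude_scale = amplitude_scale,
                      zero_fill = config$zero_fill_factor,
                      apodization = config$apodization)
    } else {
      alignment_correction(amplitude_scale = amplitude_scale)
    }
  }
  fid_a_corr <- apply_correction(fid_a, correction,
                                 zero_fill = config$zero_fill_factor)

  diff <- difference_fid(fid_b_nus, fid_a_corr)
  s_diff <- cs_reconstruct_2d(diff, config, provenance = "difference")

  s_a <- if (is_fully_sampled(fid_a_corr)) {
    fid_a_full <- fid_a_corr
    fid_a_full$schedule <- NULL
    ft2d(fid_a_full, zero_fill = rep(config$zero_fill_factor, 2),
         apodization = config$apodization)
  } else {
    cs_reconstruct_2d(fid_a_corr, config)
  }
  if (!all(dim(s_a$data) == dim(s_diff$data))) {
    abort_dcs("reference and difference spectra were processed to different sizes",
              "dcsnmr_shape_error")
  }
  out <- nmr_spectrum(s_a$data + s_diff$data, s_diff$axis1, s_diff$axis2,
                      temperature = fid_b_nus$temperature,
                      provenance = "dcs_rec", label = fid_b_nus$label)
  attr(out, "difference_spectrum") <- s_diff
  attr(out, "reference_spectrum") <- s_a
  attr(out, "correction") <- correction
  out
}

#' DCS reconstruction of a whole series against matched references
#'
#' Estimates a single alignment correction from one target/reference pair
#' (by default the first, i.e. lowest-temperature, pair, where the spectra
#' are most similar and the correction is best determined) and applies it
#' to every reconstruction in the series.
#'
#' @param targets list of NUS [nmr_fid()] (or fully sampled FIDs if
#'   `schedule` is given, in which case they are undersampled first).
#' @param references list of matched reference [nmr_fid()].
#' @param config a [recon_config()].
#' @param schedule optional [nus_schedule()] applied to fully sampled
#'   targets.
#' @param amplitude_scale fixed reference amplitude factor (dilution).
#' @param align_pair index of the pair used to estimate the correction;
#'   `NULL` disables alignment (amplitude scale still applied).
#' @param shift_range,sigma_range search grids for [align_reference()].
#' @return list of [nmr_spectrum()] with provenance `"dcs_rec"`.
#' @export
dcs_reconstruct_series <- function(targets, references, config = recon_config(),
                                   schedule = NULL, amplitude_scale = 1,
                                   align_pair = 1L,
                                   shift_range = -10:10,
                                   sigma_range = seq(0, 5, by = 0.25)) {
  if (length(targets) != length(references)) {
    abort_dcs("target and reference series lengths differ", "dcsnmr_input_error")
  }
  if (!is.null(schedule)) {
    targets <- lapply(targets, function(f) {
      if (is.null(f$schedule)) undersample(f, schedule) else f
    })
  }
  correction <- if (!is.null(align_pair)) {
    align_reference(references[[align_pair]], targets[[align_pair]],
                    shift_range = shift_range, sigma_range = sigma_range,
                    amplitude_scale = amplitude_scale,
                    zero_fill = config$zero_fill_factor,
                    apodization = config$apodization)
  } else {
    alignment_correction(amplitude_scale = amplitude_scale)
  }
  lapply(seq_along(targets), function(i) {
    dcs_reconstruct(targets[[i]], references[[i]], config,
                    correction = correction)
  })
}
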