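# Conventional Fourier processing.
#
# Processing conventions (used consistently everywhere):
#  * apodization: cosine-squared over the acquired points (configurable),
#  * first time-domain point scaled by 0.5 in each transformed dimension
#    (standard baseline-offset correction; it also makes the one-sided FT
#    and the virtual-echo FT agree exactly),
#  * zero fill to `zero_fill_factor * n_points` (default 2x),
#  * frequency axes descending, index 1 at +SW/2.

#' 2D Fourier transform of a fully sampled FID
#'
#' Applies apodization, first-point scaling and zero filling in both
#' dimensions, transforms, and returns the real part (data generated or
#' phased to zero phase is absorptive).
#'
#' @param fid fully sampled [nmr_fid()].
#' @param zero_fill integer vector of length 2: zero-fill factors for the
#'   indirect and direct dimension (processed size = factor * n_points).
#' @param apodization `"cosine2"` (default) or `"none"`.
#' @return an [nmr_spectrum()] with provenance `"full_ft"`.
#' @export
ft2d <- function(fid, zero_fill = c(2L, 2L), apodization = "cosine2") {
  stopifnot(inherits(fid, "nmr_fid"))
  if (!is_fully_sampled(fid)) {
    abort_dcs("ft2d requires fully sampled data; reconstruct NUS data with cs_reconstruct_2d or dcs_reconstruct",
              "dcsnmr_nus_error")
  }
  n1 <- fid$axis1$n_points; n2 <- fid$axis2$n_points
  z1 <- as.integer(zero_fill[1]) * n1
  z2 <- as.integer(zero_fill[2]) * n2

  w2 <- apod_window(n2, apodization); w2[1] <- w2[1] * 0.5
  w1 <- apod_window(n1, apodization); w1[1] <- w1[1] * 0.5

  x <- fid$data * rep(w1, times = n2) # row weights
  x <- x * rep(w2, each = nrow(x))    # column weights
  big <- matrix(0 + 0i, z1, z2)
  big[seq_len(n1), seq_len(n2)] <- x
  # FT along t2 (rows of t(big)) then along t1
  sp <- t(stats::mvfft(t(big)))
  sp <- stats::mvfft(sp)
  sp <- fft_to_desc(sp)
  sp <- t(fft_to_desc(t(sp)))

  ax1 <- axis_meta(z1, fid$axis1$spectral_width, fid$axis1$carrier_ppm,
                   fid$axis1$base_frequency)
  ax2 <- axis_meta(z2, fid$axis2$spectral_width, fid$axis2$carrier_ppm,
                   fid$axis2$base_frequency)
  nmr_spectrum(Re(sp), ax1, ax2, temperature = fid$temperature,
               provenance = "full_ft", label = fid$label)
}

#' Direct-dimension Fourier transform (interferogram)
#'
#' Transforms along t2 only, leaving the (possibly non-uniformly sampled) t1
#' rows intact: the mixed-domain input to column-wise reconstruction.
#'
#' @param fid an [nmr_fid()], fully or NUS sampled.
#' @param zero_fill integer zero-fill factor for the direct dimension.
#' @param apodization `"cosine2"` or `"none"`.
#' @return an object of class `interferogram`: complex matrix
#'   `[t1 row, omega2]` (descending frequency) plus axis metadata and the
#'   schedule.
#' @export
direct_ft <- function(fid, zero_fill = 2L, apodization = "cosine2") {
  stopifnot(inherits(fid, "nmr_fid"))
  n2 <- fid$axis2$n_points
  z2 <- as.integer(zero_fill) * n2
  w2 <- apod_window(n2, apodization); w2[1] <- w2[1] * 0.5
  x <- fid$data * rep(w2, each = nrow(fid$data))
  big <- matrix(0 + 0i, nrow(x), z2)
  big[, seq_len(n2)] <- x
  sp <- t(stats::mvfft(t(big)))
  sp <- t(fft_to_desc(t(sp)))
  ax2 <- axis_meta(z2, fid$axis2$spectral_width, fid$axis2$carrier_ppm,
                   fid$axis2$base_frequency)
  structure(list(data = sp, axis1 = fid$axis1, axis2 = ax2,
                 schedule = fid$schedule, temperature = fid$temperature,
                 label = fid$label),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d t1 rows x %d omega2 points\n",
              nrow(x$data), ncol(x$data)))
  invisible(x)
}
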