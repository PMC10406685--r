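# Compressed-sensing reconstruction: column-wise iterative soft thresholding
# (IST) on the indirect dimension, with optional virtual-echo symmetrization.
#
# IST scheme (threshold-and-restore): starting from the zero-augmented
# measured signal, each iteration Fourier transforms the current estimate,
# soft-thresholds the spectrum, inverse transforms and restores the measured
# time-domain points to their measured values.  The threshold decays
# multiplicatively (tau_k = rho^k * max|initial spectrum|, rho = 0.96 by
# default).  The returned spectrum is the transform of the final
# data-consistent estimate, so measured points are honored exactly and
# soft-threshold amplitude bias is not carried into the output.

#' Reconstruction settings
#'
#' @param n_iterations maximum IST iterations (default 200).
#' @param virtual_echo symmetrize each column by conjugate time reversal
#'   before reconstruction (default `TRUE`); the spectrum of the
#'   symmetrized signal is real and sparser.
#' @param threshold_schedule `"multiplicative_decay"` (tau decays as
#'   `parameter^k` from the initial spectrum maximum) or `"fixed_fraction"`
#'   (tau is `parameter` times the current spectrum maximum at every
#'   iteration).
#' @param threshold_parameter decay ratio / fraction in (0, 1), default 0.96: after 200 iterations the
#'   threshold has decayed to ~3e-4 of the initial spectrum maximum, deep
#'   enough that weak peaks are released from thresholding.
#' @param zero_fill_factor processed size = factor * grid size (default 2).
#' @param convergence_tol stop early when the relative change of the
#'   estimate drops below this (default 1e-6).
#' @param apodization direct/indirect window, as in [ft2d()].
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 200L, virtual_echo = TRUE,
                         threshold_schedule = c("multiplicative_decay", "fixed_fraction"),
                         threshold_parameter = 0.96,
                         zero_fill_factor = 2L, convergence_tol = 1e-6,
                         apodization = "cosine2") {
  threshold_schedule <- match.arg(threshold_schedule)
  stopifnot(n_iterations >= 1,
            threshold_parameter > 0, threshold_parameter < 1,
            zero_fill_factor >= 1)
  structure(list(
    n_iterations = as.integer(n_iterations), virtual_echo = virtual_echo,
    threshold_schedule = threshold_schedule,
    threshold_parameter = threshold_parameter,
    zero_fill_factor = as.integer(zero_fill_factor),
    convergence_tol = convergence_tol, apodization = apodization
  ), class = "recon_config")
}

#' @export
print.recon_config <- function(x, ...) {
  cat(sprintf("<recon_config> %d iterations, virtual echo %s, %s (%.3g), zero fill %dx\n",
              x$n_iterations, if (x$virtual_echo) "on" else "off",
              x$threshold_schedule, x$threshold_parameter, x$zero_fill_factor))
  invisible(x)
}

# 1-based positions on the processed grid that lie beyond the acquisition
# window and are therefore known to be zero (zero filling); IST holds them
# fixed and only infers the unmeasured points inside the window.
zero_fill_positions <- function(n, z, virtual_echo) {
  if (virtual_echo) {
    # window occupies 0..n-1 and the mirrored z-(n-1)..z-1
    if (z - n >= n) (n + 1L):(z - n + 1L) else integer(0)
  } else {
    if (z > n) (n + 1L):z else integer(0)
  }
}

# processed indirect-dimension length for a grid of n points
recon_grid_length <- function(n, config) {
  z <- config$zero_fill_factor * n
  if (config$virtual_echo && z < 2L * n) {
    z <- 2L^ceiling(log2(2L * n)) # VE needs room for the mirrored half
  }
  as.integer(z)
}

#' Virtual echo of a (possibly undersampled) t1 column
#'
#' Extends a phased column to a conjugate-symmetric signal on a circular
#' grid of length `z`: time t maps to position t, time -t to position z - t,
#' with `v[-t] = Conj(v[t])` and t = 0 stored once.  The Fourier transform
#' of the symmetrized signal is exactly real; on full sampling it equals
#' twice the real part of the one-sided transform with the first point
#' halved, which is the package's conventional FT.  The sampled-index set is
#' mirrored accordingly (2M - 1 distinct positions).
#'
#' @param column complex vector of measured t1 values (one per schedule
#'   index, ascending).
#' @param schedule a [nus_schedule()] (or `NULL` for a fully sampled
#'   column, in which case indices 0..length-1 are assumed).
#' @param z length of the symmetrized grid, at least `2 * schedule$n`.
#' @return list with `v` (complex length-z vector, zeros off-schedule) and
#'   `positions` (1-based positions in `v` that carry measured values).
#' @export
virtual_echo <- function(column, schedule = NULL, z = NULL) {
  n <- if (is.null(schedule)) length(column) else schedule$n
  idx <- if (is.null(schedule)) 0:(length(column) - 1L) else schedule$indices
  if (length(column) != length(idx)) {
    abort_dcs("column length must match the schedule", "dcsnmr_shape_error")
  }
  z <- as.integer(z %||% (2L * n))
  if (z < 2L * n) abort_dcs("virtual echo grid must be at least 2 * n", "dcsnmr_shape_error")
  v <- complex(z)
  v[idx + 1L] <- column
  mir <- idx[idx > 0L]
  v[z - mir + 1L] <- Conj(column[idx > 0L])
  positions <- c(idx + 1L, z - mir + 1L)
  list(v = v, positions = sort(unique(positions)))
}

# Vectorized IST on a Z x C matrix of zero-augmented measured signals.
# `positions` are the 1-based rows holding measured values (shared by all
# columns).  Returns the complex spectrum matrix (fft-bin order).
ist_core <- function(y, positions, config) {
  z <- nrow(y)
  meas <- y[positions, , drop = FALSE]
  x <- y
  rho <- config$threshold_parameter
  tau0 <- NULL
  prev <- x
  for (k in seq_len(config$n_iterations)) {
    X <- stats::mvfft(x)
    a <- abs(X)
    colmax <- apply(a, 2, max)
    if (is.null(tau0)) tau0 <- colmax
    tau <- switch(config$threshold_schedule,
      multiplicative_decay = tau0 * rho^k,
      fixed_fraction       = colmax * rho
    )
    shrink <- pmax(1 - rep(tau, each = z) / pmax(a, .Machine$double.xmin), 0)
    X <- X * shrink
    x <- stats::mvfft(X, inverse = TRUE) / z
    x[positions, ] <- meas
    dx <- sqrt(sum(abs(x - prev)^2))
    nx <- sqrt(sum(abs(prev)^2))
    if (nx > 0 && dx / nx < config$convergence_tol) break
    prev <- x
  }
  stats::mvfft(x) # final transform of the data-consistent estimate
}

#' IST reconstruction of a single indirect-dimension column
#'
#' @param column complex vector of measured t1 values (ascending schedule
#'   order).
#' @param schedule a [nus_schedule()]; `NULL` means fully sampled.
#' @param config a [recon_config()].
#' @param apodize apply the config's indirect apodization window to the
#'   measured values before reconstruction (default `TRUE`, matching the
#'   conventional processing of full data).
#' @return real frequency-domain vector on the processed grid (descending
#'   frequency, index 1 at +SW/2).
#' @export
ist_reconstruct <- function(column, schedule = NULL, config = recon_config(),
                            apodize = TRUE) {
  if (any(!is.finite(column))) {
    abort_dcs("non-finite values in reconstruction input", "dcsnmr_input_error")
  }
  n <- if (is.null(schedule)) length(column) else schedule$n
  idx <- if (is.null(schedule)) 0:(n - 1L) else schedule$indices
  if (apodize) {
    w <- apod_window(n, config$apodization)
    column <- column * w[idx + 1L]
  }
  if (config$virtual_echo) {
    z <- recon_grid_length(n, config)
    ve <- virtual_echo(column, schedule, z = z)
    fixed <- sort(unique(c(ve$positions, zero_fill_positions(n, z, TRUE))))
    sp <- ist_core(cbind(ve$v), fixed, config)
    fft_to_desc(Re(sp[, 1]) / 2)
  } else {
    z <- config$zero_fill_factor * n
    y <- complex(z)
    col2 <- column
    col2[idx == 0L] <- col2[idx == 0L] * 0.5 # first-point convention
    y[idx + 1L] <- col2
    fixed <- sort(unique(c(idx + 1L, zero_fill_positions(n, z, FALSE))))
    sp <- ist_core(cbind(y), fixed, config)
    fft_to_desc(Re(sp[, 1]))
  }
}

#' Compressed-sensing reconstruction of a 2D NUS data set
#'
#' Direct-dimension FT, then IST reconstruction of every omega2 column of
#' the interferogram, assembled into a real 2D spectrum.  A fully sampled
#' input reproduces [ft2d()] output.
#'
#' @param fid an [nmr_fid()], usually NUS (schedule attached).
#' @param config a [recon_config()].
#' @param provenance provenance tag of the output (internal use).
#' @return an [nmr_spectrum()] with provenance `"cs_rec"`.
#' @export
cs_reconstruct_2d <- function(fid, config = recon_config(),
                              provenance = "cs_rec") {
  stopifnot(inherits(fid, "nmr_fid"))
  if (any(!is.finite(fid$data))) {
    abort_dcs("non-finite values in reconstruction input", "dcsnmr_input_error")
  }
  interf <- direct_ft(fid, zero_fill = config$zero_fill_factor,
                      apodization = config$apodization)
  n1 <- fid$axis1$n_points
  idx <- if (is.null(fid$schedule)) 0:(n1 - 1L) else fid$schedule$indices
  w1 <- apod_window(n1, config$apodization)
  dat <- interf$data * w1[idx + 1L] # row-wise apodization at sampled t1

  if (config$virtual_echo) {
    z1 <- recon_grid_length(n1, config)
    y <- matrix(0 + 0i, z1, ncol(dat))
    y[idx + 1L, ] <- dat
    mir <- idx > 0L
    y[z1 - idx[mir] + 1L, ] <- Conj(dat[mir, , drop = FALSE])
    positions <- sort(unique(c(idx + 1L, z1 - idx[mir] + 1L,
                               zero_fill_positions(n1, z1, TRUE))))
    sp <- ist_core(y, positions, config)
    out <- fft_to_desc(Re(sp) / 2)
  } else {
    z1 <- config$zero_fill_factor * n1
    dat[idx == 0L, ] <- dat[idx == 0L, ] * 0.5
    y <- matrix(0 + 0i, z1, ncol(dat))
    y[idx + 1L, ] <- dat
    positions <- sort(unique(c(idx + 1L, zero_fill_positions(n1, z1, FALSE))))
    sp <- ist_core(y, positions, config)
    out <- fft_to_desc(Re(sp))
  }
  ax1 <- axis_meta(z1, fid$axis1$spectral_width, fid$axis1$carrier_ppm,
                   fid$axis1$base_frequency)
  nmr_spectrum(out, ax1, interf$axis2, temperature = fid$temperature,
               provenance = provenance, label = fid$label)
}
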