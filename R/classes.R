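#' Axis metadata for one dimension of a 2D NMR data set
#'
#' Bundles the acquisition parameters of a single spectral dimension: grid
#' size, spectral width, maximum evolution time, carrier position and base
#' (Larmor) frequency.  The frequency-axis convention used throughout the
#' package is: index 1 corresponds to +spectral_width/2 relative to the
#' carrier, and frequency decreases with increasing index.
#'
#' @param n_points number of (complex) grid points, >= 1.
#' @param spectral_width spectral width in Hz, > 0.
#' @param carrier_ppm carrier position in ppm.
#' @param base_frequency base frequency of the nucleus in MHz (converts Hz
#'   offsets to ppm).
#' @param max_evolution_time maximum evolution time in seconds.  If `NULL` it
#'   is derived as `(n_points - 1) / spectral_width`; if supplied it must be
#'   consistent with that relation to within 1e-9 relative.
#' @return an object of class `axis_meta`.
#' @export
axis_meta <- function(n_points, spectral_width, carrier_ppm = 0,
                      base_frequency = 1, max_evolution_time = NULL) {
  n_points <- as.integer(n_points)
  stopifnot(length(n_points) == 1, n_points >= 1,
            length(spectral_width) == 1, spectral_width > 0)
  met <- (n_points - 1) / spectral_width
  if (!is.null(max_evolution_time)) {
    if (abs(max_evolution_time - met) > 1e-9 * max(met, 1e-12)) {
      abort_dcs(sprintf(
        "max_evolution_time %.6g inconsistent with (n_points - 1)/spectral_width = %.6g",
        max_evolution_time, met), "dcsnmr_axis_error")
    }
    met <- max_evolution_time
  }
  structure(list(
    n_points = n_points,
    spectral_width = spectral_width,
    max_evolution_time = met,
    carrier_ppm = carrier_ppm,
    base_frequency = base_frequency
  ), class = "axis_meta")
}

#' @export
print.axis_meta <- function(x, ...) {
  cat(sprintf("<axis_meta> %d pts, SW %.4g Hz, t_max %.4g s, carrier %.4g ppm @ %.4g MHz\n",
              x$n_points, x$spectral_width, x$max_evolution_time,
              x$carrier_ppm, x$base_frequency))
  invisible(x)
}

#' Convert between ppm and Hz offsets on an axis
#'
#' Hz offsets are relative to the carrier.
#' @param axis an [axis_meta()].
#' @param ppm,hz values to convert.
#' @return numeric vector.
#' @export
ppm_to_hz <- function(axis, ppm) (ppm - axis$carrier_ppm) * axis$base_frequency

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(axis, hz) hz / axis$base_frequency + axis$carrier_ppm

#' Time-domain 2D NMR data (FID)
#'
#' A complex matrix indexed `[t1 increment, t2 sample]`.  When a sampling
#' schedule is attached the rows are the sampled indirect-dimension
#' increments, in ascending schedule order; otherwise the data is fully
#' sampled and has `axis1$n_points` rows.  The indirect dimension is held as
#' one complex value per t1 increment (States-equivalent), so a NUS "point"
#' is one complex increment.
#'
#' @param data complex matrix `[t1, t2]`.
#' @param axis1 indirect-dimension [axis_meta()].
#' @param axis2 direct-dimension [axis_meta()].
#' @param schedule optional [nus_schedule()] describing which t1 increments
#'   the rows correspond to.
#' @param temperature optional sample temperature in degrees Celsius.
#' @param label free-text label.
#' @return an object of class `nmr_fid`.
#' @export
nmr_fid <- function(data, axis1, axis2, schedule = NULL,
                    temperature = NULL, label = "") {
  stopifnot(is.matrix(data), inherits(axis1, "axis_meta"),
            inherits(axis2, "axis_meta"))
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (ncol(data) != axis2$n_points) {
    abort_dcs("ncol(data) must equal axis2$n_points", "dcsnmr_shape_error")
  }
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "nus_schedule"))
    if (schedule$n != axis1$n_points) {
      abort_dcs("schedule grid size does not match axis1$n_points",
                "dcsnmr_shape_error")
    }
    if (nrow(data) != length(schedule$indices)) {
      abort_dcs("data must have one row per sampled t1 increment",
                "dcsnmr_shape_error")
    }
  } else if (nrow(data) != axis1$n_points) {
    abort_dcs("fully sampled data must have axis1$n_points rows",
              "dcsnmr_shape_error")
  }
  structure(list(
    data = data, axis1 = axis1, axis2 = axis2, schedule = schedule,
    temperature = temperature, label = label
  ), class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  samp <- if (is.null(x$schedule)) "full" else
    sprintf("NUS %d/%d", length(x$schedule$indices), x$schedule$n)
  cat(sprintf("<nmr_fid> %s, %d x %d points (%s)%s%s\n",
              samp, nrow(x$data), ncol(x$data),
              "t1 x t2",
              if (!is.null(x$temperature)) sprintf(", %.1f degC", x$temperature) else "",
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

is_fully_sampled <- function(fid) {
  is.null(fid$schedule) ||
    length(fid$schedule$indices) == fid$schedule$n
}

#' Frequency-domain 2D NMR spectrum
#'
#' A real matrix indexed `[omega1, omega2]` on the processed (zero-filled)
#' grids declared by the axes, with frequency decreasing along each index
#' (index 1 is +SW/2).
#'
#' @param data real matrix `[omega1, omega2]`.
#' @param axis1,axis2 [axis_meta()] of the processed grids (n_points equals
#'   the transform sizes).
#' @param temperature optional sample temperature, degrees Celsius.
#' @param provenance one of `"full_ft"`, `"cs_rec"`, `"dcs_rec"`,
#'   `"difference"`.
#' @param label free-text label.
#' @return an object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(data, axis1, axis2, temperature = NULL,
                         provenance = c("full_ft", "cs_rec", "dcs_rec", "difference"),
                         label = "") {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(data), is.numeric(data))
  if (nrow(data) != axis1$n_points || ncol(data) != axis2$n_points) {
    abort_dcs("spectrum dimensions must equal the transform sizes declared by the axes",
              "dcsnmr_shape_error")
  }
  structure(list(
    data = data, axis1 = axis1, axis2 = axis2,
    temperature = temperature, provenance = provenance, label = label
  ), class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d x %d points [%s]%s%s\n",
              nrow(x$data), ncol(x$data), x$provenance,
              if (!is.null(x$temperature)) sprintf(", %.1f degC", x$temperature) else "",
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

#' Frequency axes of a spectrum as vectors
#'
#' @param spectrum an [nmr_spectrum()].
#' @param unit `"hz"` (offset from carrier) or `"ppm"`.
#' @return list with components `omega1` and `omega2`.
#' @export
spectrum_axes <- function(spectrum, unit = c("hz", "ppm")) {
  unit <- match.arg(unit)
  f1 <- freq_axis_hz(spectrum$axis1$spectral_width, spectrum$axis1$n_points)
  f2 <- freq_axis_hz(spectrum$axis2$spectral_width, spectrum$axis2$n_points)
  if (unit == "ppm") {
    f1 <- hz_to_ppm(spectrum$axis1, f1)
    f2 <- hz_to_ppm(spectrum$axis2, f2)
  }
  list(omega1 = f1, omega2 = f2)
}

#' Tabulate a 2D spectrum
#'
#' Long-format view of a spectrum for plotting and tidy manipulation.
#' @param x an [nmr_spectrum()].
#' @param ... unused.
#' @return a tibble with columns `omega1_hz`, `omega2_hz`, `omega1_ppm`,
#'   `omega2_ppm`, `intensity`.
#' @export
tidy.nmr_spectrum <- function(x, ...) {
  ax <- spectrum_axes(x, "hz")
  tibble::tibble(
    omega1_hz = rep(ax$omega1, times = length(ax$omega2)),
    omega2_hz = rep(ax$omega2, each = length(ax$omega1)),
    omega1_ppm = hz_to_ppm(x$axis1, rep(ax$omega1, times = length(ax$omega2))),
    omega2_ppm = hz_to_ppm(x$axis2, rep(ax$omega2, each = length(ax$omega1))),
    intensity = as.vector(x$data)
  )
}
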