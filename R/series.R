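# Variable-temperature series analysis: peak heights, relative intensities,
# sigmoidal transition-temperature fits with rejection filters, and the
# normalized peak-height residual used as reconstruction quality metric.
# This layer is tabular: tibbles in, tibbles out.

#' Peak height at an assigned position
#'
#' Maximum of the real spectrum within a square window around the assigned
#' position, accommodating small apex offsets.
#'
#' @param spectrum an [nmr_spectrum()].
#' @param omega1_ppm,omega2_ppm assigned position, ppm.
#' @param window half-width of the search window in spectral points
#'   (default 1).
#' @return numeric peak height.
#' @export
peak_height <- function(spectrum, omega1_ppm, omega2_ppm, window = 1L) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  f1 <- ppm_to_hz(spectrum$axis1, omega1_ppm)
  f2 <- ppm_to_hz(spectrum$axis2, omega2_ppm)
  if (abs(f1) > spectrum$axis1$spectral_width / 2 ||
      abs(f2) > spectrum$axis2$spectral_width / 2) {
    abort_dcs("assigned position outside the spectral window", "dcsnmr_input_error")
  }
  i1 <- freq_to_index(f1, spectrum$axis1$spectral_width, spectrum$axis1$n_points)
  i2 <- freq_to_index(f2, spectrum$axis2$spectral_width, spectrum$axis2$n_points)
  w <- as.integer(window)
  r1 <- pmin(pmax(i1 + (-w:w), 1L), nrow(spectrum$data))
  r2 <- pmin(pmax(i2 + (-w:w), 1L), ncol(spectrum$data))
  max(spectrum$data[r1, r2])
}

#' Heights of a peak list in one spectrum
#'
#' @param spectrum an [nmr_spectrum()].
#' @param peaks data frame with columns `label`, `omega1_ppm`, `omega2_ppm`.
#' @param window passed to [peak_height()].
#' @return tibble with columns `label`, `height`.
#' @export
peak_heights <- function(spectrum, peaks, window = 1L) {
  stopifnot(all(c("label", "omega1_ppm", "omega2_ppm") %in% names(peaks)))
  tibble::tibble(
    label = peaks$label,
    height = vapply(seq_len(nrow(peaks)), function(i) {
      peak_height(spectrum, peaks$omega1_ppm[i], peaks$omega2_ppm[i], window)
    }, numeric(1))
  )
}

#' Noise level of a spectrum from a signal-free region
#'
#' Standard deviation of the intensities in a declared signal-free rectangle
#' (by default the last 10% of rows and columns, the spectrum corner).
#'
#' @param spectrum an [nmr_spectrum()].
#' @param rows,cols index vectors of the region; defaults to the
#'   bottom-right corner.
#' @return numeric noise sd.
#' @export
estimate_noise <- function(spectrum, rows = NULL, cols = NULL) {
  n1 <- nrow(spectrum$data); n2 <- ncol(spectrum$data)
  rows <- rows %||% seq.int(max(1L, floor(0.9 * n1)), n1)
  cols <- cols %||% seq.int(max(1L, floor(0.9 * n2)), n2)
  stats::sd(as.vector(spectrum$data[rows, cols]))
}

#' Relative intensities of a peak list across a matched series
#'
#' For each peak and temperature, measures the heights in the target and
#' reference spectra and forms `i_rel = height_target / height_ref`.  A
#' point is flagged invisible (and `i_rel` set to `NA`) when either height
#' falls below the noise threshold (3x the reference spectrum noise sd by
#' default, per spectrum).
#'
#' @param target_spectra,ref_spectra lists of [nmr_spectrum()], matched by
#'   position; temperatures must agree pairwise.
#' @param peaks peak table (`label`, `omega1_ppm`, `omega2_ppm`).
#' @param window search window for [peak_height()].
#' @param noise_factor visibility threshold in units of the noise sd.
#' @param noise_threshold absolute visibility threshold; overrides the
#'   per-spectrum estimate when supplied.
#' @return tibble with columns `label`, `temperature`, `height_ref`,
#'   `height_target`, `i_rel`, `visible`.
#' @export
relative_intensity <- function(target_spectra, ref_spectra, peaks,
                               window = 1L, noise_factor = 3,
                               noise_threshold = NULL) {
  if (length(target_spectra) != length(ref_spectra)) {
    abort_dcs("target and reference series lengths differ", "dcsnmr_input_error")
  }
  temps_t <- vapply(target_spectra, function(s) s$temperature %||% NA_real_, numeric(1))
  temps_r <- vapply(ref_spectra, function(s) s$temperature %||% NA_real_, numeric(1))
  if (!isTRUE(all.equal(temps_t, temps_r))) {
    abort_dcs("target and reference temperature lists do not match", "dcsnmr_input_error")
  }
  purrr::map_dfr(seq_along(target_spectra), function(i) {
    thr <- noise_threshold %||% (noise_factor * estimate_noise(ref_spectra[[i]]))
    h_r <- peak_heights(ref_spectra[[i]], peaks, window)$height
    h_t <- peak_heights(target_spectra[[i]], peaks, window)$height
    visible <- h_r >= thr & h_t >= thr
    tibble::tibble(
      label = peaks$label, temperature = temps_t[i],
      height_ref = h_r, height_target = h_t,
      i_rel = ifelse(visible, h_t / h_r, NA_real_),
      visible = visible
    )
  })
}

#' Bounded sigmoid fit of a relative-intensity profile
#'
#' Fits [sigmoid_curve()] by bounded nonlinear least squares
#' (Levenberg-Marquardt with box constraints).  Bounds:
#' `0.05 < x_scale < 0.8`, `20 < x_shift < 40` (transition temperatures
#' between 20 and 40 degC), `y_scale` within half to twice the observed y
#' range, `y_shift` within `min(y) +/- 0.1`.  Starting values: `x_shift` at
#' the median temperature, `x_scale = 0.3`, `y_scale` = y range, `y_shift`
#' = `min(y)`.
#'
#' @param temps temperatures, degC.
#' @param i_rel relative intensities (NAs dropped).
#' @param x_shift_bounds,x_scale_bounds numeric length-2 bounds.
#' @return an object of class `sigmoid_fit` with elements `par` (named
#'   vector), `relative_residual` (`||y_fit - y|| / ||y||`), `status`
#'   (`"accepted"` or `"poor_fit"` at this stage; see [filter_fits()]),
#'   `temps`, `y`, `fitted`, `n_points`.
#' @export
fit_sigmoid <- function(temps, i_rel,
                        x_shift_bounds = c(20, 40),
                        x_scale_bounds = c(0.05, 0.8)) {
  keep <- is.finite(temps) & is.finite(i_rel)
  x <- temps[keep]; y <- i_rel[keep]
  if (length(x) < 2) {
    abort_dcs("need at least 2 finite points to fit", "dcsnmr_input_error")
  }
  yr <- max(diff(range(y)), 1e-6)
  lower <- c(x_scale = x_scale_bounds[1], x_shift = x_shift_bounds[1],
             y_scale = yr / 2, y_shift = min(y) - 0.1)
  upper <- c(x_scale = x_scale_bounds[2], x_shift = x_shift_bounds[2],
             y_scale = 2 * yr, y_shift = min(y) + 0.1)
  start <- c(x_scale = 0.3,
             x_shift = min(max(stats::median(x), lower["x_shift"]), upper["x_shift"]),
             y_scale = yr, y_shift = min(y))
  names(start) <- c("x_scale", "x_shift", "y_scale", "y_shift")

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y_scale * (1 - tanh(x_scale * (x - x_shift))) / 2 + y_shift,
      data = data.frame(x = x, y = y),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(par = start, relative_residual = Inf, status = "poor_fit",
                diagnostics = conditionMessage(fit),
                temps = x, y = y, fitted = rep(NA_real_, length(x)),
                n_points = length(x))
    return(structure(out, class = "sigmoid_fit"))
  }
  par <- stats::coef(fit)
  yhat <- sigmoid_curve(x, par["x_scale"], par["x_shift"], par["y_scale"], par["y_shift"])
  structure(list(
    par = par,
    relative_residual = l2(yhat - y) / l2(y),
    status = "accepted", diagnostics = NULL,
    temps = x, y = y, fitted = yhat, n_points = length(x)
  ), class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> %s: x_shift %.2f degC, x_scale %.3f, y_scale %.3f, y_shift %.3f (rel. residual %.3g, %d points)\n",
              x$status, x$par["x_shift"], x$par["x_scale"],
              x$par["y_scale"], x$par["y_shift"],
              x$relative_residual, x$n_points))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$temps else newdata
  unname(sigmoid_curve(x, object$par[["x_scale"]], object$par[["x_shift"]],
                       object$par[["y_scale"]], object$par[["y_shift"]]))
}

#' Tidy a sigmoid fit
#' @param x a `sigmoid_fit`.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' One-row summary of a sigmoid fit
#' @param x a `sigmoid_fit`.
#' @param ... unused.
#' @return one-row tibble: the four parameters, `relative_residual`,
#'   `n_points`, `status`.
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    x_scale = unname(x$par["x_scale"]), x_shift = unname(x$par["x_shift"]),
    y_scale = unname(x$par["y_scale"]), y_shift = unname(x$par["y_shift"]),
    relative_residual = x$relative_residual,
    n_points = x$n_points, status = x$status
  )
}

#' Fit sigmoids for every peak of a relative-intensity table
#'
#' @param series tibble from [relative_intensity()].
#' @return tibble with one row per label: the fitted parameters, residual,
#'   number of visible points, and a `fit` list-column of `sigmoid_fit`
#'   objects (NULL where fewer than 2 visible points were available).
#' @export
fit_series <- function(series) {
  series |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(d, key) {
      vis <- d[d$visible & is.finite(d$i_rel), ]
      if (nrow(vis) < 2) {
        return(tibble::tibble(
          x_scale = NA_real_, x_shift = NA_real_, y_scale = NA_real_,
          y_shift = NA_real_, relative_residual = NA_real_,
          n_points = nrow(vis), status = "too_few_points",
          fit = list(NULL)
        ))
      }
      f <- fit_sigmoid(vis$temperature, vis$i_rel)
      g <- glance(f)
      g$fit <- list(f)
      g
    }) |>
    dplyr::ungroup()
}

#' Apply the rejection filters to fitted profiles
#'
#' A fit is rejected, in this order, when: (a) fewer than six visible data
#' points are available (`too_few_points`); (b) the fitted horizontal scale
#' is too small, `x_scale <= 0.08`, meaning only the near-linear middle of
#' the sigmoid was seen (`linear`); (c) the transition is too small: the
#' last-but-one data points on both sides (the second and the penultimate
#' visible points) differ by less than a factor of two (`small_transition`);
#' (d) the relative fit residual exceeds 0.1 (`poor_fit`).  The rest are
#' accepted.
#'
#' @param fits tibble from [fit_series()].
#' @param series tibble from [relative_intensity()] (to evaluate rule (c)
#'   on the visible profile).
#' @param min_points,x_scale_min,transition_ratio,max_residual filter
#'   thresholds (defaults as above).
#' @return `fits` with `status` updated and a logical `accepted` column.
#' @export
filter_fits <- function(fits, series, min_points = 6, x_scale_min = 0.08,
                        transition_ratio = 2, max_residual = 0.1) {
  ratio_rule <- series |>
    dplyr::filter(.data$visible & is.finite(.data$i_rel)) |>
    dplyr::arrange(.data$temperature) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_visible = dplyr::n(),
      side_ratio = if (dplyr::n() >= 4) {
        a <- .data$i_rel[2]; b <- .data$i_rel[dplyr::n() - 1]
        max(a, b) / max(min(a, b), .Machine$double.eps)
      } else NA_real_,
      .groups = "drop"
    )
  out <- dplyr::left_join(fits, ratio_rule, by = "label")
  out$n_visible <- dplyr::coalesce(out$n_visible, 0L)
  out$status <- dplyr::case_when(
    out$n_visible < min_points                    ~ "too_few_points",
    !is.na(out$x_scale) & out$x_scale <= x_scale_min ~ "linear",
    !is.na(out$side_ratio) & out$side_ratio < transition_ratio ~ "small_transition",
    !is.finite(out$relative_residual) |
      out$relative_residual > max_residual        ~ "poor_fit",
    TRUE                                          ~ "accepted"
  )
  out$accepted <- out$status == "accepted"
  out
}

#' Normalized peak-height residual
#'
#' The reconstruction quality metric: the l2 norm of the difference between
#' the reconstructed and the full-data peak-height vectors, divided by the
#' l2 norm of the full-data vector.
#'
#' @param heights_rec,heights_full equal-length numeric vectors.
#' @return numeric scalar.
#' @export
normalized_residual <- function(heights_rec, heights_full) {
  if (length(heights_rec) != length(heights_full)) {
    abort_dcs("height vectors must have equal length", "dcsnmr_input_error")
  }
  denom <- l2(heights_full)
  if (denom == 0) abort_dcs("full-data height vector has zero norm", "dcsnmr_input_error")
  l2(heights_rec - heights_full) / denom
}

#' Transition-temperature table
#'
#' Residue numbers are parsed from peak labels of the form `"A069N-H"`
#' (first digit group); unparseable labels get `NA` with a warning.
#'
#' @param fits tibble from [filter_fits()] (or [fit_series()]).
#' @param accepted_only keep only accepted fits (default `FALSE`: all rows
#'   are emitted with their status).
#' @return tibble (`label`, `residue`, `x_shift`, `status`) sorted by
#'   residue number.
#' @export
transition_table <- function(fits, accepted_only = FALSE) {
  if (nrow(fits) == 0) {
    return(tibble::tibble(label = character(), residue = integer(),
                          x_shift = numeric(), status = character()))
  }
  res <- suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", fits$label)))
  if (anyNA(res)) {
    warning("could not parse residue numbers from labels: ",
            paste(fits$label[is.na(res)], collapse = ", "))
  }
  out <- tibble::tibble(label = fits$label, residue = res,
                        x_shift = fits$x_shift, status = fits$status)
  if (accepted_only) out <- out[out$status == "accepted", ]
  dplyr::arrange(out, .data$residue)
}
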