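# ggplot2 views of the result types.

#' Plot a 2D spectrum
#'
#' Filled-raster view on ppm axes (reversed, NMR convention).
#'
#' @param object an [nmr_spectrum()].
#' @param floor intensities below `floor * max` are clipped to zero for
#'   display (default 0.02).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nmr_spectrum <- function(object, floor = 0.02, ...) {
  d <- tidy(object)
  top <- max(abs(d$intensity))
  d$intensity[abs(d$intensity) < floor * top] <- 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega2_ppm, y = .data$omega1_ppm,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "omega2 (ppm)", y = "omega1 (ppm)",
                  fill = "intensity",
                  title = sprintf("%s spectrum%s", object$provenance,
                                  if (!is.null(object$temperature))
                                    sprintf(" at %.1f degC", object$temperature) else "")) +
    ggplot2::theme_minimal()
}

#' Plot a sigmoid fit
#'
#' Data points and the fitted melting curve, with the transition
#' temperature marked.
#'
#' @param object a `sigmoid_fit` from [fit_sigmoid()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  pts <- tibble::tibble(temperature = object$temps, i_rel = object$y)
  xs <- seq(min(object$temps), max(object$temps), length.out = 200)
  curve <- tibble::tibble(temperature = xs, i_rel = predict(object, xs))
  ggplot2::ggplot(pts, ggplot2::aes(.data$temperature, .data$i_rel)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, color = "firebrick") +
    ggplot2::geom_vline(xintercept = unname(object$par["x_shift"]),
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "temperature (degC)", y = "relative intensity",
                  title = sprintf("transition at %.1f degC (%s)",
                                  object$par["x_shift"], object$status)) +
    ggplot2::theme_minimal()
}

#' Per-peak relative-intensity profiles
#'
#' Faceted I_rel vs temperature profiles for a (subset of a)
#' relative-intensity table.
#'
#' @param series tibble from [relative_intensity()].
#' @param labels optional subset of peak labels to show.
#' @return a ggplot.
#' @export
plot_intensity_profiles <- function(series, labels = NULL) {
  if (!is.null(labels)) series <- series[series$label %in% labels, ]
  ggplot2::ggplot(series[series$visible & is.finite(series$i_rel), ],
                  ggplot2::aes(.data$temperature, .data$i_rel)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "temperature (degC)", y = "relative intensity") +
    ggplot2::theme_minimal()
}

#' Transition temperature vs residue number
#'
#' @param table tibble from [transition_table()] (accepted fits are drawn
#'   filled; rejected fits, if present, are hollow).
#' @return a ggplot.
#' @export
plot_transition_temperatures <- function(table) {
  tab <- table[is.finite(table$x_shift), ]
  ggplot2::ggplot(tab, ggplot2::aes(.data$residue, .data$x_shift,
                                    shape = .data$status == "accepted")) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "residue number", y = "transition temperature (degC)") +
    ggplot2::theme_minimal()
}
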