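make_spectrum <- function(mat, sw1 = 2700, sw2 = 4000, temperature = NULL) {
  ax1 <- axis_meta(nrow(mat), sw1, carrier_ppm = 118, base_frequency = 70.95)
  ax2 <- axis_meta(ncol(mat), sw2, carrier_ppm = 8.3, base_frequency = 700)
  nmr_spectrum(mat, ax1, ax2, temperature = temperature)
}

test_that("peak heights are window maxima at assigned positions", {
  mat <- matrix(0, 64, 64)
  ax1 <- axis_meta(64, 2700, 118, 70.95); ax2 <- axis_meta(64, 4000, 8.3, 700)
  f1 <- 400; f2 <- -700
  i1 <- dcsnmr:::freq_to_index(f1, 2700, 64); i2 <- dcsnmr:::freq_to_index(f2, 4000, 64)
  mat[i1, i2] <- 1
  sp <- nmr_spectrum(mat, ax1, ax2)
  p1 <- hz_to_ppm(ax1, f1); p2 <- hz_to_ppm(ax2, f2)
  expect_equal(peak_height(sp, p1, p2), 1.0)

  expect_equal(peak_height(nmr_spectrum(matrix(0, 64, 64), ax1, ax2), p1, p2), 0.0)

  # apex one point off the nominal coordinate is still found with window 1
  mat2 <- matrix(0, 64, 64); mat2[i1 + 1, i2] <- 0.8; mat2[i1, i2] <- 0.5
  expect_equal(peak_height(nmr_spectrum(mat2, ax1, ax2), p1, p2, window = 1), 0.8)
  expect_equal(peak_height(nmr_spectrum(mat2, ax1, ax2), p1, p2, window = 0), 0.5)

  expect_error(peak_height(sp, 200, p2), "outside")
})

test_that("relative intensities divide target by reference and flag invisibility", {
  base <- matrix(0.001, 32, 32)
  i1 <- 10; i2 <- 20
  ref <- base; ref[i1, i2] <- 1
  ax1 <- axis_meta(32, 2700, 118, 70.95); ax2 <- axis_meta(32, 4000, 8.3, 700)
  peaks <- tibble::tibble(
    label = "A001N-H",
    omega1_ppm = hz_to_ppm(ax1, dcsnmr:::freq_axis_hz(2700, 32)[i1]),
    omega2_ppm = hz_to_ppm(ax2, dcsnmr:::freq_axis_hz(4000, 32)[i2]))
  sp_ref <- lapply(c(15, 17), function(tt) {
    s <- nmr_spectrum(ref, ax1, ax2, temperature = tt); s
  })
  sp_half <- lapply(sp_ref, function(s) { s$data <- 0.5 * s$data; s })

  same <- relative_intensity(sp_ref, sp_ref, peaks, noise_threshold = 0.01)
  expect_equal(same$i_rel, c(1, 1))

  halved <- relative_intensity(sp_half, sp_ref, peaks, noise_threshold = 0.01)
  expect_equal(halved$i_rel, c(0.5, 0.5))

  # target below the visibility threshold
  dim_t <- lapply(sp_ref, function(s) { s$data <- 0.001 * s$data; s })
  invis <- relative_intensity(dim_t, sp_ref, peaks, noise_threshold = 0.01)
  expect_false(any(invis$visible))
  expect_true(all(is.na(invis$i_rel)))

  bad <- sp_ref; bad[[2]]$temperature <- 99
  expect_error(relative_intensity(sp_ref, bad, peaks, noise_threshold = 0.01),
               "temperature")
})

test_that("an attenuated N-terminal block shows up as a low relative-intensity segment", {
  spec <- hsqc_series_spec(n_peaks = 40, n1 = 64, n2 = 64, sw2 = 2900,
                           snr = 200, shift_points = 0, broaden_hz = 0, seed = 11)
  ser <- generate_series(spec)
  peaks <- tibble::tibble(label = spec$peaks$label,
                          omega1_ppm = hz_to_ppm(spec$axis1, spec$peaks$f1),
                          omega2_ppm = hz_to_ppm(spec$axis2, spec$peaks$f2))
  # lowest temperature only: the N-terminal block (residues 1-10 of 40) is
  # already partially bound, the rest sit near the dilution-scaled reference
  ri <- relative_intensity(list(ft2d(ser$target[[1]])), list(ft2d(ser$reference[[1]])),
                           peaks, window = 2)
  res <- as.integer(sub("R(\\d+).*", "\\1", ri$label))
  nterm <- ri$i_rel[res <= 10]; rest <- ri$i_rel[res > 10]
  expect_lt(stats::median(nterm, na.rm = TRUE), 0.82)
  expect_gt(stats::median(rest, na.rm = TRUE), 0.82)
})

test_that("noiseless sigmoid data inverts to its generating parameters", {
  temps <- seq(15, 43, by = 2)
  y <- sigmoid_curve(temps, 0.3, 26, 0.8, 0.1)
  f <- fit_sigmoid(temps, y)
  expect_equal(unname(f$par), c(0.3, 26, 0.8, 0.1), tolerance = 1e-3)
  expect_lt(f$relative_residual, 1e-6)
  # midpoint identity: the fitted curve at x_shift is y_scale/2 + y_shift
  expect_equal(predict(f, f$par[["x_shift"]]),
               f$par[["y_scale"]] / 2 + f$par[["y_shift"]], tolerance = 1e-9)
  expect_error(fit_sigmoid(15, 1), "at least 2")
})

test_that("tidy and glance expose the fit in broom shape", {
  f <- fit_sigmoid(seq(15, 43, 2), sigmoid_curve(seq(15, 43, 2), 0.3, 26, 0.8, 0.1))
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("x_scale", "x_shift", "y_scale", "y_shift"))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("x_shift", "relative_residual", "status") %in% names(gl)))
})

test_that("transition temperatures survive 2% noise within a degree", {
  temps <- seq(15, 43, by = 2)
  y0 <- sigmoid_curve(temps, 0.3, 26, 0.8, 0.1)
  hits <- dcsnmr:::with_seed(123, {
    vapply(1:20, function(i) {
      y <- y0 + stats::rnorm(length(temps), sd = 0.02)
      abs(fit_sigmoid(temps, y)$par[["x_shift"]] - 26) <= 1
    }, logical(1))
  })
  expect_gte(sum(hits), 19)
})

test_that("each rejection filter fires on its constructed profile", {
  temps <- seq(15, 43, by = 2)
  mk_series <- function(label, y, visible = rep(TRUE, length(y))) {
    tibble::tibble(label = label, temperature = temps,
                   height_ref = 1, height_target = y,
                   i_rel = ifelse(visible, y, NA), visible = visible)
  }
  lin <- mk_series("L001", 1 - 0.015 * (temps - 15))                 # linear
  small <- mk_series("S001", sigmoid_curve(temps, 0.5, 29, 0.35, 0.6)) # shallow step
  short <- mk_series("F001", sigmoid_curve(temps, 0.3, 26, 0.8, 0.1),
                     visible = temps <= 23)                          # 5 points
  good <- mk_series("G001", sigmoid_curve(temps, 0.35, 27, 0.85, 0.05))
  noisy <- mk_series("N001", dcsnmr:::with_seed(9,
    sigmoid_curve(temps, 0.35, 27, 0.8, 0.1) + stats::rnorm(15, sd = 0.12)))
  series <- dplyr::bind_rows(lin, small, short, good, noisy)
  fits <- filter_fits(fit_series(series), series)
  status <- setNames(fits$status, fits$label)
  expect_equal(status[["L001"]], "linear")
  expect_equal(status[["S001"]], "small_transition")
  expect_equal(status[["F001"]], "too_few_points")
  expect_equal(status[["G001"]], "accepted")
  expect_equal(status[["N001"]], "poor_fit")
  # the documented ratio reading: second vs penultimate visible point
  expect_lt(fits$side_ratio[fits$label == "S001"], 2)
  expect_gt(fits$side_ratio[fits$label == "G001"], 2)
})

test_that("normalized residual matches its defining identities", {
  h <- c(1, 2, 3, 4)
  expect_equal(normalized_residual(h, h), 0)
  expect_equal(normalized_residual(rep(0, 4), h), 1)
  expect_equal(normalized_residual(1.1 * h, h), 0.1)
  # invariant to simultaneous rescaling of both vectors
  expect_equal(normalized_residual(3 * c(1.2, 1.9, 3.3), 3 * h[1:3]),
               normalized_residual(c(1.2, 1.9, 3.3), h[1:3]))
  expect_error(normalized_residual(h, c(0, 0, 0, 0)), "zero norm")
  expect_error(normalized_residual(h, h[1:2]), "equal length")
})

test_that("transition tables parse residue numbers and sort by them", {
  expect_equal(nrow(transition_table(tibble::tibble(
    label = character(), x_shift = numeric(), status = character()))), 0)

  fits <- tibble::tibble(label = c("A069N-H", "T059N-H"),
                         x_shift = c(27.5, 25.1),
                         status = c("accepted", "accepted"))
  tab <- transition_table(fits)
  expect_equal(tab$residue, c(59, 69))
  expect_equal(tab$x_shift, c(25.1, 27.5))

  odd <- tibble::tibble(label = c("A069N-H", "???"), x_shift = c(27, 28),
                        status = "accepted")
  expect_warning(tab2 <- transition_table(odd), "parse")
  expect_true(any(is.na(tab2$residue)))
})

test_that("a programmed transition-temperature gradient is recovered end to end", {
  spec <- hsqc_series_spec(n_peaks = 30, n1 = 64, n2 = 128, sw2 = 2900,
                           snr = 500, shift_points = 0, broaden_hz = 0, seed = 13)
  ser <- generate_series(spec)
  peaks <- tibble::tibble(label = spec$peaks$label,
                          omega1_ppm = hz_to_ppm(spec$axis1, spec$peaks$f1),
                          omega2_ppm = hz_to_ppm(spec$axis2, spec$peaks$f2))
  ri <- relative_intensity(lapply(ser$target, ft2d), lapply(ser$reference, ft2d),
                           peaks, window = 2)
  fits <- filter_fits(fit_series(ri), ri)
  tab <- transition_table(fits, accepted_only = TRUE)
  truth <- spec$peaks[match(tab$label, spec$peaks$label), ]
  expect_gt(nrow(tab), 10)
  expect_gt(stats::cor(tab$x_shift, truth$x_shift), 0.9)
  # the core block's programmed rise along the sequence survives
  core <- tab[tab$residue > 8 & tab$residue <= 22, ]
  expect_gt(stats::cor(core$residue, core$x_shift, method = "spearman"), 0.8)
})

test_that("plot constructors return ggplot objects", {
  f <- fit_sigmoid(seq(15, 43, 2), sigmoid_curve(seq(15, 43, 2), 0.3, 26, 0.8, 0.1))
  expect_s3_class(autoplot(f), "ggplot")
  tab <- tibble::tibble(label = "A010N-H", residue = 10, x_shift = 26,
                        status = "accepted")
  expect_s3_class(plot_transition_temperatures(tab), "ggplot")
  sp <- make_spectrum(matrix(rnorm(64), 8, 8))
  expect_s3_class(autoplot(sp), "ggplot")
  ser <- tibble::tibble(label = "A010N-H", temperature = seq(15, 43, 2),
                        i_rel = runif(15), visible = TRUE)
  expect_s3_class(plot_intensity_profiles(ser), "ggplot")
})
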