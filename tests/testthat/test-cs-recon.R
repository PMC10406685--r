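# conventional FT of a single column under the package conventions: the
# independent oracle for the IST output
conventional_column_ft <- function(column, z, apod = TRUE) {
  n <- length(column)
  if (apod) column <- column * dcsnmr:::apod_window(n, "cosine2")
  column[1] <- column[1] * 0.5
  dcsnmr:::fft_to_desc(Re(stats::fft(c(column, complex(z - n)))))
}

test_that("direct_ft flattens a t2 impulse and is linear", {
  ax <- small_axes(n1 = 4, n2 = 32)
  delta <- matrix(0 + 0i, 4, 32); delta[, 1] <- c(1, 2i, -1, 3)
  fid <- nmr_fid(delta, ax$ax1, ax$ax2)
  ig <- direct_ft(fid, apodization = "none")
  # t2 impulse at zero -> flat omega2 rows (halved by the first-point rule)
  expect_equal(Mod(ig$data[1, ]), rep(0.5, 64))
  expect_equal(ig$data[2, 5], 1i)

  f1 <- generate_fid(small_peaks(), small_axes()$ax1, small_axes()$ax2,
                     noise_sigma = 0.02, seed = 1)
  f2 <- generate_fid(small_peaks(), small_axes()$ax1, small_axes()$ax2,
                     noise_sigma = 0.02, seed = 2)
  fsum <- f1; fsum$data <- f1$data + 2 * f2$data
  expect_equal(direct_ft(fsum)$data,
               direct_ft(f1)$data + 2 * direct_ft(f2)$data, tolerance = 1e-9)
})

test_that("a single peak's omega2 column carries the full t1 modulation", {
  ax <- small_axes(n1 = 64, n2 = 64)
  pk <- data.frame(f1 = 700, f2 = -900, r2_1 = 12, r2_2 = 18, amplitude = 1)
  ig <- direct_ft(generate_fid(pk, ax$ax1, ax$ax2))
  i2 <- dcsnmr:::freq_to_index(-900, 4000, 128)
  col <- ig$data[, i2]
  t1 <- (0:63) / 2700
  model <- exp((2i * pi * 700 - 12) * t1)
  # column proportional to the analytic t1 modulation
  ratio <- col / model
  expect_lt(stats::sd(Mod(ratio)) / mean(Mod(ratio)), 1e-9)
})

test_that("virtual echo symmetrizes, counts 2M-1 positions, and yields a real transform", {
  ve <- virtual_echo(rep(1 + 0i, 8), NULL, z = 16)
  expect_equal(ve$v, Conj(ve$v[c(1, 16:2)])) # conjugate-symmetric
  expect_length(ve$positions, 15)

  sched <- poisson_gap_schedule(64, 16, seed = 5)
  col <- random_column(2, 31, n = 64)
  ve2 <- virtual_echo(col[sched$indices + 1], sched, z = 128)
  expect_length(ve2$positions, 2 * 16 - 1)

  full <- virtual_echo(col, NULL, z = 128)
  sp <- stats::fft(full$v)
  expect_lt(max(abs(Im(sp))), 1e-9 * max(abs(Re(sp))))
})

test_that("IST at full sampling reproduces the conventional FT", {
  col <- random_column(3, 17)
  rec <- ist_reconstruct(col, NULL)
  oracle <- conventional_column_ft(col, 512)
  expect_equal(rec, oracle, tolerance = 1e-6)

  # no virtual echo path as well
  rec2 <- ist_reconstruct(col, NULL, recon_config(virtual_echo = FALSE))
  expect_equal(rec2, oracle, tolerance = 1e-6)
})

test_that("IST maps zero to zero and rejects non-finite input", {
  sched <- poisson_gap_schedule(64, 16, seed = 2)
  expect_equal(ist_reconstruct(complex(16), sched), numeric(128))
  expect_error(ist_reconstruct(c(1 + 0i, NA), nus_schedule(c(0, 3), 8)),
               "non-finite")
})

test_that("a lone peak is recovered exactly in position and to 1% in height at M = 16", {
  col <- damped_column(450, 14, 1)
  full <- conventional_column_ft(col, 512)
  i_pk <- which.max(full)
  sched <- poisson_gap_schedule(256, 16, seed = 9)
  rec <- ist_reconstruct(col[sched$indices + 1], sched)
  expect_equal(which.max(rec), i_pk)
  expect_lt(abs(rec[i_pk] - full[i_pk]) / full[i_pk], 0.01)
})

test_that("three graded peaks reconstruct at r > 0.999 with heights within 1% at M = 64", {
  col <- damped_column(c(500, -300, 100), c(15, 20, 18), c(1, 0.6, 0.3))
  full <- conventional_column_ft(col, 512)
  idx <- vapply(c(500, -300, 100), function(f) dcsnmr:::freq_to_index(f, 2700, 512),
                integer(1))
  for (s in 1:5) {
    sched <- poisson_gap_schedule(256, 64, seed = s)
    rec <- ist_reconstruct(col[sched$indices + 1], sched)
    expect_gt(stats::cor(rec, full), 0.999)
    expect_lt(max(abs(rec[idx] - full[idx]) / full[idx]), 0.01)
  }
})

test_that("2D reconstruction of fully sampled data equals the plain FT", {
  ax <- small_axes(n1 = 32, n2 = 32)
  fid <- generate_fid(small_peaks(), ax$ax1, ax$ax2, noise_sigma = 0.01, seed = 3)
  sp <- ft2d(fid)
  rec <- cs_reconstruct_2d(fid)
  expect_lt(max(abs(rec$data - sp$data)), 1e-6 * max(abs(sp$data)))
  expect_equal(rec$provenance, "cs_rec")
})

test_that("noise-only input is not amplified by reconstruction", {
  # A deeply decayed threshold concentrates part of the measured noise into
  # isolated single-point spikes (the sparse explanation of noise); the
  # invariants are that noise energy is not amplified and spikes stay within
  # a small factor of the full-data noise maximum of the same realization.
  ax <- small_axes(n1 = 256, n2 = 8)
  empty <- data.frame(f1 = 0, f2 = 0, r2_1 = 0, r2_2 = 0, amplitude = 0)
  ratios <- vapply(21:24, function(s) {
    fid <- generate_fid(empty, ax$ax1, ax$ax2, noise_sigma = 1, seed = s)
    nus <- undersample(fid, poisson_gap_schedule(256, 64, seed = s))
    rec <- cs_reconstruct_2d(nus)
    full <- ft2d(fid)
    expect_lt(stats::sd(rec$data), stats::sd(full$data))
    max(abs(rec$data)) / max(abs(full$data))
  }, numeric(1))
  expect_lt(mean(ratios), 2)
  expect_lt(max(ratios), 3)
})

test_that("all true peaks of a crowded 2D spectrum survive reconstruction at M = 64", {
  p <- crossover_pair(1, Inf) # 50 peaks, noiseless
  nus <- undersample(p$tgt, poisson_gap_schedule(256, 64, seed = 31))
  rec <- cs_reconstruct_2d(nus)
  full <- ft2d(p$tgt)
  h_rec <- peak_heights(rec, p$peaks, window = 1)$height
  h_full <- peak_heights(full, p$peaks, window = 1)$height
  expect_true(all(h_rec > 0.5 * h_full))
  expect_lt(normalized_residual(h_rec, h_full), 0.1)
})

test_that("measured t1 points are honored exactly by the reconstruction", {
  col <- random_column(4, 77)
  sched <- poisson_gap_schedule(256, 32, seed = 6)
  cfg <- recon_config()
  w <- dcsnmr:::apod_window(256, "cosine2")
  meas <- col[sched$indices + 1] * w[sched$indices + 1]
  rec <- ist_reconstruct(col[sched$indices + 1], sched, cfg)
  # invert: the VE signal is the inverse FFT of the (real) doubled spectrum
  v <- stats::fft(dcsnmr:::desc_to_fft(2 * rec), inverse = TRUE) / length(rec)
  expect_equal(v[sched$indices + 1], meas, tolerance = 1e-9)
})

test_that("reconstruction error decreases with M and with spectral sparsity", {
  col <- random_column(8, 42)
  full <- conventional_column_ft(col, 512)
  ms <- c(8, 16, 24, 32, 40, 48, 56, 64, 128)
  err <- vapply(ms, function(m) {
    mean(vapply(1:10, function(s) {
      sched <- poisson_gap_schedule(256, m, seed = s)
      rec <- ist_reconstruct(col[sched$indices + 1], sched)
      dcsnmr:::l2(rec - full) / dcsnmr:::l2(full)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-6))

  sparse_err <- mean(vapply(1:10, function(s) {
    cl <- random_column(2, 100 + s)
    fl <- conventional_column_ft(cl, 512)
    sched <- poisson_gap_schedule(256, 16, seed = s)
    dcsnmr:::l2(ist_reconstruct(cl[sched$indices + 1], sched) - fl) / dcsnmr:::l2(fl)
  }, numeric(1)))
  crowded_err <- mean(vapply(1:10, function(s) {
    cl <- random_column(20, 200 + s)
    fl <- conventional_column_ft(cl, 512)
    sched <- poisson_gap_schedule(256, 16, seed = s)
    dcsnmr:::l2(ist_reconstruct(cl[sched$indices + 1], sched) - fl) / dcsnmr:::l2(fl)
  }, numeric(1)))
  expect_lt(sparse_err, crowded_err)
})
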