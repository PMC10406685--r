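# Fixtures built in code; everything is deterministic given the seeds used
# in the tests.

# a t1 column of K exponentially damped complex sinusoids on an n-point grid
damped_column <- function(freqs, rates, amps, n = 256, sw = 2700) {
  t1 <- (seq_len(n) - 1) / sw
  colSums(t(vapply(seq_along(freqs), function(k) {
    amps[k] * exp((2i * pi * freqs[k] - rates[k]) * t1)
  }, complex(n))))
}

random_column <- function(k, seed, n = 256, sw = 2700) {
  dcsnmr:::with_seed(seed, {
    damped_column(stats::runif(k, -0.45, 0.45) * sw,
                  stats::runif(k, 12, 25),
                  stats::runif(k, 0.4, 1.2), n = n, sw = sw)
  })
}

# small 2D peak table + axes for quick FID-level tests
small_axes <- function(n1 = 64, n2 = 64, sw1 = 2700, sw2 = 4000) {
  list(ax1 = axis_meta(n1, sw1, carrier_ppm = 118, base_frequency = 70.95),
       ax2 = axis_meta(n2, sw2, carrier_ppm = 8.3, base_frequency = 700))
}

small_peaks <- function() {
  data.frame(f1 = c(500, -300, 100), f2 = c(1000, -1500, 300),
             r2_1 = c(15, 20, 18), r2_2 = c(20, 25, 22),
             amplitude = c(1, 0.6, 0.3))
}

# matched 50-peak reference/target pair in which exactly 2 peaks change;
# used for the low-sparsity-difference head-to-head
crossover_pair <- function(seed, snr, n1 = 256, n2 = 32, sw1 = 2700, sw2 = 4000) {
  ax1 <- axis_meta(n1, sw1, carrier_ppm = 118, base_frequency = 70.95)
  ax2 <- axis_meta(n2, sw2, carrier_ppm = 8.3, base_frequency = 700)
  pk <- dcsnmr:::with_seed(seed, tibble::tibble(
    label = sprintf("P%02d", 1:50),
    f1 = stats::runif(50, -0.4, 0.4) * sw1,
    f2 = stats::runif(50, -0.4, 0.4) * sw2,
    r2_1 = stats::runif(50, 12, 25),
    r2_2 = stats::runif(50, 15, 30),
    amplitude = stats::runif(50, 0.6, 1.4)))
  sigma <- if (is.finite(snr)) calibrate_noise_sigma(pk, ax1, ax2, snr) else 0
  ref <- generate_fid(pk, ax1, ax2, noise_sigma = sigma, seed = seed * 1000 + 1)
  pk2 <- pk
  pk2$amplitude[c(10, 30)] <- pk2$amplitude[c(10, 30)] * c(0.25, 1.8)
  tgt <- generate_fid(pk2, ax1, ax2, noise_sigma = sigma, seed = seed * 1000 + 2)
  peaks <- tibble::tibble(label = pk$label,
                          omega1_ppm = hz_to_ppm(ax1, pk$f1),
                          omega2_ppm = hz_to_ppm(ax2, pk$f2))
  list(ref = ref, tgt = tgt, peaks = peaks, noise_sigma = sigma)
}

# one-seed CS-vs-DCS residual pair on the crossover fixture
crossover_residuals <- function(seed, m, snr) {
  p <- crossover_pair(seed, snr)
  sch <- poisson_gap_schedule(256, m, seed = seed)
  tn <- undersample(p$tgt, sch)
  h_full <- peak_heights(ft2d(p$tgt), p$peaks)$height
  h_cs <- peak_heights(cs_reconstruct_2d(tn), p$peaks)$height
  h_dcs <- peak_heights(dcs_reconstruct(tn, p$ref, auto_align = FALSE), p$peaks)$height
  c(cs = normalized_residual(h_cs, h_full),
    dcs = normalized_residual(h_dcs, h_full))
}

# minimal Varian fid-directory writer (big-endian), used to exercise the
# reader; 28-byte block headers with trailing pad
write_varian_fixture <- function(fid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n2 <- ncol(fid$data); n1 <- nrow(fid$data)
  np <- 2L * n2; ebytes <- 4L; tbytes <- np * ebytes
  bh <- 28L; bbytes <- bh + tbytes
  con <- file(file.path(dir, "fid"), "wb")
  writeBin(c(n1, 1L, np, ebytes, tbytes, bbytes), con, size = 4, endian = "big")
  writeBin(c(0L, 9L), con, size = 2, endian = "big")  # vers_id, status: S_DATA|S_FLOAT
  writeBin(1L, con, size = 4, endian = "big")          # nbheaders
  for (i in seq_len(n1)) {
    writeBin(raw(bh), con)                             # block header (ignored)
    inter <- as.numeric(rbind(Re(fid$data[i, ]), Im(fid$data[i, ])))
    writeBin(inter, con, size = 4, endian = "big")
  }
  close(con)
  pp <- c(
    "np 1 1 0 0 0 2 1 0 1 64",
    sprintf("1 %d", np), "0",
    "ni 1 1 0 0 0 2 1 0 1 64",
    sprintf("1 %d", n1), "0",
    "sw 1 1 0 0 0 2 1 0 1 64",
    sprintf("1 %.4f", fid$axis2$spectral_width), "0",
    "sw1 1 1 0 0 0 2 1 0 1 64",
    sprintf("1 %.4f", fid$axis1$spectral_width), "0",
    "sfrq 1 1 0 0 0 2 1 0 1 64",
    sprintf("1 %.4f", fid$axis2$base_frequency), "0",
    "dfrq 1 1 0 0 0 2 1 0 1 64",
    sprintf("1 %.4f", fid$axis1$base_frequency), "0")
  writeLines(pp, file.path(dir, "procpar"))
  invisible(dir)
}
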