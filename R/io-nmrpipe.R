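# Minimal NMRPipe 2D dialect: the standard 512-float32 header followed by
# float32 data records.  Covered subset: single-file 2D planes, complex
# time-domain (records hold re then im halves; indirect re/im rows
# interleaved) and real frequency-domain data.  Header word offsets follow
# the published fdatap.h layout.

FD <- list(
  MAGIC = 0L, FLTFORMAT = 1L, FLTORDER = 2L, DIMCOUNT = 9L,
  F1QUADFLAG = 55L, F2QUADFLAG = 56L, F2CAR = 66L, F1CAR = 67L,
  REALSIZE = 97L, SIZE = 99L, F2SW = 100L, F2ORIG = 101L,
  QUADFLAG = 106L, F2OBS = 119L, F2FTFLAG = 220L, F1FTFLAG = 222L,
  F2LABEL = 16L, F1LABEL = 18L,
  F1OBS = 218L, SPECNUM = 219L, TRANSPOSED = 221L,
  F1SW = 229L, F1ORIG = 249L, PIPEFLAG = 57L, TWODPHASE = 256L
)

nmrpipe_header <- function(fid_or_spec, freq_domain) {
  h <- numeric(512)
  obj <- fid_or_spec
  h[FD$FLTFORMAT + 1L] <- 4008636160 # 0xEEEEEEEE marker
  h[FD$FLTORDER + 1L] <- 2.345
  h[FD$DIMCOUNT + 1L] <- 2
  h[FD$SIZE + 1L] <- ncol(obj$data)            # direct-dimension points
  h[FD$SPECNUM + 1L] <- nrow(obj$data)         # indirect rows (complex increments)
  h[FD$QUADFLAG + 1L] <- if (freq_domain) 1 else 0
  h[FD$F2QUADFLAG + 1L] <- if (freq_domain) 1 else 0
  h[FD$F1QUADFLAG + 1L] <- if (freq_domain) 1 else 0
  h[FD$F2FTFLAG + 1L] <- if (freq_domain) 1 else 0
  h[FD$F1FTFLAG + 1L] <- if (freq_domain) 1 else 0
  h[FD$F2SW + 1L] <- obj$axis2$spectral_width
  h[FD$F1SW + 1L] <- obj$axis1$spectral_width
  h[FD$F2OBS + 1L] <- obj$axis2$base_frequency
  h[FD$F1OBS + 1L] <- obj$axis1$base_frequency
  h[FD$F2CAR + 1L] <- obj$axis2$carrier_ppm
  h[FD$F1CAR + 1L] <- obj$axis1$carrier_ppm
  # ORIG: frequency (Hz, absolute) of the last spectral point
  h[FD$F2ORIG + 1L] <- obj$axis2$carrier_ppm * obj$axis2$base_frequency -
    obj$axis2$spectral_width / 2 + obj$axis2$spectral_width / ncol(obj$data)
  h[FD$F1ORIG + 1L] <- obj$axis1$carrier_ppm * obj$axis1$base_frequency -
    obj$axis1$spectral_width / 2 + obj$axis1$spectral_width / nrow(obj$data)
  h
}

#' Write 2D data in NMRPipe format
#'
#' Writes the covered NMRPipe subset: real frequency-domain spectra
#' ([nmr_spectrum()]) or fully sampled complex time-domain data
#' ([nmr_fid()]; records hold the real then the imaginary half of each t2
#' vector, with indirect real/imaginary rows interleaved).
#'
#' @param obj an [nmr_spectrum()] or fully sampled [nmr_fid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nmrpipe <- function(obj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (inherits(obj, "nmr_spectrum")) {
    h <- nmrpipe_header(obj, freq_domain = TRUE)
    writeBin(as.numeric(h), con, size = 4, endian = "little")
    writeBin(as.numeric(as.vector(t(obj$data))), con, size = 4, endian = "little")
  } else if (inherits(obj, "nmr_fid")) {
    if (!is_fully_sampled(obj)) {
      abort_dcs("NMRPipe export of NUS data is not supported; write the internal container instead",
                "dcsnmr_io_error")
    }
    h <- nmrpipe_header(obj, freq_domain = FALSE)
    writeBin(as.numeric(h), con, size = 4, endian = "little")
    for (i in seq_len(nrow(obj$data))) {
      writeBin(as.numeric(c(Re(obj$data[i, ]), Im(obj$data[i, ]))),
               con, size = 4, endian = "little")
      # placeholder imaginary t1 row (States pair), kept zero: the package
      # represents one complex value per t1 increment
      writeBin(numeric(2 * ncol(obj$data)), con, size = 4, endian = "little")
    }
  } else {
    abort_dcs("obj must be nmr_fid or nmr_spectrum", "dcsnmr_input_error")
  }
  invisible(path)
}

#' Read 2D data in NMRPipe format (covered subset)
#'
#' @param path NMRPipe file written by [write_nmrpipe()] or a compatible
#'   single-plane 2D file.
#' @return an [nmr_spectrum()] (frequency domain) or [nmr_fid()] (time
#'   domain).
#' @export
read_nmrpipe <- function(path) {
  if (!file.exists(path)) abort_dcs(paste0("no such file: ", path), "dcsnmr_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "double", n = 512, size = 4, endian = "little")
  if (length(h) < 512 || abs(h[FD$FLTORDER + 1L] - 2.345) > 1e-4) {
    abort_dcs("not a little-endian NMRPipe file (FDFLTORDER mismatch)",
              "dcsnmr_io_error")
  }
  if (h[FD$DIMCOUNT + 1L] != 2) {
    abort_dcs("only 2D NMRPipe data is supported", "dcsnmr_io_error")
  }
  nx <- as.integer(h[FD$SIZE + 1L])
  ny <- as.integer(h[FD$SPECNUM + 1L])
  freq_domain <- h[FD$F2FTFLAG + 1L] == 1
  ax2 <- axis_meta(nx, h[FD$F2SW + 1L], h[FD$F2CAR + 1L], h[FD$F2OBS + 1L])
  ax1 <- axis_meta(ny, h[FD$F1SW + 1L], h[FD$F1CAR + 1L], h[FD$F1OBS + 1L])
  if (freq_domain) {
    dat <- readBin(con, "double", n = nx * ny, size = 4, endian = "little")
    if (length(dat) != nx * ny) abort_dcs("truncated NMRPipe file", "dcsnmr_io_error")
    nmr_spectrum(matrix(dat, ny, nx, byrow = TRUE), ax1, ax2)
  } else {
    dat <- readBin(con, "double", n = 4 * nx * ny, size = 4, endian = "little")
    if (length(dat) != 4 * nx * ny) abort_dcs("truncated NMRPipe file", "dcsnmr_io_error")
    rows <- matrix(dat, nrow = 2 * ny, byrow = TRUE) # re|im records, t1 re/im interleaved
    cplx <- matrix(0 + 0i, ny, nx)
    for (i in seq_len(ny)) {
      r <- rows[2 * i - 1, ]
      cplx[i, ] <- complex(real = r[seq_len(nx)], imaginary = r[nx + seq_len(nx)])
    }
    nmr_fid(cplx, ax1, ax2)
  }
}
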