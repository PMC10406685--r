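# Minimal Varian/Agilent fid-directory reader: `procpar` (text parameter
# file) + `fid` (big-endian binary: 32-byte file header, per-block headers,
# float32 traces with interleaved re/im).  The block-header size is derived
# from the file header's own bookkeeping (bbytes = nbheaders * headersize +
# ntraces * tbytes), so both 24- and 28-byte header dialects read correctly.

#' Parse a Varian procpar file
#'
#' Returns a named list of parameter values (numeric where possible,
#' character otherwise; multi-value parameters become vectors).
#'
#' @param path path to a `procpar` file.
#' @return named list.
#' @export
read_procpar <- function(path) {
  if (!file.exists(path)) abort_dcs(paste0("no such file: ", path), "dcsnmr_io_error")
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    head <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(head) >= 3 && grepl("^[A-Za-z_]", head[1])) {
      name <- head[1]
      basictype <- head[3] # 1 = real, 2 = string
      i <- i + 1L
      vals_line <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      nvals <- suppressWarnings(as.integer(vals_line[1]))
      if (!is.na(nvals)) {
        if (identical(basictype, "2")) {
          vals <- character(0)
          first <- sub("^\\s*\\d+\\s*", "", lines[i])
          vals <- c(vals, gsub("\"", "", first))
          while (length(vals) < nvals && i < length(lines)) {
            i <- i + 1L
            vals <- c(vals, gsub("\"", "", trimws(lines[i])))
          }
          out[[name]] <- vals
        } else {
          vals <- suppressWarnings(as.numeric(vals_line[-1]))
          out[[name]] <- vals
        }
        i <- i + 1L # skip the trailing enumeration line
      }
    }
    i <- i + 1L
  }
  out
}

#' Read a Varian/Agilent fid directory
#'
#' Reads `procpar` and `fid` and assembles a [nmr_fid()].  If the file
#' holds two blocks per t1 increment (hypercomplex/States acquisition,
#' `nblocks == 2 * ni`), consecutive block pairs A, B are combined into one
#' complex increment as `A + 1i * B`; phase correction beyond this
#' combination is not attempted.
#'
#' @param dir directory containing `procpar` and `fid`.
#' @return a fully sampled [nmr_fid()].
#' @export
read_varian <- function(dir) {
  fid_path <- file.path(dir, "fid")
  pp_path <- file.path(dir, "procpar")
  if (!file.exists(fid_path) || !file.exists(pp_path)) {
    abort_dcs(paste0(dir, " is not a Varian fid directory (need fid + procpar)"),
              "dcsnmr_io_error")
  }
  pp <- read_procpar(pp_path)
  con <- file(fid_path, "rb")
  on.exit(close(con))
  nblocks <- readBin(con, "integer", 1, size = 4, endian = "big")
  ntraces <- readBin(con, "integer", 1, size = 4, endian = "big")
  np      <- readBin(con, "integer", 1, size = 4, endian = "big")
  ebytes  <- readBin(con, "integer", 1, size = 4, endian = "big")
  tbytes  <- readBin(con, "integer", 1, size = 4, endian = "big")
  bbytes  <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 1, size = 2, endian = "big") # vers_id
  status  <- readBin(con, "integer", 1, size = 2, endian = "big")
  nbheaders <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (np * ebytes != tbytes) {
    abort_dcs("inconsistent Varian file header (np * ebytes != tbytes)",
              "dcsnmr_io_error")
  }
  bh_size <- if (nbheaders > 0) (bbytes - ntraces * tbytes) %/% nbheaders else 0L
  is_float <- bitwAnd(status, 8L) != 0
  traces <- matrix(0 + 0i, nblocks * ntraces, np %/% 2L)
  row <- 1L
  for (b in seq_len(nblocks)) {
    if (bh_size > 0) readBin(con, "raw", n = bh_size * nbheaders)
    for (tr in seq_len(ntraces)) {
      raw <- if (is_float) {
        readBin(con, "double", n = np, size = ebytes, endian = "big")
      } else {
        readBin(con, "integer", n = np, size = ebytes, endian = "big")
      }
      if (length(raw) != np) abort_dcs("truncated Varian fid file", "dcsnmr_io_error")
      traces[row, ] <- complex(real = raw[c(TRUE, FALSE)],
                               imaginary = raw[c(FALSE, TRUE)])
      row <- row + 1L
    }
  }
  ni <- as.integer(pp$ni %||% nrow(traces))[1]
  if (!is.na(ni) && ni > 0 && nrow(traces) == 2L * ni) {
    traces <- traces[seq(1, nrow(traces), by = 2), , drop = FALSE] +
      1i * traces[seq(2, nrow(traces), by = 2), , drop = FALSE]
  }
  sw  <- (pp$sw %||% 1)[1]
  sw1 <- (pp$sw1 %||% 1)[1]
  sfrq <- (pp$sfrq %||% 1)[1]
  dfrq <- (pp$dfrq %||% 1)[1]
  ax2 <- axis_meta(ncol(traces), sw, carrier_ppm = 0, base_frequency = sfrq)
  ax1 <- axis_meta(nrow(traces), sw1, carrier_ppm = 0, base_frequency = dfrq)
  nmr_fid(traces, ax1, ax2, label = basename(dir))
}

#' Read 2D NMR data, dispatching on format
#'
#' @param path internal container directory, NMRPipe file, or Varian fid
#'   directory.
#' @param format `"internal"`, `"nmrpipe"` or `"varian"`; `"auto"` guesses
#'   from the path contents.
#' @return for `"internal"`, a list of objects; otherwise a single
#'   [nmr_fid()] or [nmr_spectrum()].
#' @export
read_spectrum_data <- function(path, format = c("auto", "internal", "nmrpipe", "varian")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) && file.exists(file.path(path, "manifest.json"))) {
      "internal"
    } else if (dir.exists(path) && file.exists(file.path(path, "fid"))) {
      "varian"
    } else if (file.exists(path) && !dir.exists(path)) {
      "nmrpipe"
    } else {
      abort_dcs(paste0("cannot determine format of ", path), "dcsnmr_io_error")
    }
  }
  switch(format,
    internal = read_series_container(path),
    nmrpipe = read_nmrpipe(path),
    varian = read_varian(path)
  )
}
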