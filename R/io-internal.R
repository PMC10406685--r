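# Internal self-describing container: one directory per series with a JSON
# manifest (axes, temperatures, schedule, seed) and one flat binary file per
# spectrum -- float64 little-endian, interleaved re/im (for complex time-
# domain data) or plain re (for real spectra), row-major.

axis_to_list <- function(ax) {
  list(n_points = ax$n_points, spectral_width = ax$spectral_width,
       carrier_ppm = ax$carrier_ppm, base_frequency = ax$base_frequency)
}

axis_from_list <- function(l) {
  axis_meta(l$n_points, l$spectral_width, l$carrier_ppm, l$base_frequency)
}

write_complex_bin <- function(mat, path) {
  # row-major, interleaved re/im
  v <- as.vector(t(mat))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.double(rbind(Re(v), Im(v))), con, size = 8, endian = "little")
  invisible(path)
}

read_complex_bin <- function(path, nrow, ncol) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = 2 * nrow * ncol, size = 8, endian = "little")
  if (length(raw) != 2 * nrow * ncol) {
    abort_dcs(paste0("truncated binary file: ", path), "dcsnmr_io_error")
  }
  v <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  matrix(v, nrow, ncol, byrow = TRUE)
}

write_real_bin <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.double(as.vector(t(mat))), con, size = 8, endian = "little")
  invisible(path)
}

read_real_bin <- function(path, nrow, ncol) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = nrow * ncol, size = 8, endian = "little")
  if (length(raw) != nrow * ncol) {
    abort_dcs(paste0("truncated binary file: ", path), "dcsnmr_io_error")
  }
  matrix(raw, nrow, ncol, byrow = TRUE)
}

#' Write / read a series of FIDs or spectra as an internal container
#'
#' The container is a directory holding `manifest.json` plus one `.bin`
#' file per object (little-endian float64, row-major; complex data is
#' stored with interleaved real/imaginary parts).
#'
#' @param objects list of [nmr_fid()] and/or [nmr_spectrum()] objects.
#' @param dir directory to create.
#' @param seed optional seed recorded in the manifest.
#' @param extra named list merged into the manifest (e.g. generation
#'   settings).
#' @return `write_series_container` returns `dir` invisibly;
#'   `read_series_container` returns the list of objects.
#' @export
write_series_container <- function(objects, dir, seed = NULL, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(objects), function(i) {
    obj <- objects[[i]]
    name <- if (nzchar(obj$label %||% "")) obj$label else sprintf("item_%03d", i)
    file <- paste0(name, ".bin")
    e <- list(
      file = file, label = obj$label,
      type = if (inherits(obj, "nmr_fid")) "fid" else "spectrum",
      n_rows = nrow(obj$data), n_cols = ncol(obj$data),
      axis1 = axis_to_list(obj$axis1), axis2 = axis_to_list(obj$axis2),
      temperature = obj$temperature
    )
    if (inherits(obj, "nmr_fid")) {
      write_complex_bin(obj$data, file.path(dir, file))
      if (!is.null(obj$schedule)) {
        e$schedule <- list(indices = obj$schedule$indices, n = obj$schedule$n,
                           seed = obj$schedule$seed, kind = obj$schedule$kind)
      }
    } else if (inherits(obj, "nmr_spectrum")) {
      write_real_bin(obj$data, file.path(dir, file))
      e$provenance <- obj$provenance
    } else {
      abort_dcs("objects must be nmr_fid or nmr_spectrum", "dcsnmr_input_error")
    }
    e
  })
  manifest <- c(list(format = "dcsnmr-series", version = 1L,
                     seed = seed, entries = entries), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_series_container
#' @export
read_series_container <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    abort_dcs(paste0("no manifest.json in ", dir), "dcsnmr_io_error")
  }
  manifest <- jsonlite::read_json(mpath)
  if (!identical(manifest$format, "dcsnmr-series")) {
    abort_dcs("not a dcsnmr series container", "dcsnmr_io_error")
  }
  lapply(manifest$entries, function(e) {
    ax1 <- axis_from_list(e$axis1); ax2 <- axis_from_list(e$axis2)
    path <- file.path(dir, e$file)
    if (!file.exists(path)) abort_dcs(paste0("missing data file: ", path),
                                      "dcsnmr_io_error")
    if (identical(e$type, "fid")) {
      sched <- NULL
      if (!is.null(e$schedule)) {
        sched <- nus_schedule(unlist(e$schedule$indices), e$schedule$n,
                              seed = e$schedule$seed %||% NA_integer_,
                              kind = e$schedule$kind %||% "explicit")
      }
      nmr_fid(read_complex_bin(path, e$n_rows, e$n_cols), ax1, ax2,
              schedule = sched, temperature = e$temperature,
              label = e$label %||% "")
    } else {
      nmr_spectrum(read_real_bin(path, e$n_rows, e$n_cols), ax1, ax2,
                   temperature = e$temperature,
                   provenance = e$provenance %||% "full_ft",
                   label = e$label %||% "")
    }
  })
}
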