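# Internal helpers shared across modules.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Reorder FFT output so index 1 is +SW/2 and frequency decreases with index
#'
#' `stats::fft` places the frequency f = j * SW / Z at 1-based bin j + 1
#' (modulo Z).  The package-wide axis convention puts +SW/2 first and runs
#' downward, so output index k (1-based) holds bin (Z/2 - (k - 1)) mod Z.
#' @noRd
fft_to_desc <- function(x) {
  if (is.matrix(x)) {
    z <- nrow(x)
    x[((z %/% 2 - seq_len(z) + 1) %% z) + 1L, , drop = FALSE]
  } else {
    z <- length(x)
    x[((z %/% 2 - seq_len(z) + 1) %% z) + 1L]
  }
}

#' Inverse of fft_to_desc
#' @noRd
desc_to_fft <- function(x) {
  if (is.matrix(x)) {
    z <- nrow(x)
    idx <- ((z %/% 2 - seq_len(z) + 1) %% z) + 1L
    out <- x
    out[idx, ] <- x
    out
  } else {
    z <- length(x)
    idx <- ((z %/% 2 - seq_len(z) + 1) %% z) + 1L
    out <- x
    out[idx] <- x
    out
  }
}

#' Frequency axis (Hz offsets from carrier) on a processed grid, descending
#' @noRd
freq_axis_hz <- function(sw, z) sw / 2 - (seq_len(z) - 1) * sw / z

#' 1-based grid index of a frequency (Hz offset from carrier), descending axis
#' @noRd
freq_to_index <- function(f, sw, z) {
  k <- round((sw / 2 - f) / (sw / z))
  as.integer(k %% z) + 1L
}

#' Apodization window over n acquired points
#' @noRd
apod_window <- function(n, kind = c("cosine2", "none")) {
  kind <- match.arg(kind)
  switch(kind,
    cosine2 = cos((pi / 2) * (seq_len(n) - 1) / n)^2,
    none    = rep(1, n)
  )
}

l2 <- function(x) sqrt(sum(abs(x)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_dcs <- function(msg, class) {
  stop(structure(
    class = c(class, "dcsnmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
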