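#' Non-uniform sampling schedule
#'
#' An ordered set of indirect-dimension grid indices (0-based) out of a full
#' grid of `n` points.  Index 0 (the first increment) is always part of any
#' schedule produced by the package generators.
#'
#' @param indices strictly increasing integer vector of 0-based grid indices.
#' @param n full grid size.
#' @param seed seed used to generate the schedule (`NA` for explicit ones).
#' @param kind `"poisson_gap"`, `"uniform"` or `"explicit"`.
#' @return an object of class `nus_schedule`.
#' @export
nus_schedule <- function(indices, n, seed = NA_integer_,
                         kind = c("explicit", "poisson_gap", "uniform")) {
  kind <- match.arg(kind)
  indices <- as.integer(indices)
  n <- as.integer(n)
  if (length(indices) < 1 || length(indices) > n) {
    abort_dcs("schedule must contain between 1 and n indices", "dcsnmr_schedule_error")
  }
  if (any(diff(indices) <= 0)) {
    abort_dcs("schedule indices must be strictly increasing", "dcsnmr_schedule_error")
  }
  if (indices[1] < 0 || indices[length(indices)] > n - 1) {
    abort_dcs("schedule indices must lie in [0, n - 1]", "dcsnmr_schedule_error")
  }
  structure(list(indices = indices, n = n, m = length(indices),
                 seed = seed, kind = kind),
            class = "nus_schedule")
}

#' @export
print.nus_schedule <- function(x, ...) {
  cat(sprintf("<nus_schedule> %d of %d points (%s%s)\n", x$m, x$n, x$kind,
              if (!is.na(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}

# One stochastic pass of sinusoidally weighted Poisson-gap placement.
# Gap after each sampled point is drawn from Pois(lambda * sin(pi*t/(2N)))
# so gaps grow toward late evolution times.  Returns 0-based indices
# (always starting at 0) that fit in [0, N-1].
poisson_gap_pass <- function(n, lambda, sinusoidal) {
  idx <- integer(0)
  pos <- 0L
  while (pos <= n - 1L) {
    idx <- c(idx, pos)
    w <- if (sinusoidal) sin(pi * (pos + 0.5) / (2 * n)) else 1
    gap <- stats::rpois(1L, lambda * w)
    pos <- pos + 1L + gap
  }
  idx
}

#' Generate a Poisson-gap sampling schedule
#'
#' Draws gaps between consecutive sampled indirect-dimension points from
#' Poisson distributions whose means are (optionally) sinusoidally modulated
#' so that gaps are larger at late evolution times, where the signal has
#' decayed.  The internal rate is rescaled iteratively (secant-style
#' adjustment, with a restart rather than clipping when a drawn gap overruns
#' the grid) until exactly `m` points land in `[0, n - 1]`.  The first
#' increment (index 0) is always sampled.
#'
#' @param n full indirect-dimension grid size.
#' @param m number of points to sample, `1 <= m <= n`.
#' @param seed integer seed; the same seed always yields the same schedule.
#' @param sinusoidal_weight logical; apply the sinusoidal gap weighting
#'   (default `TRUE`).
#' @return a [nus_schedule()] with `kind = "poisson_gap"`.
#' @export
poisson_gap_schedule <- function(n, m, seed = 1L, sinusoidal_weight = TRUE) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1) abort_dcs("m must be at least 1", "dcsnmr_schedule_error")
  if (m > n) abort_dcs("m cannot exceed the grid size n", "dcsnmr_schedule_error")
  if (m == n) {
    return(nus_schedule(0:(n - 1L), n, seed = seed, kind = "poisson_gap"))
  }
  idx <- with_seed(seed, {
    # initial mean gap so that m points span the grid
    lambda <- max(n / m - 1, 1e-3)
    best <- NULL
    for (attempt in seq_len(4000L)) {
      cand <- poisson_gap_pass(n, lambda, sinusoidal_weight)
      k <- length(cand)
      if (k == m) { best <- cand; break }
      # multiplicative rate update toward the target count
      lambda <- max(lambda * (k / m)^1.0 + (k - m) / m * 0.1, 1e-4)
    }
    if (is.null(best)) {
      abort_dcs("Poisson-gap rate adjustment failed to converge", "dcsnmr_schedule_error")
    }
    best
  })
  nus_schedule(idx, n, seed = seed, kind = "poisson_gap")
}

#' Draw a nested (subset) schedule from a parent schedule
#'
#' Difference reconstruction requires the target schedule to be a subset of
#' the reference schedule.  This draws `m_child` of the parent's positions by
#' Poisson-gap-weighted subsampling: a Poisson-gap schedule is generated on
#' the parent's ordinal positions and mapped back to the parent's indices.
#' Index 0 is retained.
#'
#' @param parent a [nus_schedule()].
#' @param m_child number of points in the child schedule.
#' @param seed integer seed.
#' @param sinusoidal_weight passed to the underlying Poisson-gap draw.
#' @return a [nus_schedule()] whose indices are a subset of `parent$indices`.
#' @export
nest_schedule <- function(parent, m_child, seed = 1L, sinusoidal_weight = TRUE) {
  stopifnot(inherits(parent, "nus_schedule"))
  m_child <- as.integer(m_child)
  if (m_child > parent$m) {
    abort_dcs("m_child cannot exceed the parent schedule size", "dcsnmr_schedule_error")
  }
  if (m_child == parent$m) {
    return(nus_schedule(parent$indices, parent$n, seed = seed, kind = parent$kind))
  }
  pos <- poisson_gap_schedule(parent$m, m_child, seed = seed,
                              sinusoidal_weight = sinusoidal_weight)
  nus_schedule(parent$indices[pos$indices + 1L], parent$n,
               seed = seed, kind = "poisson_gap")
}

#' Artificially undersample a fully sampled FID
#'
#' Keeps the rows of `fid_full` at the schedule's indices and attaches the
#' schedule, emulating non-uniform acquisition of an already-measured data
#' set.
#'
#' @param fid_full fully sampled [nmr_fid()].
#' @param schedule a [nus_schedule()] with `n` equal to the indirect grid
#'   size.
#' @return an [nmr_fid()] carrying `schedule`.
#' @export
undersample <- function(fid_full, schedule) {
  stopifnot(inherits(fid_full, "nmr_fid"), inherits(schedule, "nus_schedule"))
  if (!is.null(fid_full$schedule) &&
      length(fid_full$schedule$indices) != fid_full$schedule$n) {
    abort_dcs("input FID is already undersampled", "dcsnmr_schedule_error")
  }
  if (schedule$n != fid_full$axis1$n_points) {
    abort_dcs("schedule grid size does not match the FID's indirect dimension",
              "dcsnmr_schedule_error")
  }
  nmr_fid(fid_full$data[schedule$indices + 1L, , drop = FALSE],
          fid_full$axis1, fid_full$axis2, schedule = schedule,
          temperature = fid_full$temperature, label = fid_full$label)
}

#' Read / write NUS schedule files
#'
#' Plain-text "nuslist"-style files: one grid index per line, ascending.
#' Files are written 0-based; 1-based files can be read with
#' `one_based = TRUE`.
#'
#' @param path file path.
#' @param n full grid size.  When reading, defaults to `max(index) + 1`.
#' @param one_based logical; the file stores 1-based indices.
#' @return `read_schedule` returns a [nus_schedule()];
#'   `write_schedule` returns `path` invisibly.
#' @export
read_schedule <- function(path, n = NULL, one_based = FALSE) {
  if (!file.exists(path)) abort_dcs(paste0("no such schedule file: ", path),
                                    "dcsnmr_io_error")
  idx <- scan(path, what = integer(), quiet = TRUE)
  if (one_based) idx <- idx - 1L
  idx <- sort(unique(as.integer(idx)))
  nus_schedule(idx, n %||% (max(idx) + 1L), kind = "explicit")
}

#' @rdname read_schedule
#' @param schedule a [nus_schedule()] to write.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "nus_schedule"))
  writeLines(as.character(schedule$indices), path)
  invisible(path)
}
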