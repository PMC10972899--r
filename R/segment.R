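#' Detect crawling cycles from the left-palm pressure signal
#'
#' The pressure signal is flat (at the plateau) during stance and flat (at
#' zero) during swing, so its first derivative is positive only while
#' transitioning into stance and negative only while transitioning into
#' swing. Cycle starting points are the sustained positive-derivative
#' crossings (stance onsets); swing onsets are the sustained negative
#' crossings; a crawling cycle spans two adjacent stance onsets.
#'
#' Real derivatives are never exactly zero, so the signal is pre-smoothed
#' with a moving average, the derivative is thresholded at a fraction of its
#' robust maximum, and a minimum phase duration debounces spurious
#' crossings. Detection is invariant to positive rescaling of the signal.
#' Incomplete leading/trailing phases are discarded: the event sequence
#' always starts and ends with a stance onset.
#'
#' @param pressure Numeric pressure vector (finite).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param smooth_ms Moving-average window (ms) applied before
#'   differentiation.
#' @param deriv_frac Threshold as a fraction of the derivative's robust
#'   (99.5th percentile) absolute maximum.
#' @param min_phase_ms Minimum credible phase duration (ms); events closer
#'   than this to the previously accepted event are discarded.
#' @param amp_frac A candidate transition must change the smoothed signal by
#'   at least this fraction of its robust (1st-99th percentile) range; sensor
#'   noise moves the derivative but not the level, so this rejects spurious
#'   crossings that survive smoothing.
#' @return An object of class `cycle_boundaries`: a tibble with columns
#'   `event` (`"stance"`/`"swing"`), `sample_index` (1-based), `time_s`,
#'   with the sampling rate stored in the `sample_rate` attribute.
#' @export
detect_cycles <- function(pressure, sample_rate, smooth_ms = 25,
                          deriv_frac = 0.1, min_phase_ms = 100,
                          amp_frac = 0.3) {
  if (any(!is.finite(pressure))) stop("pressure contains non-finite samples", call. = FALSE)
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  n <- length(pressure)
  min_phase <- max(1L, round(min_phase_ms / 1000 * sample_rate))
  if (n < 2L * min_phase) stop("signal shorter than two minimum phases", call. = FALSE)

  w <- max(1L, round(smooth_ms / 1000 * sample_rate))
  sm <- if (w > 1) {
    padded <- c(rep(pressure[1], w), pressure, rep(pressure[n], w))
    as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[w + seq_len(n)]
  } else {
    pressure
  }
  d <- diff(sm) * sample_rate
  thr <- deriv_frac * stats::quantile(abs(d), 0.995, names = FALSE)
  if (thr <= 0) stop("no complete crawling cycle found (flat signal)", call. = FALSE)

  state <- ifelse(d > thr, 1L, ifelse(d < -thr, -1L, 0L))
  r <- rle(state)
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  run_end <- run_start + r$lengths - 1L
  # level change across the run: a real transition traverses (most of) the
  # plateau amplitude, noise-induced runs do not
  rng <- diff(stats::quantile(sm, c(0.01, 0.99), names = FALSE))
  delta <- sm[pmin(run_end + 1L, n)] - sm[run_start]
  keep <- r$values != 0L & (r$values * delta) >= amp_frac * rng
  cand <- tibble::tibble(
    type = ifelse(r$values == 1L, "stance", "swing"),
    index = run_start
  )[keep, ]

  kept_type <- character(0)
  kept_idx <- integer(0)
  expect <- "stance"
  for (i in seq_len(nrow(cand))) {
    if (length(kept_idx) > 0 && cand$index[i] - kept_idx[length(kept_idx)] < min_phase) next
    if (cand$type[i] != expect) next
    kept_type <- c(kept_type, cand$type[i])
    kept_idx <- c(kept_idx, cand$index[i])
    expect <- if (expect == "stance") "swing" else "stance"
  }
  # trim so the sequence ends on a stance onset (complete cycles only)
  if (length(kept_type) > 0 && kept_type[length(kept_type)] == "swing") {
    kept_type <- kept_type[-length(kept_type)]
    kept_idx <- kept_idx[-length(kept_idx)]
  }
  if (sum(kept_type == "stance") < 2) {
    stop("no complete crawling cycle found", call. = FALSE)
  }
  out <- tibble::tibble(
    event = kept_type,
    sample_index = kept_idx,
    time_s = (kept_idx - 1) / sample_rate
  )
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("cycle_boundaries", class(out))
  out
}

boundary_onsets <- function(boundaries) {
  list(
    stance = boundaries$sample_index[boundaries$event == "stance"],
    swing = boundaries$sample_index[boundaries$event == "swing"]
  )
}

#' Per-cycle stance and swing durations
#'
#' For each complete cycle (two adjacent stance onsets with a swing onset
#' between them): stance = swing onset minus stance onset, swing = next
#' stance onset minus swing onset, in seconds.
#'
#' @param boundaries A `cycle_boundaries` object from [detect_cycles()].
#' @param sample_rate Sampling rate (Hz); defaults to the rate recorded in
#'   `boundaries`.
#' @return A tibble with columns `cycle`, `stance_s`, `swing_s`.
#' @export
phase_durations <- function(boundaries, sample_rate = attr(boundaries, "sample_rate")) {
  on <- boundary_onsets(boundaries)
  n_cycles <- length(on$stance) - 1
  if (n_cycles < 1) stop("need at least one complete cycle", call. = FALSE)
  if (length(on$swing) != n_cycles ||
    any(on$swing <= on$stance[seq_len(n_cycles)]) ||
    any(on$swing >= on$stance[seq_len(n_cycles) + 1])) {
    stop("malformed alternation of stance/swing onsets", call. = FALSE)
  }
  tibble::tibble(
    cycle = seq_len(n_cycles),
    stance_s = (on$swing - on$stance[seq_len(n_cycles)]) / sample_rate,
    swing_s = (on$stance[seq_len(n_cycles) + 1] - on$swing) / sample_rate
  )
}

#' Slice a multi-channel EMG matrix into per-cycle segments
#'
#' Each complete cycle is the half-open sample interval from one stance
#' onset up to (not including) the next, so concatenating the segments
#' reproduces the spanned signal exactly.
#'
#' @param emg A `30 x T` numeric matrix (channels in rows).
#' @param boundaries A `cycle_boundaries` object from [detect_cycles()].
#' @return A list of `30 x L_k` matrices, one per complete cycle.
#' @export
slice_cycles <- function(emg, boundaries) {
  stopifnot(is.matrix(emg))
  on <- boundary_onsets(boundaries)$stance
  if (max(on) - 1 > ncol(emg)) stop("boundaries exceed EMG length", call. = FALSE)
  purrr::map(seq_len(length(on) - 1), function(k) {
    emg[, on[k]:(on[k + 1] - 1), drop = FALSE]
  })
}
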