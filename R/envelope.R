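#' Extract the EMG envelope of one crawling cycle
#'
#' The raw EMG of each crawling cycle is high-pass filtered, demeaned,
#' full-wave rectified, and low-pass filtered to extract the envelope, the
#' low-frequency amplitude profile that reflects muscle activation intensity
#' over the cycle. Filters are zero-phase (forward-backward) Butterworth, so
#' burst timing -- the discriminative feature -- is not shifted.
#'
#' @param x Numeric matrix, time points in rows, channels in columns.
#' @param sample_rate Sampling rate (Hz).
#' @param hp_hz High-pass cutoff (Hz), default 20.
#' @param lp_hz Low-pass cutoff (Hz), default 5.
#' @param order Butterworth order (applied forward and backward), default 4.
#' @return Envelope matrix, same shape as `x`, nonnegative up to filter
#'   ringing.
#' @export
extract_envelope <- function(x, sample_rate, hp_hz = 20, lp_hz = 5, order = 4) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("EMG contains non-finite values", call. = FALSE)
  warmup <- 3 * sample_rate / lp_hz # three low-pass periods
  if (nrow(x) < warmup) {
    stop("cycle shorter than the filter warm-up (", ceiling(warmup), " samples)", call. = FALSE)
  }
  hp <- signal::butter(order, hp_hz / (sample_rate / 2), type = "high")
  lp <- signal::butter(order, lp_hz / (sample_rate / 2), type = "low")
  apply(x, 2, function(ch) {
    y <- signal::filtfilt(hp, ch)
    y <- abs(y - mean(y))
    signal::filtfilt(lp, y)
  })
}

#' Normalize each channel of an envelope to unit variance
#'
#' Channels with zero variance cannot be scaled; they are left at zero and a
#' warning records which ones.
#'
#' @param x Numeric matrix, time in rows, channels in columns.
#' @return Matrix of the same shape with per-column variance 1 (or a zero
#'   column where the input had no variance).
#' @export
normalize_amplitude <- function(x) {
  x <- as.matrix(x)
  v <- apply(x, 2, stats::var)
  dead <- v == 0 | !is.finite(v)
  if (any(dead)) {
    warning(
      "zero-variance channel(s) left at zero: ",
      paste(which(dead), collapse = ", "),
      call. = FALSE
    )
    x[, dead] <- 0
    v[dead] <- 1
  }
  sweep(x, 2, sqrt(v), "/")
}

#' Resample a cycle to a fixed number of time points
#'
#' Linear interpolation over a common `[0, 1]` phase axis; endpoints are
#' preserved, so every cycle becomes directly comparable regardless of its
#' raw duration.
#'
#' @param x Numeric matrix, time in rows, channels in columns (>= 2 rows).
#' @param n_points Output length, default 1000.
#' @return An `n_points x ncol(x)` matrix.
#' @export
normalize_cycle_length <- function(x, n_points = 1000) {
  x <- as.matrix(x)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (nrow(x) < 2) stop("cycle must have at least 2 samples", call. = FALSE)
  phase_in <- seq(0, 1, length.out = nrow(x))
  phase_out <- seq(0, 1, length.out = n_points)
  apply(x, 2, function(ch) stats::approx(phase_in, ch, xout = phase_out)$y)
}

#' Build the envelope feature dataset from a cohort of trials
#'
#' For every trial: detect cycle boundaries from the pressure signal, slice
#' the EMG into per-cycle segments, and convert each segment into the
#' normalized envelope feature -- high-pass, demean, rectify, low-pass, then
#' resample to `n_points` time points and scale every channel to unit
#' variance. One labelled sample per complete crawling cycle.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (columns
#'   `participant_id`, `mode`, `speed`, `trial`).
#' @param boundaries Optional list of precomputed `cycle_boundaries`, one per
#'   trial row; detected from each trial's pressure signal when `NULL`.
#' @param n_points Time points per normalized cycle, default 1000.
#' @param hp_hz,lp_hz,order Envelope filter settings, see
#'   [extract_envelope()].
#' @param ... Passed to [detect_cycles()].
#' @return A tibble with one row per cycle: `participant_id`, `mode`,
#'   `speed`, `trial_row`, `cycle`, and `envelope` (list of
#'   `n_points x 30` matrices).
#' @export
build_dataset <- function(cohort, boundaries = NULL, n_points = 1000,
                          hp_hz = 20, lp_hz = 5, order = 4, ...) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    trial <- cohort$trial[[i]]
    b <- if (is.null(boundaries)) {
      detect_cycles(trial$pressure, trial$sample_rate, ...)
    } else {
      boundaries[[i]]
    }
    segs <- slice_cycles(trial$emg, b)
    if (length(segs) == 0) stop("trial ", i, " has zero complete cycles", call. = FALSE)
    env <- purrr::map(segs, function(seg) {
      e <- extract_envelope(t(seg), trial$sample_rate, hp_hz, lp_hz, order)
      normalize_amplitude(normalize_cycle_length(e, n_points))
    })
    tibble::tibble(
      participant_id = trial$participant_id,
      mode = trial$mode,
      speed = trial$speed,
      trial_row = i,
      cycle = seq_along(env),
      envelope = env
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-trial cycle-count manifest of a feature dataset
#'
#' @param dataset A dataset tibble from [build_dataset()].
#' @return A tibble with one row per (participant, mode, speed) and the
#'   number of cycles contributed.
#' @export
dataset_manifest <- function(dataset) {
  dplyr::count(
    dataset, .data$participant_id, .data$mode, .data$speed,
    name = "n_cycles"
  )
}
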