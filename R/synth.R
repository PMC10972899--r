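#' Configuration for the synthetic crawling-cohort generator
#'
#' The generator emulates the statistical structure of multi-channel crawling
#' recordings: a left-palm pressure channel that plateaus during stance, and
#' 30 surface-EMG channels whose burst timing encodes which limb is swinging.
#' Defaults reproduce the study conditions of the emulated experiment: cycle
#' durations of roughly 3.5 / 2.33 / 1.75 s at low / medium / fast speed and
#' per-cycle stance fractions with means 0.7040 / 0.6497 / 0.5898 and sds
#' 0.0654 / 0.0532 / 0.0481.
#'
#' @param speeds Named list (`low`, `medium`, `fast`); each element a list
#'   with `cycle_mean`, `cycle_sd` (s) and `stance_mean`, `stance_sd`
#'   (fraction of cycle).
#' @param muscle_map Named list mapping each limb (`LP`, `RP`, `LK`, `RK`) to
#'   the EMG channel indices preferentially activated during that limb's
#'   swing. All 30 channels must be covered.
#' @param jitter_sd Per-event touchdown jitter sd (s) for non-left-palm limbs.
#' @param gain_sdlog Log-sd of the per-participant, per-channel lognormal
#'   gain multipliers.
#' @param participant_timing_sd Sd of the per-participant systematic
#'   burst-center shift per channel, as a fraction of the swing duration
#'   (timing individuality scales with cycle period).
#' @param limb_timing_sd Sd of the per-participant, per-limb coherent
#'   burst-center offset (fraction of swing duration) shared by all of a
#'   limb's channels; this is what makes one participant's activation
#'   pattern systematically unlike another's.
#' @param burst_width_frac Gaussian burst sd as a fraction of the swing
#'   duration.
#' @param burst_amp Peak activation amplitude (arbitrary units).
#' @param baseline_noise Baseline noise amplitude relative to `burst_amp`.
#' @param carrier_band Two-element EMG carrier pass band (Hz).
#' @param pressure_plateau Pressure plateau level during stance (> 0).
#' @param pressure_ramp Rise/fall ramp duration at phase transitions (s).
#' @param pressure_noise_sd Additive pressure sensor noise sd.
#' @param sample_rate Sampling rate (Hz); the emulated hardware used 1000.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(speeds = list(
                           low = list(cycle_mean = 3.50, cycle_sd = 0.15, stance_mean = 0.7040, stance_sd = 0.0654),
                           medium = list(cycle_mean = 2.33, cycle_sd = 0.10, stance_mean = 0.6497, stance_sd = 0.0532),
                           fast = list(cycle_mean = 1.75, cycle_sd = 0.08, stance_mean = 0.5898, stance_sd = 0.0481)
                         ),
                         muscle_map = list(
                           LP = 1:8, LK = 9:15, RP = 16:23, RK = 24:30
                         ),
                         jitter_sd = 0.05,
                         gain_sdlog = 0.3,
                         participant_timing_sd = 0.12,
                         limb_timing_sd = 0.15,
                         burst_width_frac = 0.30,
                         burst_amp = 1,
                         baseline_noise = 0.05,
                         carrier_band = c(30, 300),
                         pressure_plateau = 1,
                         pressure_ramp = 0.05,
                         pressure_noise_sd = 0.01,
                         sample_rate = 1000) {
  channels <- sort(unique(unlist(muscle_map)))
  if (!identical(channels, 1:30)) {
    stop("muscle_map must cover exactly channels 1..30", call. = FALSE)
  }
  for (sp in names(speeds)) {
    s <- speeds[[sp]]
    if (!(s$stance_mean > 0 && s$stance_mean < 1)) {
      stop("stance_mean must be in (0, 1) for speed ", sp, call. = FALSE)
    }
    if (s$cycle_sd < 0 || s$stance_sd < 0) {
      stop("sds must be nonnegative for speed ", sp, call. = FALSE)
    }
  }
  if (jitter_sd < 0 || gain_sdlog < 0 || participant_timing_sd < 0 ||
    limb_timing_sd < 0) {
    stop("variability parameters must be nonnegative", call. = FALSE)
  }
  structure(
    list(
      speeds = speeds, muscle_map = muscle_map, jitter_sd = jitter_sd,
      gain_sdlog = gain_sdlog, participant_timing_sd = participant_timing_sd,
      limb_timing_sd = limb_timing_sd,
      burst_width_frac = burst_width_frac, burst_amp = burst_amp,
      baseline_noise = baseline_noise, carrier_band = carrier_band,
      pressure_plateau = pressure_plateau, pressure_ramp = pressure_ramp,
      pressure_noise_sd = pressure_noise_sd, sample_rate = sample_rate
    ),
    class = "synth_config"
  )
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 9176 + 1) %% 2147483647
  }
  as.integer(s)
}

#' Generate ground-truth limb timing for one synthetic trial
#'
#' Per-cycle durations and stance fractions are drawn from the speed
#' condition's normal distributions; non-left-palm touchdowns receive
#' Gaussian jitter. If jitter reorders the mode's event groups within a
#' cycle, that cycle's jitter is resampled (bounded attempts). The returned
#' timing covers `n_cycles` complete left-palm-to-left-palm cycles, i.e. the
#' left palm has `n_cycles + 1` touchdowns (cycles 1..n plus the closing
#' touchdown). A warm-up cycle 0 contributes touchdown/liftoff pairs for the
#' non-palm limbs only (at negative times), so that every swing interval
#' overlapping the first real cycle is defined; it adds no pressure cycle.
#'
#' @param config A [synth_config()].
#' @param mode An `ilcm_definition` or mode id.
#' @param speed `"low"`, `"medium"` or `"fast"`.
#' @param n_cycles Number of complete cycles (>= 1).
#' @param seed Integer seed.
#' @param participant Optional participant parameter list from
#'   [participant_params()] (currently only used by [generate_emg()]).
#' @return A tibble with columns `limb`, `cycle`, `touchdown`, `liftoff`.
#' @export
generate_timing <- function(config, mode, speed, n_cycles, seed,
                            participant = NULL) {
  mode <- as_ilcm(mode)
  stopifnot(n_cycles >= 1)
  sp <- config$speeds[[speed]]
  if (is.null(sp)) stop("unknown speed condition: ", speed, call. = FALSE)
  with_local_seed(seed, {
    # cycle 0 is a warm-up: its non-palm events provide the liftoffs whose
    # swings (and EMG bursts) fall inside the first real cycle
    n_all <- n_cycles + 2 # warm-up + n_cycles + closing LP touchdown
    durations <- pmax(stats::rnorm(n_all, sp$cycle_mean, sp$cycle_sd), 0.5 * sp$cycle_mean)
    stance <- pmin(pmax(stats::rnorm(n_all, sp$stance_mean, sp$stance_sd), 0.05), 0.95)
    starts <- c(-durations[1], -durations[1] + cumsum(durations))[seq_len(n_all)]
    phases <- mode$ideal_phase
    limbs <- names(phases)
    rows <- vector("list", n_all)
    group_of <- rep(seq_along(mode$landing_order), lengths(mode$landing_order))
    names(group_of) <- unlist(mode$landing_order)
    for (k in seq_len(n_all)) {
      # warm-up cycle 0 has no palm event (so no extra pressure cycle); the
      # closing cycle keeps all limbs so every swing spanning the last real
      # cycle has its terminating touchdown
      use <- if (k == 1) setdiff(limbs, "LP") else limbs
      if (length(use) == 0) next
      for (try in seq_len(100L)) {
        td <- starts[k] + phases[use] * durations[k]
        jit <- stats::rnorm(length(use), 0, config$jitter_sd)
        jit[use == "LP"] <- 0 # LP touchdowns define the cycle grid
        td <- td + jit
        g <- group_of[use]
        gmax <- tapply(td, g, max) # tapply orders by group index
        gmin <- tapply(td, g, min)
        ord_ok <- length(gmax) <= 1 || all(gmax[-length(gmax)] < gmin[-1])
        if (ord_ok) break
        if (try == 100L) {
          stop("could not realize landing order under the configured jitter", call. = FALSE)
        }
      }
      rows[[k]] <- tibble::tibble(
        limb = use, cycle = k - 1L, # warm-up is cycle 0
        touchdown = unname(td),
        liftoff = unname(td) + stance[k] * durations[k]
      )
    }
    dplyr::bind_rows(rows) |> dplyr::arrange(.data$touchdown, .data$limb)
  })
}

#' Per-participant generator parameters
#'
#' Draws the participant-level variability: lognormal per-channel gains, a
#' systematic per-channel burst-center shift, and a burst-width multiplier.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A list with `gains` (length 30), `shift_frac` (length 30,
#'   fraction of swing duration), `limb_shift` (named, per limb, fraction of
#'   swing duration), `width_mult` (scalar).
#' @export
participant_params <- function(config, seed) {
  with_local_seed(seed, {
    limbs <- names(config$muscle_map)
    list(
      gains = stats::rlnorm(30, 0, config$gain_sdlog),
      shift_frac = stats::rnorm(30, 0, config$participant_timing_sd),
      limb_shift = stats::setNames(
        stats::rnorm(length(limbs), 0, config$limb_timing_sd), limbs
      ),
      width_mult = exp(stats::rnorm(1, 0, 0.15))
    )
  })
}

trial_n_samples <- function(timing, config) {
  ceiling((max(timing$liftoff) + 2 * config$pressure_ramp) * config$sample_rate) + 1L
}

#' Synthesize the left-palm pressure signal from ground-truth timing
#'
#' The signal sits at the plateau level during left-palm stance, at zero
#' during swing, with linear ramps of the configured width at each
#' transition; optional additive sensor noise is clipped at zero.
#'
#' @param timing Timing tibble from [generate_timing()] or [ideal_schedule()].
#' @param config A [synth_config()].
#' @param n_samples Signal length; defaults to covering the timing span.
#' @param seed Optional seed for the sensor noise.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_pressure <- function(timing, config, n_samples = NULL, seed = NULL) {
  lp <- dplyr::filter(timing, .data$limb == "LP")
  if (nrow(lp) == 0) stop("timing has no left-palm events", call. = FALSE)
  if (config$pressure_plateau <= 0) stop("pressure plateau must be > 0", call. = FALSE)
  ramp <- config$pressure_ramp
  shortest <- min(lp$liftoff - lp$touchdown, diff(lp$touchdown) - (lp$liftoff - lp$touchdown)[-nrow(lp)])
  if (ramp >= shortest) stop("pressure ramp longer than the shortest phase", call. = FALSE)
  fs <- config$sample_rate
  if (is.null(n_samples)) n_samples <- trial_n_samples(timing, config)
  t <- (seq_len(n_samples) - 1) / fs
  p <- numeric(n_samples)
  for (i in seq_len(nrow(lp))) {
    up <- pmin(1, pmax(0, (t - lp$touchdown[i]) / ramp))
    down <- pmin(1, pmax(0, (lp$liftoff[i] + ramp - t) / ramp))
    p <- p + config$pressure_plateau * up * down
  }
  if (config$pressure_noise_sd > 0) {
    p <- with_local_seed(seed, p + stats::rnorm(n_samples, 0, config$pressure_noise_sd))
  }
  pmax(p, 0)
}

band_limited_noise <- function(n, band, fs) {
  w <- band / (fs / 2)
  bf <- signal::butter(4, w, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Synthesize the 30-channel EMG matrix from ground-truth timing
#'
#' Each channel is band-limited Gaussian noise amplitude-modulated by smooth
#' Gaussian activation bursts centred in the swing phase of the channel's
#' limb, plus low-level baseline noise, scaled by the participant's
#' per-channel gain. Modes therefore differ in the cross-channel timing of
#' the bursts rather than in marginal amplitude.
#'
#' @inheritParams generate_pressure
#' @param seed Integer seed.
#' @param participant Participant parameters from [participant_params()];
#'   `NULL` means unit gains, no shift.
#' @return A `30 x n_samples` numeric matrix.
#' @export
generate_emg <- function(timing, config, seed, participant = NULL,
                         n_samples = NULL) {
  if (length(config$muscle_map) == 0) stop("empty muscle_map", call. = FALSE)
  fs <- config$sample_rate
  if (is.null(n_samples)) n_samples <- trial_n_samples(timing, config)
  t <- (seq_len(n_samples) - 1) / fs
  if (is.null(participant)) {
    participant <- list(
      gains = rep(1, 30), shift_frac = rep(0, 30),
      limb_shift = stats::setNames(rep(0, length(config$muscle_map)), names(config$muscle_map)),
      width_mult = 1
    )
  }
  # swing intervals per limb: liftoff -> next touchdown of the same limb
  swings <- timing |>
    dplyr::group_by(.data$limb) |>
    dplyr::arrange(.data$touchdown, .by_group = TRUE) |>
    dplyr::mutate(next_td = dplyr::lead(.data$touchdown)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_td))
  limb_of <- character(30)
  for (limb in names(config$muscle_map)) limb_of[config$muscle_map[[limb]]] <- limb
  with_local_seed(seed, {
    emg <- matrix(0, nrow = 30, ncol = n_samples)
    for (ch in 1:30) {
      sw <- swings[swings$limb == limb_of[ch], ]
      act <- numeric(n_samples)
      if (config$burst_amp > 0 && nrow(sw) > 0) {
        for (i in seq_len(nrow(sw))) {
          dur <- sw$next_td[i] - sw$liftoff[i]
          centre <- (sw$liftoff[i] + sw$next_td[i]) / 2 +
            (participant$shift_frac[ch] + participant$limb_shift[[limb_of[ch]]]) * dur
          sigma <- config$burst_width_frac * dur * participant$width_mult
          act <- act + config$burst_amp * exp(-(t - centre)^2 / (2 * sigma^2))
        }
      }
      carrier <- band_limited_noise(n_samples, config$carrier_band, fs)
      base <- band_limited_noise(n_samples, config$carrier_band, fs)
      emg[ch, ] <- participant$gains[ch] *
        (act * carrier + config$baseline_noise * base)
    }
    emg
  })
}

#' Generate one synthetic crawling trial
#'
#' @inheritParams generate_timing
#' @param participant_id Participant identifier (e.g. `"P1"`).
#' @param participant Participant parameters; drawn from `seed` when `NULL`.
#' @return A list of class `crawl_trial` with elements `emg` (30 x T),
#'   `pressure` (length T), `sample_rate`, `participant_id`, `speed`,
#'   `mode`, and the ground-truth `timing` tibble.
#' @export
generate_trial <- function(config, participant_id, mode, speed, n_cycles,
                           seed, participant = NULL) {
  mode <- as_ilcm(mode)
  if (is.null(participant)) participant <- participant_params(config, derive_seed(seed, 1))
  timing <- generate_timing(config, mode, speed, n_cycles, derive_seed(seed, 2))
  n <- trial_n_samples(timing, config)
  pressure <- generate_pressure(timing, config, n, seed = derive_seed(seed, 3))
  emg <- generate_emg(timing, config, derive_seed(seed, 4), participant, n)
  structure(
    list(
      emg = emg, pressure = pressure, sample_rate = config$sample_rate,
      participant_id = participant_id, speed = speed, mode = mode$mode_id,
      timing = timing
    ),
    class = "crawl_trial"
  )
}

#' @export
print.crawl_trial <- function(x, ...) {
  cat(sprintf(
    "<crawl_trial %s %s %s: 30 x %d EMG @ %g Hz, %d LP touchdowns>\n",
    x$participant_id, x$mode, x$speed, ncol(x$emg), x$sample_rate,
    sum(x$timing$limb == "LP")
  ))
  invisible(x)
}

#' Generate a synthetic cohort of crawling trials
#'
#' One trial per (participant, mode, speed) combination. Participant-level
#' parameters (gains, timing shifts) are drawn once per participant so every
#' trial of a participant shares them; the whole cohort is reproducible from
#' the master seed.
#'
#' @param config A [synth_config()].
#' @param n_participants Number of virtual participants (>= 1).
#' @param modes Character vector of mode ids.
#' @param speeds Character vector of speed conditions.
#' @param cycles_per_trial Complete cycles per trial.
#' @param seed Master integer seed.
#' @return A tibble with columns `participant_id`, `mode`, `speed`,
#'   `n_cycles` and a `trial` list column of `crawl_trial` objects.
#' @export
generate_cohort <- function(config, n_participants, modes, speeds,
                            cycles_per_trial, seed) {
  if (n_participants < 1) stop("need at least one participant", call. = FALSE)
  if (length(modes) == 0 || length(speeds) == 0) {
    stop("modes and speeds must be nonempty", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    participant = seq_len(n_participants),
    mode = modes,
    speed = speeds
  )
  pars <- purrr::map(seq_len(n_participants), function(p) {
    participant_params(config, derive_seed(seed, p, 0, 0))
  })
  trials <- purrr::pmap(grid, function(participant, mode, speed) {
    generate_trial(
      config,
      participant_id = paste0("P", participant),
      mode = mode, speed = speed, n_cycles = cycles_per_trial,
      seed = derive_seed(seed, participant, match(mode, modes), match(speed, speeds)),
      participant = pars[[participant]]
    )
  })
  tibble::tibble(
    participant_id = paste0("P", grid$participant),
    mode = grid$mode,
    speed = grid$speed,
    n_cycles = cycles_per_trial,
    trial = trials
  )
}
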