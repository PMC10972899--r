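# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A fast-paced configuration for quick trials: short cycles, standard
# variability structure. Used where the speed condition itself is not under
# test.
quick_config <- function(...) {
  synth_config(
    speeds = list(
      low = list(cycle_mean = 1.6, cycle_sd = 0.06, stance_mean = 0.70, stance_sd = 0.04),
      medium = list(cycle_mean = 1.3, cycle_sd = 0.05, stance_mean = 0.65, stance_sd = 0.04),
      fast = list(cycle_mean = 1.0, cycle_sd = 0.04, stance_mean = 0.59, stance_sd = 0.04)
    ),
    jitter_sd = 0.02,
    ...
  )
}

# Noise-free variant: deterministic timing, clean pressure, no
# participant-level variation (EMG carriers remain stochastic).
noiseless_config <- function(...) {
  synth_config(
    speeds = list(
      low = list(cycle_mean = 1.6, cycle_sd = 0, stance_mean = 0.70, stance_sd = 0),
      medium = list(cycle_mean = 1.3, cycle_sd = 0, stance_mean = 0.65, stance_sd = 0),
      fast = list(cycle_mean = 1.0, cycle_sd = 0, stance_mean = 0.59, stance_sd = 0)
    ),
    jitter_sd = 0, gain_sdlog = 0, participant_timing_sd = 0,
    limb_timing_sd = 0, pressure_noise_sd = 0,
    ...
  )
}

small_cohort <- function() {
  cached("small_cohort", generate_cohort(
    quick_config(), 3, c("M1", "M2", "M3", "M4"), "fast", 6,
    seed = 20260101
  ))
}

small_dataset <- function() {
  cached("small_dataset", build_dataset(small_cohort()))
}

# Two-class, clearly separated toy envelopes: class A bursts early in the
# cycle, class B late. Constructed directly, independent of the generator.
toy_envelopes <- function(n_per_class = 6, seed = 99) {
  withr::with_seed(seed, {
    phase <- seq(0, 1, length.out = 1000)
    make <- function(centre) {
      env <- sapply(1:30, function(ch) {
        exp(-(phase - centre)^2 / (2 * 0.1^2)) + rnorm(1000, 0, 0.05)
      })
      normalize_amplitude(env)
    }
    tibble::tibble(
      participant_id = rep("P1", 2 * n_per_class),
      mode = rep(c("A", "B"), each = n_per_class),
      speed = "fast",
      trial_row = 1L,
      cycle = seq_len(2 * n_per_class),
      envelope = c(
        replicate(n_per_class, make(0.25), simplify = FALSE),
        replicate(n_per_class, make(0.75), simplify = FALSE)
      )
    )
  })
}

# Hand-built cycle_boundaries object (stance/swing onsets in samples).
make_boundaries <- function(stance, swing, sample_rate = 1000) {
  n <- length(stance) + length(swing)
  ev <- character(n)
  idx <- integer(n)
  ord <- order(c(stance, swing))
  ev <- c(rep("stance", length(stance)), rep("swing", length(swing)))[ord]
  idx <- c(stance, swing)[ord]
  out <- tibble::tibble(event = ev, sample_index = idx, time_s = (idx - 1) / sample_rate)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("cycle_boundaries", class(out))
  out
}
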