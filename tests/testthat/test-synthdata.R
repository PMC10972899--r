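test_that("zero-variability timing degenerates to the ideal schedule", {
  cfg <- noiseless_config()
  tm <- generate_timing(cfg, "M4", "fast", 3, seed = 1)
  ideal <- ideal_schedule("M4", 1.0, 0.59, 3)
  got <- dplyr::semi_join(tm, ideal, by = c("limb", "cycle"))
  expect_equal(got$touchdown, ideal$touchdown, tolerance = 1e-12)
  expect_equal(got$liftoff, ideal$liftoff, tolerance = 1e-12)
  # plus the closing left-palm touchdown that completes the last cycle
  expect_equal(sum(tm$limb == "LP"), 4)
})

test_that("timing generation is reproducible and seed-sensitive", {
  cfg <- quick_config()
  a <- generate_timing(cfg, "M3", "fast", 5, seed = 11)
  b <- generate_timing(cfg, "M3", "fast", 5, seed = 11)
  c <- generate_timing(cfg, "M3", "fast", 5, seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$touchdown, c$touchdown)))
})

test_that("mean cycle duration tracks the configured speed condition", {
  cfg <- synth_config()
  tm <- generate_timing(cfg, "M2", "low", 120, seed = 3)
  lp <- tm$touchdown[tm$limb == "LP"]
  # sd 0.15 s over 120 cycles: 3 standard errors ~ 0.04 s
  expect_lt(abs(mean(diff(lp)) - 3.5), 3 * 0.15 / sqrt(120))
})

test_that("landing order within every cycle matches the mode", {
  cfg <- quick_config()
  for (m in c("M1", "M3", "M7")) {
    def <- ilcm_definition(m)
    tm <- generate_timing(cfg, m, "fast", 8, seed = 21)
    grp <- rep(seq_along(def$landing_order), lengths(def$landing_order))
    names(grp) <- unlist(def$landing_order)
    for (k in 1:8) {
      cyc <- tm[tm$cycle == k, ]
      g <- grp[cyc$limb]
      expect_true(all(diff(g[order(cyc$touchdown)]) >= 0))
    }
  }
})

test_that("ground-truth IPL stays near the ideal for every mode", {
  cfg <- quick_config()
  for (i in 1:8) {
    m <- paste0("M", i)
    ideal <- ilcm_definition(m)$ideal_ipl
    tm <- generate_timing(cfg, m, "fast", 12, seed = 30 + i)
    ipl <- compute_ipl(
      tm$touchdown[tm$limb == "LP"], tm$touchdown[tm$limb == "LK"],
      wrap = TRUE
    )
    # jitter sd 0.02 s on 1 s cycles = 2 IPL points; allow 3 sd on the mean
    expect_lt(mean(ipl_circular_distance(ipl, ideal)), 3 * 2)
  }
})

test_that("pressure is nonnegative with one plateau per stance", {
  cfg <- noiseless_config()
  tm <- generate_timing(cfg, "M2", "fast", 5, seed = 2)
  p <- generate_pressure(tm, cfg)
  expect_true(all(p >= 0))
  at_plateau <- rle(p > 0.99 * cfg$pressure_plateau)
  # 5 complete cycles plus the closing stance
  expect_equal(sum(at_plateau$values), 6)
})

test_that("noiseless pressure derivative is positive only in post-touchdown ramps", {
  cfg <- noiseless_config()
  timing <- tibble::tibble(
    limb = "LP", cycle = 1:3,
    touchdown = c(1, 3, 5), liftoff = c(2.4, 4.4, 6.4)
  )
  p <- generate_pressure(timing, cfg)
  d <- diff(p)
  pos <- which(d > 1e-9) / cfg$sample_rate
  ramp <- cfg$pressure_ramp
  expect_true(all(
    (pos >= 1 - 2e-3 & pos <= 1 + ramp + 2e-3) |
      (pos >= 3 - 2e-3 & pos <= 3 + ramp + 2e-3) |
      (pos >= 5 - 2e-3 & pos <= 5 + ramp + 2e-3)
  ))
  expect_error(
    generate_pressure(timing, synth_config(pressure_plateau = 0)),
    "plateau"
  )
})

test_that("EMG bursts sit in the assigned limb's swing phase", {
  cfg <- noiseless_config(baseline_noise = 0.01)
  tm <- generate_timing(cfg, "M2", "fast", 6, seed = 5)
  emg <- generate_emg(tm, cfg, seed = 6)
  expect_equal(nrow(emg), 30)
  # rectified + smoothed channel correlates with its programmed activation
  fs <- cfg$sample_rate
  t <- (seq_len(ncol(emg)) - 1) / fs
  lk <- tm[tm$limb == "LK", ]
  sw_start <- lk$liftoff[-nrow(lk)]
  sw_end <- lk$touchdown[-1]
  act <- rowSums(sapply(seq_along(sw_start), function(i) {
    centre <- (sw_start[i] + sw_end[i]) / 2
    sigma <- cfg$burst_width_frac * (sw_end[i] - sw_start[i])
    exp(-(t - centre)^2 / (2 * sigma^2))
  }))
  ch <- cfg$muscle_map$LK[1]
  smooth <- stats::filter(abs(emg[ch, ]), rep(1 / 201, 201), sides = 2)
  keep <- !is.na(smooth)
  expect_gt(cor(as.numeric(smooth[keep]), act[keep]), 0.8)
})

test_that("zero burst amplitude leaves only baseline noise", {
  cfg <- noiseless_config(burst_amp = 0, baseline_noise = 0.05)
  tm <- generate_timing(cfg, "M1", "fast", 3, seed = 7)
  emg <- generate_emg(tm, cfg, seed = 8)
  expect_lt(max(abs(emg)), 1)
  expect_equal(apply(emg, 1, sd), rep(0.05, 30), tolerance = 0.05)
})

test_that("modes differ in burst timing, not in marginal amplitude", {
  cfg <- noiseless_config(baseline_noise = 0.01)
  tm2 <- generate_timing(cfg, "M2", "fast", 4, seed = 9)
  tm3 <- generate_timing(cfg, "M3", "fast", 4, seed = 9)
  e2 <- generate_emg(tm2, cfg, seed = 10)
  e3 <- generate_emg(tm3, cfg, seed = 10)
  # an RP channel's burst centre shifts by about a quarter cycle between
  # M2 (RP at phase 0.5) and M3 (RP at phase 0.25)
  ch <- cfg$muscle_map$RP[1]
  centre_of <- function(x) {
    sm <- stats::filter(abs(x), rep(1 / 201, 201), sides = 2)
    which.max(ifelse(is.na(sm), -Inf, sm))
  }
  shift_s <- abs(centre_of(e2[ch, seq_len(2000)]) - centre_of(e3[ch, seq_len(2000)])) / 1000
  expect_equal(shift_s, 0.25, tolerance = 0.12)
})

test_that("cohorts enumerate the design grid reproducibly", {
  cfg <- quick_config()
  co <- generate_cohort(cfg, 2, c("M1", "M2"), c("fast", "medium"), 4, seed = 13)
  expect_equal(nrow(co), 2 * 2 * 2)
  expect_setequal(unique(co$participant_id), c("P1", "P2"))
  expect_true(all(purrr::map_int(co$trial, ~ sum(.x$timing$limb == "LP")) == 5))
  co2 <- generate_cohort(cfg, 2, c("M1", "M2"), c("fast", "medium"), 4, seed = 13)
  expect_identical(co$trial[[3]]$emg, co2$trial[[3]]$emg)
  expect_identical(co$trial[[5]]$pressure, co2$trial[[5]]$pressure)
  expect_error(generate_cohort(cfg, 0, "M1", "fast", 4, 1), "participant")
  expect_error(generate_cohort(cfg, 1, character(0), "fast", 4, 1), "nonempty")
})

test_that("participant parameters are shared across a participant's trials", {
  cfg <- quick_config()
  co <- generate_cohort(cfg, 2, c("M1", "M2"), "fast", 3, seed = 17)
  # same participant, different modes -> same gain profile; different
  # participants -> different gains (lognormal with sdlog 0.3)
  rms <- function(tr) apply(tr$emg, 1, function(x) sqrt(mean(x^2)))
  p1a <- rms(co$trial[[1]])
  p1b <- rms(co$trial[[2]])
  p2a <- rms(co$trial[[3]])
  expect_gt(cor(p1a, p1b), cor(p1a, p2a))
})
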