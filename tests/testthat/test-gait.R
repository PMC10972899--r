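test_that("the mode catalogue is well-formed", {
  cat <- ilcm_catalog()
  expect_equal(cat$mode_id, paste0("M", 1:8))
  for (i in 1:8) {
    limbs <- unlist(cat$landing_order[[i]])
    expect_setequal(limbs, c("LP", "RP", "LK", "RK"))
    expect_equal(anyDuplicated(limbs), 0L)
    expect_true("LP" %in% cat$landing_order[[i]][[1]])
    k <- length(cat$landing_order[[i]])
    expected_phases <- if (k == 2) c(0, 0.5) else c(0, 0.25, 0.5, 0.75)
    expect_setequal(unique(unname(cat$ideal_phase[[i]])), expected_phases)
    expect_equal(cat$ideal_ipl[i], unname(cat$ideal_phase[[i]]["LK"]) * 100)
  }
  expect_equal(
    cat$ideal_ipl,
    c(0, 50, 50, 75, 25, 25, 75, 50)
  )
  expect_error(ilcm_definition("M9"), "unknown")
})

test_that("ideal schedules place touchdowns at the mode's phases", {
  s2 <- ideal_schedule("M2", cycle_duration = 2, stance_fraction = 0.7, n_cycles = 1)
  td <- setNames(s2$touchdown, s2$limb)
  expect_equal(unname(td[c("LP", "RK")]), c(0, 0))
  expect_equal(unname(td[c("RP", "LK")]), c(1, 1))

  s4 <- ideal_schedule("M4", 4, 0.6, 1)
  td <- setNames(s4$touchdown, s4$limb)
  expect_equal(unname(td[c("LP", "RP", "RK", "LK")]), c(0, 1, 2, 3))

  # touchdown of each limb in cycle k is (k - 1 + phase) * duration
  s <- ideal_schedule("M5", 1.5, 0.65, 4)
  ph <- ilcm_definition("M5")$ideal_phase
  expect_equal(s$touchdown, (s$cycle - 1 + unname(ph[s$limb])) * 1.5)
  expect_equal(s$liftoff - s$touchdown, rep(0.65 * 1.5, nrow(s)))

  expect_error(ideal_schedule("M1", 2, 1.2, 1), "stance_fraction")
  expect_error(ideal_schedule("M1", 2, 0, 1), "stance_fraction")
  expect_error(ideal_schedule("M1", -1, 0.5, 1), "cycle_duration")
})

test_that("IPL is lag over cycle duration in percent", {
  expect_equal(compute_ipl(c(0, 2), 1), 50)
  expect_equal(compute_ipl(c(0, 2), 0), 0)
  expect_equal(compute_ipl(c(0, 4), 3), 75)
  # per-cycle values with varying cycle lengths
  expect_equal(compute_ipl(c(0, 2, 5), c(1, 3.5)), c(50, 50))
  expect_error(compute_ipl(0, numeric(0)), "at least 2")
  expect_error(compute_ipl(c(0, 2, 4), 1), "exactly one")
  expect_error(compute_ipl(c(2, 0), 1), "sorted")
})

test_that("IPL on every ideal schedule reproduces the catalogue value", {
  cat <- ilcm_catalog()
  for (i in 1:8) {
    for (dur in c(1.75, 2.33, 3.5)) {
      s <- ideal_schedule(cat$mode_id[i], dur, 0.7, 5)
      lp <- s$touchdown[s$limb == "LP"]
      lk <- s$touchdown[s$limb == "LK"]
      ipl <- compute_ipl(lp, lk)
      # 5 touchdowns close 4 full cycles
      expect_equal(ipl, rep(cat$ideal_ipl[i], 4), tolerance = 1e-12)
    }
  }
})

test_that("IPL is invariant to a global time shift", {
  lp <- c(0, 2.1, 4.05, 6.2)
  lk <- c(1.0, 3.2, 5.1)
  for (shift in c(-3, 0.7, 120)) {
    expect_equal(compute_ipl(lp + shift, lk + shift), compute_ipl(lp, lk))
  }
})

test_that("wrap-tolerant IPL handles knee touchdowns astride the cycle start", {
  lp <- c(0, 2, 4, 6)
  lk <- c(1.95, 4.05, 5.95) # pace-like: knee lands just before/after the palm
  expect_error(compute_ipl(lp, lk), "exactly one")
  w <- compute_ipl(lp, lk, wrap = TRUE)
  expect_true(all(w >= 0 & w < 100))
  expect_true(all(ipl_circular_distance(w, 0) <= 3))
})

test_that("duty factor follows stance/(stance+swing) and its symmetry", {
  expect_equal(duty_factor(1.437, 0.601), 1.437 / (1.437 + 0.601) * 100)
  expect_equal(round(duty_factor(1.437, 0.601), 2), 70.51)
  expect_equal(duty_factor(0.8, 0.8), 50)
  expect_equal(duty_factor(1.2, 0), 100)
  set.seed(4)
  s <- runif(20, 0.1, 3)
  w <- runif(20, 0.1, 3)
  expect_equal(duty_factor(s, w) + duty_factor(w, s), rep(100, 20))
  expect_error(duty_factor(0, 0), "both")
  expect_error(duty_factor(-1, 1), "nonnegative")
})

test_that("IPL categorization assigns nearest ideal with declared tie rule", {
  res <- categorize_ipl(c(50, 3, 98, 26, 75, 37.5, 12.5, 87.5))
  expect_equal(
    as.character(res$category),
    c(
      "trot", "pace", "pace", "no-limb-pairing", "no-limb-pairing",
      "trot", "no-limb-pairing", "pace"
    )
  )
  expect_equal(res$boundary, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(categorize_ipl(101), "\\[0, 100\\]")
  expect_error(categorize_ipl(-0.5), "\\[0, 100\\]")
})

test_that("the catalogue round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  ilcm_write_json(path)
  back <- ilcm_read_json(path)
  cat <- ilcm_catalog()
  expect_equal(back$mode_id, cat$mode_id)
  expect_equal(back$ideal_ipl, cat$ideal_ipl)
  expect_equal(back$landing_order, cat$landing_order)
  expect_equal(back$ideal_phase, cat$ideal_phase)
})
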