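test_that("confusion matrices count and conserve", {
  truth <- c("M1", "M1", "M2", "M3", "M3", "M3")
  perfect <- confusion(truth, truth, levels = paste0("M", 1:3))
  expect_equal(diag(perfect), c(M1 = 2, M2 = 1, M3 = 3))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)

  collapsed <- confusion(truth, rep("M2", 6), levels = paste0("M", 1:3))
  expect_equal(colSums(collapsed), c(M1 = 0, M2 = 6, M3 = 0))

  set.seed(31)
  t2 <- sample(paste0("M", 1:8), 40, replace = TRUE)
  p2 <- sample(paste0("M", 1:8), 40, replace = TRUE)
  cm <- confusion(t2, p2, levels = paste0("M", 1:8))
  expect_equal(sum(cm), 40)
  expect_equal(rowSums(cm), table(factor(t2, paste0("M", 1:8))) |> as.numeric() |>
    setNames(paste0("M", 1:8)))

  expect_error(confusion(c("a", "b"), "a"), "equal length")
  expect_error(confusion("M1", "M9", levels = paste0("M", 1:8)), "unknown label")
})

test_that("protocols produce the expected fold structure", {
  ds <- small_dataset()
  spec <- classifier_spec("knn")

  lopo <- run_protocol(ds, "participant_independent", spec, "fast", seed = 1)
  expect_equal(nrow(lopo$folds), 3) # one fold per participant
  expect_setequal(lopo$folds$participant_id, paste0("P", 1:3))
  expect_equal(sum(lopo$confusion), nrow(ds))

  multi <- run_protocol(ds, "multi_participant", spec, "fast", seed = 1)
  expect_equal(nrow(multi$folds), 3)
  expect_true(all(abs(multi$folds$n_test - nrow(ds) / 3) <= 4))
  expect_equal(sum(multi$folds$n_test), nrow(ds))

  ps <- run_protocol(ds, "participant_specific", spec, "fast", seed = 1)
  expect_equal(nrow(ps$folds), 9) # 3 folds x 3 participants
  within_p <- dplyr::count(ps$folds, participant_id, wt = n_test)
  expect_true(all(within_p$n == nrow(ds) / 3))

  # invariants: accuracies in range, confusion row sums = per-class counts
  for (ev in list(lopo, multi, ps)) {
    expect_true(all(ev$folds$accuracy >= 0 & ev$folds$accuracy <= 100))
    expect_equal(
      as.numeric(rowSums(ev$confusion)),
      as.numeric(table(factor(ds$mode, rownames(ev$confusion))))
    )
  }
  expect_error(run_protocol(ds, "participant_independent", spec, "low"), "no samples")
  expect_error(
    run_protocol(ds[ds$participant_id == "P1", ], "participant_independent", spec, "fast"),
    ">= 2 participants"
  )
})

test_that("tidy/glance agree with the underlying folds", {
  ds <- small_dataset()
  ev <- run_protocol(ds, "multi_participant", classifier_spec("knn"), "fast", seed = 3)
  td <- tidy(ev)
  expect_equal(nrow(td), nrow(ev$folds))
  expect_equal(td$accuracy, ev$folds$accuracy)
  gl <- glance(ev)
  expect_equal(gl$mean_fold_accuracy, mean(td$accuracy))
  expect_equal(gl$overall_accuracy, overall_accuracy(ev))
  expect_equal(gl$n_test, nrow(ds))
})

test_that("classifiers beat 8-class chance by a wide margin on synthetic data", {
  cfg <- noiseless_config()
  co <- generate_cohort(cfg, 3, paste0("M", 1:8), "fast", 9, seed = 5)
  ds <- build_dataset(co)
  for (spec in list(
    classifier_spec("knn"), classifier_spec("svm"),
    classifier_spec("bilstm",
      hidden = 32, epochs = 20, seq_points = 25,
      dense_sizes = c(64, 32, 16)
    )
  )) {
    ev <- run_protocol(ds, "participant_independent", spec, "fast", seed = 2)
    expect_gt(overall_accuracy(ev), 12.5 + 50) # chance is 12.5%
  }
})

test_that("t-SNE embedding separates modes and is reproducible", {
  ds <- small_dataset()
  emb <- embed_2d(ds, seed = 2, perplexity = 10)
  expect_equal(nrow(emb), nrow(ds))
  expect_named(emb, c("participant_id", "mode", "speed", "dim1", "dim2"))
  emb2 <- embed_2d(ds, seed = 2, perplexity = 10)
  expect_identical(emb, emb2)
  sil <- cluster::silhouette(
    as.integer(factor(ds$mode)),
    dist(cbind(emb$dim1, emb$dim2))
  )
  expect_gt(mean(sil[, 3]), 0)
  expect_error(embed_2d(ds[1:5, ]), "at least 10")
  expect_error(embed_2d(ds, perplexity = 1000), "perplexity")
})

test_that("self-selected proportions are percentages that sum to 100", {
  ds <- small_dataset()
  m <- train_classifier(classifier_spec("knn"), ds, seed = 1)
  # stand-in for self-selected cycles: one participant's cycles re-classified
  self_ds <- ds[ds$participant_id == "P1", ]
  props <- analyze_self_selected(m, self_ds)
  sums <- dplyr::summarise(dplyr::group_by(props, speed), s = sum(pct))
  expect_equal(sums$s, rep(100, nrow(sums)))
  expect_equal(sum(props$n), nrow(self_ds))
  expect_error(analyze_self_selected(m, self_ds[0, ]), "no self-selected")
  # the proportion arithmetic itself
  expect_equal(round(mode_proportion(92, 99), 1), 92.9)
  expect_equal(round(mode_proportion(23, 95), 1), 24.2)
  expect_error(mode_proportion(1, 0), "positive")
})

test_that("gait summaries recover configured stance fractions", {
  cfg <- quick_config()
  co <- generate_cohort(cfg, 2, "M2", c("low", "medium", "fast"), 8, seed = 61)
  gs <- summarize_gait(co)
  gs <- gs[match(c("low", "medium", "fast"), gs$speed), ]
  expect_equal(gs$n_cycles, rep(2 * 8, 3))
  # configured stance fractions 0.70/0.65/0.59 with sd 0.04: recovered mean
  # duty factor within 2 standard errors of the configured mean
  for (i in 1:3) {
    target <- c(70, 65, 59)[i]
    se <- 4 / sqrt(16)
    expect_lt(abs(gs$duty_mean[i] - target), 2 * se)
  }
  # monotone decrease across speeds mirrors the configuration
  expect_true(all(diff(gs$duty_mean) < 0))

  # exact arithmetic on constructed boundaries: 1.4 s / 0.6 s -> 70%
  b <- make_boundaries(stance = c(1001, 3001), swing = 2401)
  d <- phase_durations(b)
  expect_equal(duty_factor(d$stance_s, d$swing_s), 70)
})

test_that("identical-cycle trials give (near) zero dispersion", {
  cfg <- noiseless_config()
  co <- generate_cohort(cfg, 1, "M2", "fast", 6, seed = 62)
  gs <- summarize_gait(co)
  expect_lt(gs$duty_sd, 0.2) # quantized only by the sampling grid
  expect_lt(gs$stance_sd, 0.005)
})
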