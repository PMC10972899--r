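#' Run a pattern-recognition protocol over an envelope dataset
#'
#' Three evaluation protocols probe increasingly hard generalization:
#' * `participant_specific` -- stratified 3-fold cross-validation within each
#'   participant; fold accuracies are reported per participant and the
#'   headline figure is their average.
#' * `multi_participant` -- stratified (by class and participant) 3-fold
#'   cross-validation over the pooled cohort.
#' * `participant_independent` -- leave-one-participant-out: train on all
#'   other participants, test on the held-out one.
#'
#' The `speed` argument restricts the dataset to one speed condition;
#' `"mixed"` pools low, medium and fast cycles.
#'
#' @param dataset Feature tibble from [build_dataset()].
#' @param protocol One of the three protocol names above.
#' @param spec A [classifier_spec()].
#' @param speed `"low"`, `"medium"`, `"fast"` or `"mixed"`.
#' @param seed Integer seed controlling fold assignment and model training.
#' @return An object of class `crawl_eval`: protocol/classifier/speed
#'   identifiers, a `folds` tibble (`fold`, `participant_id`, `n_test`,
#'   `accuracy` in percent) and the pooled `confusion` count matrix
#'   (rows = true class).
#' @export
run_protocol <- function(dataset,
                         protocol = c(
                           "participant_specific", "multi_participant",
                           "participant_independent"
                         ),
                         spec, speed = "mixed", seed = 1) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(spec, "classifier_spec"))
  if (speed != "mixed") dataset <- dplyr::filter(dataset, .data$speed == !!speed)
  if (nrow(dataset) == 0) stop("no samples for speed condition ", speed, call. = FALSE)
  levels_all <- sort(unique(dataset$mode))
  participants <- sort(unique(dataset$participant_id))

  run_split <- function(train_idx, test_idx, fold_seed) {
    model <- train_classifier(spec, dataset[train_idx, ], seed = fold_seed)
    pred <- predict(model, dataset[test_idx, ])
    truth <- factor(dataset$mode[test_idx], levels = object_levels(pred, levels_all))
    list(
      accuracy = mean(as.character(pred) == as.character(truth)) * 100,
      confusion = confusion(dataset$mode[test_idx], pred, levels = levels_all),
      n_test = length(test_idx)
    )
  }

  folds <- list()
  conf <- matrix(0L, length(levels_all), length(levels_all),
    dimnames = list(levels_all, levels_all)
  )
  if (protocol == "participant_independent") {
    if (length(participants) < 2) stop("participant-independent protocol needs >= 2 participants", call. = FALSE)
    for (i in seq_along(participants)) {
      p <- participants[i]
      res <- run_split(
        which(dataset$participant_id != p),
        which(dataset$participant_id == p),
        derive_seed(seed, i)
      )
      conf <- conf + res$confusion
      folds[[i]] <- tibble::tibble(
        fold = i, participant_id = p, n_test = res$n_test, accuracy = res$accuracy
      )
    }
  } else if (protocol == "multi_participant") {
    fold_of <- assign_folds(paste(dataset$mode, dataset$participant_id), 3, seed)
    for (k in 1:3) {
      res <- run_split(which(fold_of != k), which(fold_of == k), derive_seed(seed, k))
      conf <- conf + res$confusion
      folds[[k]] <- tibble::tibble(
        fold = k, participant_id = NA_character_, n_test = res$n_test,
        accuracy = res$accuracy
      )
    }
  } else {
    fi <- 0
    for (p in participants) {
      pidx <- which(dataset$participant_id == p)
      if (min(table(dataset$mode[pidx])) < 3) {
        stop("participant-specific protocol needs >= 3 samples per class", call. = FALSE)
      }
      fold_of <- assign_folds(dataset$mode[pidx], 3, derive_seed(seed, match(p, participants)))
      for (k in 1:3) {
        fi <- fi + 1
        res <- run_split(
          pidx[fold_of != k], pidx[fold_of == k],
          derive_seed(seed, match(p, participants), k)
        )
        conf <- conf + res$confusion
        folds[[fi]] <- tibble::tibble(
          fold = k, participant_id = p, n_test = res$n_test, accuracy = res$accuracy
        )
      }
    }
  }
  structure(
    list(
      protocol = protocol, classifier = spec$kind, speed = speed, seed = seed,
      folds = dplyr::bind_rows(folds), confusion = conf
    ),
    class = "crawl_eval"
  )
}

object_levels <- function(pred, fallback) {
  lv <- levels(pred)
  if (is.null(lv)) fallback else union(lv, fallback)
}

# Stratified fold assignment: within each stratum, fold labels 1..k are
# dealt out as evenly as possible in shuffled order.
assign_folds <- function(strata, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(strata))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    fold
  })
}

#' Confusion matrix of true vs predicted labels
#'
#' Entry (i, j) counts samples of true class i predicted as class j; the
#' total of all entries equals the number of samples.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param levels Class levels ordering the rows/columns; defaults to the
#'   sorted union of both label sets.
#' @return An integer count matrix with true classes in rows.
#' @export
confusion <- function(true_labels, predicted_labels, levels = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- sort(union(as.character(true_labels), as.character(predicted_labels)))
  }
  bad <- setdiff(
    union(as.character(true_labels), as.character(predicted_labels)), levels
  )
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  tab <- table(
    factor(as.character(true_labels), levels = levels),
    factor(as.character(predicted_labels), levels = levels)
  )
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = unname(dimnames(tab)))
}

#' Overall accuracy of an evaluation result
#'
#' Ratio of correctly identified samples to the total, in percent, computed
#' from the pooled confusion matrix.
#'
#' @param result A `crawl_eval`.
#' @return Scalar accuracy in `[0, 100]`.
#' @export
overall_accuracy <- function(result) {
  sum(diag(result$confusion)) / sum(result$confusion) * 100
}

#' @export
print.crawl_eval <- function(x, ...) {
  cat(sprintf(
    "<crawl_eval %s / %s / %s speed: %d folds, mean fold accuracy %.2f%%, overall %.2f%%>\n",
    x$protocol, x$classifier, x$speed, nrow(x$folds),
    mean(x$folds$accuracy), overall_accuracy(x)
  ))
  invisible(x)
}

#' 2-D t-SNE embedding of an envelope dataset
#'
#' Projects the flattened envelope samples to two dimensions for
#' visualization of mode separability. Stochastic; reproducible given the
#' seed.
#'
#' @param dataset Feature tibble from [build_dataset()] (>= 10 samples).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; capped below `(n - 1) / 3`.
#' @param rep_points Per-channel decimation before embedding.
#' @return The dataset's label columns plus `dim1`, `dim2`.
#' @export
embed_2d <- function(dataset, seed = 1, perplexity = 30, rep_points = 100) {
  n <- nrow(dataset)
  if (n < 10) stop("need at least 10 samples to embed", call. = FALSE)
  if (perplexity >= (n - 1) / 3) {
    stop("perplexity too large for ", n, " samples", call. = FALSE)
  }
  M <- dataset_matrix(dataset, rep_points)
  emb <- with_local_seed(seed, {
    Rtsne::Rtsne(M, dims = 2, perplexity = perplexity, check_duplicates = FALSE)
  })
  dplyr::bind_cols(
    dataset[, intersect(c("participant_id", "mode", "speed"), names(dataset))],
    tibble::tibble(dim1 = emb$Y[, 1], dim2 = emb$Y[, 2])
  )
}

#' Proportion of cycles assigned to a mode
#'
#' @param count Cycles assigned to the mode.
#' @param total Total cycles in the condition.
#' @return Percentage `count / total * 100`.
#' @export
mode_proportion <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  count / total * 100
}

#' Classify self-selected crawling cycles and tabulate mode proportions
#'
#' Applies a classifier trained on the eight defined modes to cycles
#' recorded under a self-selected coordination mode and reports, per speed,
#' how many cycles are assigned to each mode and the corresponding
#' percentage (summing to 100 within a speed).
#'
#' @param model A `crawl_model` trained on M1..M8.
#' @param self_cycles Feature tibble of self-selected cycles (with a `speed`
#'   column).
#' @return A tibble with columns `speed`, `mode`, `n`, `pct`.
#' @export
analyze_self_selected <- function(model, self_cycles) {
  if (nrow(self_cycles) == 0) stop("no self-selected cycles", call. = FALSE)
  pred <- predict(model, self_cycles)
  tibble::tibble(speed = self_cycles$speed, mode = pred) |>
    dplyr::count(.data$speed, .data$mode, .drop = FALSE) |>
    dplyr::group_by(.data$speed) |>
    dplyr::mutate(pct = mode_proportion(.data$n, sum(.data$n))) |>
    dplyr::ungroup()
}

#' Per-speed stance/swing/duty-factor statistics of a cohort
#'
#' Segments each trial's pressure signal, computes per-cycle stance and
#' swing durations and duty factors, and aggregates them per speed condition
#' as mean and standard deviation.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param boundaries Optional list of precomputed `cycle_boundaries`.
#' @param ... Passed to [detect_cycles()].
#' @return A tibble with one row per speed: cycle count, mean/sd of stance
#'   duration (s), swing duration (s) and duty factor (percent).
#' @export
summarize_gait <- function(cohort, boundaries = NULL, ...) {
  per_cycle <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    trial <- cohort$trial[[i]]
    b <- if (is.null(boundaries)) {
      detect_cycles(trial$pressure, trial$sample_rate, ...)
    } else {
      boundaries[[i]]
    }
    dur <- phase_durations(b)
    tibble::tibble(
      speed = trial$speed,
      stance_s = dur$stance_s,
      swing_s = dur$swing_s,
      duty = duty_factor(dur$stance_s, dur$swing_s)
    )
  })
  if (nrow(per_cycle) == 0) stop("no cycles found in cohort", call. = FALSE)
  per_cycle |>
    dplyr::group_by(.data$speed) |>
    dplyr::summarise(
      n_cycles = dplyr::n(),
      stance_mean = mean(.data$stance_s), stance_sd = stats::sd(.data$stance_s),
      swing_mean = mean(.data$swing_s), swing_sd = stats::sd(.data$swing_s),
      duty_mean = mean(.data$duty), duty_sd = stats::sd(.data$duty),
      .groups = "drop"
    )
}
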