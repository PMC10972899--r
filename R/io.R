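#' Write / read one crawling trial
#'
#' Two on-disk layouts are supported and round-trip losslessly:
#' * **HDF5** (`.h5`): datasets `emg` (30 x T) and `pressure` (T), with
#'   root attributes `sample_rate`, `participant`, `speed`, `mode`.
#' * **CSV** (`.csv`): T rows x 31 columns (`pressure`, `ch01`..`ch30`),
#'   comma-separated with a header row, plus a JSON metadata sidecar at
#'   `<path>.json`.
#'
#' The format is chosen from the file extension.
#'
#' @param trial A `crawl_trial` (ground-truth timing is generator metadata
#'   and is not persisted).
#' @param path Output/input file path ending in `.h5` or `.csv`.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns a
#'   `crawl_trial` (without `timing`).
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "crawl_trial"))
  if (nrow(trial$emg) != 30) stop("trial must have exactly 30 EMG channels", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "h5") {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(trial$emg, path, "emg")
    rhdf5::h5write(trial$pressure, path, "pressure")
    fid <- rhdf5::H5Fopen(path)
    on.exit(rhdf5::H5Fclose(fid))
    rhdf5::h5writeAttribute(trial$sample_rate, fid, "sample_rate")
    rhdf5::h5writeAttribute(trial$participant_id, fid, "participant")
    rhdf5::h5writeAttribute(trial$speed, fid, "speed")
    rhdf5::h5writeAttribute(trial$mode, fid, "mode")
  } else if (ext == "csv") {
    df <- tibble::as_tibble(t(trial$emg), .name_repair = ~ sprintf("ch%02d", 1:30))
    df <- dplyr::bind_cols(tibble::tibble(pressure = trial$pressure), df)
    readr::write_csv(df, path)
    jsonlite::write_json(
      list(
        sample_rate = trial$sample_rate, participant = trial$participant_id,
        speed = trial$speed, mode = trial$mode
      ),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  } else {
    stop("unsupported trial format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "h5") {
    emg <- rhdf5::h5read(path, "emg")
    pressure <- as.numeric(rhdf5::h5read(path, "pressure"))
    meta <- rhdf5::h5readAttributes(path, "/")
    if (is.null(meta$sample_rate)) stop("missing sample_rate attribute", call. = FALSE)
    out <- list(
      emg = emg, pressure = pressure,
      sample_rate = as.numeric(meta$sample_rate),
      participant_id = as.character(meta$participant),
      speed = as.character(meta$speed), mode = as.character(meta$mode)
    )
  } else if (ext == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    meta <- jsonlite::read_json(paste0(path, ".json"))
    if (is.null(meta$sample_rate)) stop("missing sample_rate attribute", call. = FALSE)
    out <- list(
      emg = t(as.matrix(df[, -1])), pressure = df$pressure,
      sample_rate = as.numeric(meta$sample_rate),
      participant_id = as.character(meta$participant),
      speed = as.character(meta$speed), mode = as.character(meta$mode)
    )
    dimnames(out$emg) <- NULL
  } else {
    stop("unsupported trial format: .", ext, call. = FALSE)
  }
  if (nrow(out$emg) != 30) {
    stop("malformed trial file: expected 30 channels, found ", nrow(out$emg), call. = FALSE)
  }
  if (length(out$pressure) != ncol(out$emg)) {
    stop("malformed trial file: pressure and EMG lengths differ", call. = FALSE)
  }
  structure(out, class = "crawl_trial")
}

#' Export a cohort to disk with a manifest
#'
#' Writes one trial file per cohort row plus `manifest.csv` enumerating
#' exactly the files written (path, participant, speed, mode, cycle count).
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"h5"` or `"csv"`.
#' @return The manifest tibble, invisibly; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
export_cohort <- function(cohort, dir, format = c("h5", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(cohort$trial, function(tr) {
    p <- file.path(dir, sprintf("%s_%s_%s.%s", tr$participant_id, tr$mode, tr$speed, format))
    write_trial(tr, p)
    p
  })
  manifest <- tibble::tibble(
    path = paths,
    participant_id = cohort$participant_id,
    speed = cohort$speed,
    mode = cohort$mode,
    n_cycles = cohort$n_cycles
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path Path to a `manifest.csv` written by [export_cohort()].
#' @return The manifest tibble; errors if any listed trial file is missing.
#' @export
read_manifest <- function(path) {
  manifest <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing) > 0) {
    stop("manifest lists missing files: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  manifest
}

#' Write / read an envelope feature dataset (HDF5)
#'
#' Layout: 3-D dataset `features` (samples x time points x 30 channels) plus
#' string datasets `mode`, `participant`, `speed` and integer datasets
#' `trial_row`, `cycle`; lossless at stored precision, labels preserved in
#' order. An empty dataset round-trips to a valid empty container.
#'
#' @param dataset Feature tibble from [build_dataset()].
#' @param path `.h5` file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature tibble.
#' @export
write_features <- function(dataset, path) {
  n <- nrow(dataset)
  if (n > 0) {
    shapes <- purrr::map(dataset$envelope, dim)
    ref <- shapes[[1]]
    if (ref[2] != 30 || !all(purrr::map_lgl(shapes, ~ identical(.x, ref)))) {
      stop("every sample must be an n_points x 30 matrix", call. = FALSE)
    }
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  if (n > 0) {
    arr <- array(0, dim = c(n, dim(dataset$envelope[[1]])))
    for (i in seq_len(n)) arr[i, , ] <- dataset$envelope[[i]]
    rhdf5::h5write(arr, path, "features")
  }
  rhdf5::h5write(as.character(dataset$mode), path, "mode")
  rhdf5::h5write(as.character(dataset$participant_id), path, "participant")
  rhdf5::h5write(as.character(dataset$speed), path, "speed")
  rhdf5::h5write(as.integer(dataset$trial_row), path, "trial_row")
  rhdf5::h5write(as.integer(dataset$cycle), path, "cycle")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  ls <- rhdf5::h5ls(path)$name
  mode <- as.character(rhdf5::h5read(path, "mode"))
  n <- length(mode)
  env <- if ("features" %in% ls) {
    arr <- rhdf5::h5read(path, "features")
    purrr::map(seq_len(n), ~ arr[.x, , ])
  } else {
    list()
  }
  tibble::tibble(
    participant_id = as.character(rhdf5::h5read(path, "participant")),
    mode = mode,
    speed = as.character(rhdf5::h5read(path, "speed")),
    trial_row = as.integer(rhdf5::h5read(path, "trial_row")),
    cycle = as.integer(rhdf5::h5read(path, "cycle")),
    envelope = env
  )
}

#' Persist an evaluation result
#'
#' Per-fold accuracies and metadata go to JSON; the pooled confusion matrix
#' goes to CSV with one row per true class.
#'
#' @param result A `crawl_eval` from [run_protocol()].
#' @param dir Output directory.
#' @param stem File-name stem; files are `<stem>.json` and
#'   `<stem>_confusion.csv`.
#' @return Invisible character vector of the two paths.
#' @export
write_eval_result <- function(result, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, paste0(stem, ".json"))
  cp <- file.path(dir, paste0(stem, "_confusion.csv"))
  jsonlite::write_json(
    list(
      protocol = result$protocol, classifier = result$classifier,
      speed = result$speed, seed = result$seed,
      overall_accuracy = overall_accuracy(result),
      folds = result$folds
    ),
    jp,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  cm <- as.data.frame(result$confusion)
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(true = rownames(result$confusion)), cm), cp
  )
  invisible(c(jp, cp))
}
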