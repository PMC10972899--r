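#' Specify a crawling-mode classifier
#'
#' Three classifier families operate on the normalized envelope cycles:
#' * `bilstm` -- the bidirectional LSTM of [train_bilstm()], consuming each
#'   cycle as a sequence (the 1000-point envelope is subsampled to
#'   `seq_points` time steps of 30 channels). Defaults are the reference
#'   recipe: 128 hidden units, learning rate 0.001, beta1 0.9, beta2 0.999,
#'   epsilon 1e-8, 60 epochs, batch size one-tenth of the training samples.
#' * `svm` -- radial-basis support vector machine (`e1071::svm`, cost 1,
#'   one-vs-rest pairwise voting) on each channel's envelope decimated to
#'   `rep_points` points and flattened.
#' * `knn` -- k-nearest neighbours (`class::knn`, Euclidean, `k = 5`) on the
#'   same flattened representation.
#'
#' @param classifier One of `"bilstm"`, `"svm"`, `"knn"`.
#' @param ... Overrides of the defaults listed above (`hidden`,
#'   `dense_sizes`, `lr`, `beta1`, `beta2`, `eps`, `epochs`, `batch_size`,
#'   `seq_points` for bilstm; `cost`, `kernel`, `rep_points` for svm; `k`,
#'   `rep_points` for knn).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(classifier = c("bilstm", "svm", "knn"), ...) {
  kind <- match.arg(classifier)
  defaults <- switch(kind,
    bilstm = list(
      hidden = 128, dense_sizes = c(256, 128, 64), lr = 0.001,
      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, epochs = 60,
      batch_size = NULL, seq_points = 50
    ),
    svm = list(kernel = "radial", cost = 1, rep_points = 100),
    knn = list(k = 5, rep_points = 100)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop("unknown ", kind, " hyperparameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(c(list(kind = kind), defaults), class = "classifier_spec")
}

# 1000 x 30 envelope -> seq_points x 30 subsampled sequence
envelope_sequence <- function(env, seq_points) {
  env[round(seq(1, nrow(env), length.out = seq_points)), , drop = FALSE]
}

# 1000 x 30 envelope -> flattened rep_points * 30 vector
envelope_vector <- function(env, rep_points) {
  as.numeric(env[round(seq(1, nrow(env), length.out = rep_points)), , drop = FALSE])
}

dataset_array <- function(dataset, seq_points) {
  seqs <- purrr::map(dataset$envelope, envelope_sequence, seq_points = seq_points)
  d <- dim(seqs[[1]])
  X <- array(0, dim = c(length(seqs), d[1], d[2]))
  for (i in seq_along(seqs)) X[i, , ] <- seqs[[i]]
  X
}

dataset_matrix <- function(dataset, rep_points) {
  do.call(rbind, purrr::map(dataset$envelope, envelope_vector, rep_points = rep_points))
}

#' Train a classifier on an envelope dataset
#'
#' @param spec A [classifier_spec()].
#' @param train_set Feature tibble from [build_dataset()] (needs `mode` and
#'   `envelope` columns); at least two classes.
#' @param seed Integer seed (controls BiLSTM initialization/shuffling; SVM
#'   and KNN are deterministic given the data).
#' @return A list of class `crawl_model` carrying the fitted object, the
#'   spec, the class levels and training metadata.
#' @export
train_classifier <- function(spec, train_set, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (nrow(train_set) == 0) stop("empty training set", call. = FALSE)
  y <- factor(train_set$mode)
  if (nlevels(y) < 2) stop("training set must contain at least 2 classes", call. = FALSE)
  fit <- switch(spec$kind,
    bilstm = {
      X <- dataset_array(train_set, spec$seq_points)
      train_bilstm(X, y,
        hidden = spec$hidden, dense_sizes = spec$dense_sizes,
        lr = spec$lr, beta1 = spec$beta1, beta2 = spec$beta2, eps = spec$eps,
        epochs = spec$epochs, batch_size = spec$batch_size, seed = seed
      )
    },
    svm = {
      M <- dataset_matrix(train_set, spec$rep_points)
      with_local_seed(seed, e1071::svm(M, y, kernel = spec$kernel, cost = spec$cost, scale = FALSE))
    },
    knn = {
      M <- dataset_matrix(train_set, spec$rep_points)
      list(train_x = M, train_y = y, k = spec$k)
    }
  )
  model <- structure(
    list(spec = spec, kind = spec$kind, fit = fit, levels = levels(y), seed = seed),
    class = "crawl_model"
  )
  model$train_accuracy <- mean(predict(model, train_set) == y) * 100
  model
}

#' Predict crawling modes for envelope samples
#'
#' @param object A `crawl_model` from [train_classifier()].
#' @param newdata Feature tibble from [build_dataset()], or a list of
#'   envelope matrices.
#' @param ... Unused.
#' @return Factor of predicted mode labels (empty input gives an empty
#'   factor).
#' @export
predict.crawl_model <- function(object, newdata, ...) {
  env <- if (is.data.frame(newdata)) newdata$envelope else newdata
  if (length(env) == 0) {
    return(factor(character(0), levels = object$levels))
  }
  dataset <- tibble::tibble(envelope = env)
  out <- switch(object$kind,
    bilstm = {
      X <- dataset_array(dataset, object$spec$seq_points)
      probs <- bilstm_batch_forward(object$fit$theta, X)$probs
      object$fit$levels[max.col(probs)]
    },
    svm = {
      M <- dataset_matrix(dataset, object$spec$rep_points)
      as.character(stats::predict(object$fit, M))
    },
    knn = {
      M <- dataset_matrix(dataset, object$spec$rep_points)
      as.character(class::knn(object$fit$train_x, M, object$fit$train_y, k = object$fit$k))
    }
  )
  factor(out, levels = object$levels)
}

#' @export
print.crawl_model <- function(x, ...) {
  cat(sprintf(
    "<crawl_model %s: %d classes, train accuracy %.1f%%>\n",
    x$kind, length(x$levels), x$train_accuracy
  ))
  invisible(x)
}
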