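#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation result
#'
#' One row per cross-validation fold with its accuracy.
#'
#' @param x A `crawl_eval` from [run_protocol()].
#' @param ... Unused.
#' @return A tibble with `protocol`, `classifier`, `speed`, `fold`,
#'   `participant_id`, `n_test`, `accuracy`.
#' @method tidy crawl_eval
#' @export
tidy.crawl_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      protocol = x$protocol, classifier = x$classifier, speed = x$speed
    )[rep(1, nrow(x$folds)), ],
    x$folds
  )
}

#' One-row summary of an evaluation result
#'
#' @param x A `crawl_eval` from [run_protocol()].
#' @param ... Unused.
#' @return A tibble with the protocol identifiers, number of folds, mean and
#'   sd of fold accuracies, overall (pooled) accuracy and total test count.
#' @method glance crawl_eval
#' @export
glance.crawl_eval <- function(x, ...) {
  tibble::tibble(
    protocol = x$protocol,
    classifier = x$classifier,
    speed = x$speed,
    n_folds = nrow(x$folds),
    mean_fold_accuracy = mean(x$folds$accuracy),
    sd_fold_accuracy = stats::sd(x$folds$accuracy),
    overall_accuracy = overall_accuracy(x),
    n_test = sum(x$confusion)
  )
}

#' Tidy a trained classifier
#'
#' @param x A `crawl_model` from [train_classifier()].
#' @param ... Unused.
#' @return A one-row tibble with the classifier kind, class count and
#'   training accuracy.
#' @method glance crawl_model
#' @export
glance.crawl_model <- function(x, ...) {
  tibble::tibble(
    classifier = x$kind,
    n_classes = length(x$levels),
    train_accuracy = x$train_accuracy
  )
}
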