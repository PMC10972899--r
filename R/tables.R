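#' Cycle-count bookkeeping of the reference recordings
#'
#' The synthetic generator emulates a 10-participant hands-knees crawling
#' study; this table carries that study's published per-participant crawling
#' cycle counts, for the eight defined coordination modes pooled (`"M1-M8"`)
#' and for the self-selected mode (`"self"`), at each speed. These counts
#' are inputs for bookkeeping checks (e.g. the total number of defined-mode
#' cycles, or per-speed self-selected totals), not outputs of this package.
#'
#' @return A tibble with columns `block` (`"M1-M8"` or `"self"`), `speed`,
#'   `participant_id`, `n_cycles`.
#' @export
reference_cycle_counts <- function() {
  p <- paste0("P", 1:10)
  counts <- list(
    c("M1-M8", "low", 95, 66, 85, 93, 81, 92, 86, 88, 104, 109),
    c("M1-M8", "medium", 105, 77, 90, 96, 85, 95, 98, 90, 91, 109),
    c("M1-M8", "fast", 102, 63, 96, 97, 85, 86, 91, 82, 87, 112),
    c("self", "low", 10, 9, 8, 9, 8, 10, 9, 10, 10, 11),
    c("self", "medium", 11, 11, 10, 10, 8, 9, 9, 10, 11, 10),
    c("self", "fast", 10, 8, 10, 9, 10, 9, 9, 10, 10, 10)
  )
  purrr::map_dfr(counts, function(row) {
    tibble::tibble(
      block = row[1], speed = row[2], participant_id = p,
      n_cycles = as.integer(row[-(1:2)])
    )
  })
}

#' Reference classification counts of self-selected crawling cycles
#'
#' Published per-speed counts of self-selected cycles assigned to the trot
#' mode M2 and the diagonal-sequence mode M3 by the reference analysis
#' (KNN trained multi-participant at mixed speed), together with the total
#' number of self-selected cycles at each speed. Inputs for proportion
#' checks such as the share of trot at medium speed.
#'
#' @return A tibble with columns `speed`, `mode`, `n`, `total`.
#' @export
reference_self_selected_counts <- function() {
  totals <- c(low = 94L, medium = 99L, fast = 95L)
  tibble::tibble(
    speed = rep(c("low", "medium", "fast"), each = 2),
    mode = rep(c("M2", "M3"), 3),
    n = c(87L, 9L, 92L, 0L, 68L, 23L),
    total = totals[rep(c("low", "medium", "fast"), each = 2)]
  )
}
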