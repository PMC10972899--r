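#' The eight inter-limb coordination modes (ILCMs)
#'
#' A crawling cycle runs from one left-palm touchdown to the next. An ILCM is
#' defined by the order in which the four limbs -- left palm (LP), right palm
#' (RP), left knee (LK), right knee (RK) -- touch the ground within a cycle;
#' limbs in the same event group land simultaneously. Every mode starts with
#' an event group containing LP. The ideal ipsilateral phase lag (IPL) of a
#' mode is the left-knee touchdown phase expressed in percent of the cycle,
#' with 0 and 100 equivalent.
#'
#' Two-group modes place their groups at phases {0, 0.5}; four-group modes at
#' {0, 0.25, 0.5, 0.75} (uniform spacing, which is what the ideal IPL values
#' of the catalogue imply).
#'
#' @return A tibble with one row per mode: `mode_id`, `landing_order` (list
#'   column; each element a list of character vectors of limb codes),
#'   `ideal_phase` (list column; named numeric, phase in `[0, 1)` per limb),
#'   and `ideal_ipl` (percent, in `[0, 100)`).
#' @examples
#' ilcm_catalog()
#' @export
ilcm_catalog <- function() {
  orders <- list(
    M1 = list(c("LP", "LK"), c("RP", "RK")),
    M2 = list(c("LP", "RK"), c("RP", "LK")),
    M3 = list("LP", "RP", "LK", "RK"),
    M4 = list("LP", "RP", "RK", "LK"),
    M5 = list("LP", "LK", "RP", "RK"),
    M6 = list("LP", "LK", "RK", "RP"),
    M7 = list("LP", "RK", "RP", "LK"),
    M8 = list("LP", "RK", "LK", "RP")
  )
  phases <- purrr::map(orders, function(groups) {
    k <- length(groups)
    ph <- rep(seq(0, 1, length.out = k + 1)[seq_len(k)], lengths(groups))
    stats::setNames(ph, unlist(groups))
  })
  tibble::tibble(
    mode_id = names(orders),
    landing_order = unname(orders),
    ideal_phase = unname(phases),
    ideal_ipl = unname(purrr::map_dbl(phases, ~ .x[["LK"]] * 100))
  )
}

ilcm_limbs <- c("LP", "RP", "LK", "RK")

#' Look up one ILCM definition
#'
#' @param mode_id Mode identifier, one of `"M1"` to `"M8"`.
#' @return A list of class `ilcm_definition` with elements `mode_id`,
#'   `landing_order`, `ideal_phase`, `ideal_ipl`.
#' @export
ilcm_definition <- function(mode_id) {
  cat <- ilcm_catalog()
  i <- match(mode_id, cat$mode_id)
  if (is.na(i)) {
    stop("unknown ILCM mode id: ", mode_id, " (expected M1..M8)", call. = FALSE)
  }
  structure(
    list(
      mode_id = cat$mode_id[[i]],
      landing_order = cat$landing_order[[i]],
      ideal_phase = cat$ideal_phase[[i]],
      ideal_ipl = cat$ideal_ipl[[i]]
    ),
    class = "ilcm_definition"
  )
}

#' @export
print.ilcm_definition <- function(x, ...) {
  groups <- vapply(x$landing_order, paste, "", collapse = "+")
  cat(sprintf(
    "<ILCM %s>  %s  (ideal IPL %g%%)\n",
    x$mode_id, paste(groups, collapse = " -> "), x$ideal_ipl
  ))
  invisible(x)
}

as_ilcm <- function(mode) {
  if (inherits(mode, "ilcm_definition")) mode else ilcm_definition(mode)
}

#' Ideal limb-timing schedule for an ILCM
#'
#' Lays out `n_cycles` identical crawling cycles in which each limb touches
#' down at its ideal phase and stays in stance for `stance_fraction` of the
#' cycle.
#'
#' @param mode An `ilcm_definition` or a mode id string.
#' @param cycle_duration Cycle duration in seconds (> 0).
#' @param stance_fraction Fraction of the cycle each limb spends in stance,
#'   strictly in (0, 1).
#' @param n_cycles Number of cycles (>= 1).
#' @return A tibble (one row per touchdown/liftoff pair) with columns
#'   `limb`, `cycle` (1-based), `touchdown`, `liftoff` (seconds).
#' @examples
#' ideal_schedule("M2", cycle_duration = 2, stance_fraction = 0.7, n_cycles = 3)
#' @export
ideal_schedule <- function(mode, cycle_duration, stance_fraction, n_cycles = 1) {
  mode <- as_ilcm(mode)
  stopifnot(is.numeric(cycle_duration), length(cycle_duration) == 1)
  if (!(cycle_duration > 0)) stop("cycle_duration must be > 0", call. = FALSE)
  if (!(stance_fraction > 0 && stance_fraction < 1)) {
    stop("stance_fraction must be strictly inside (0, 1)", call. = FALSE)
  }
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  grid <- tidyr::expand_grid(
    cycle = seq_len(n_cycles),
    limb = names(mode$ideal_phase)
  )
  td <- (grid$cycle - 1 + mode$ideal_phase[grid$limb]) * cycle_duration
  tibble::tibble(
    limb = grid$limb,
    cycle = grid$cycle,
    touchdown = unname(td),
    liftoff = unname(td) + stance_fraction * cycle_duration
  ) |>
    dplyr::arrange(.data$touchdown, .data$limb)
}

#' Ipsilateral phase lag (IPL) per crawling cycle
#'
#' The IPL of a cycle is `(b / a) * 100` percent, where `a` is the interval
#' between two consecutive left-palm touchdowns and `b` is the lag from the
#' left-palm touchdown to the left-knee touchdown within that cycle. Values
#' near 0/100 indicate pace gait, near 50 trot gait, near 25 or 75
#' no-limb-pairing gait.
#'
#' With `wrap = FALSE` (the default, the strict contract) every cycle must
#' contain exactly one left-knee touchdown in `[lp_k, lp_(k+1))`. With
#' `wrap = TRUE` each left-knee touchdown falling anywhere inside the spanned
#' interval is assigned to its containing cycle and one IPL value is returned
#' per left-knee event; this is the robust variant for jittered pace-like
#' data where the knee may land marginally before the palm.
#'
#' @param lp_touchdowns Increasing left-palm touchdown times (>= 2).
#' @param lk_touchdowns Increasing left-knee touchdown times.
#' @param wrap Use the wrap-tolerant assignment described above.
#' @return Numeric vector of per-cycle IPL values in `[0, 100)`.
#' @examples
#' compute_ipl(c(0, 2, 4), c(1, 3)) # trot-like: 50 50
#' @export
compute_ipl <- function(lp_touchdowns, lk_touchdowns, wrap = FALSE) {
  lp <- as.numeric(lp_touchdowns)
  lk <- as.numeric(lk_touchdowns)
  if (length(lp) < 2) stop("need at least 2 left-palm touchdowns", call. = FALSE)
  if (is.unsorted(lp, strictly = TRUE) || is.unsorted(lk, strictly = FALSE)) {
    stop("touchdown times must be sorted increasing", call. = FALSE)
  }
  a <- diff(lp)
  idx <- findInterval(lk, lp, rightmost.closed = FALSE)
  inside <- idx >= 1 & idx <= length(a)
  if (wrap) {
    lk_in <- lk[inside]
    k <- idx[inside]
    return((lk_in - lp[k]) / a[k] * 100)
  }
  counts <- tabulate(idx[inside], nbins = length(a))
  if (any(counts != 1)) {
    stop(
      "each crawling cycle must contain exactly one left-knee touchdown ",
      "(use wrap = TRUE for jittered pace-like data)",
      call. = FALSE
    )
  }
  lk_in <- lk[inside]
  ord <- order(idx[inside])
  b <- lk_in[ord] - lp[seq_along(a)]
  b / a * 100
}

#' Circular mean distance of IPL values from an ideal value
#'
#' IPL lives on a circle where 0 and 100 coincide; the distance between two
#' values is therefore `min(d, 100 - d)` with `d = |x - y| mod 100`.
#'
#' @param ipl Observed IPL values (percent).
#' @param ideal Ideal IPL (percent).
#' @return Numeric vector of circular distances in `[0, 50]`.
#' @export
ipl_circular_distance <- function(ipl, ideal) {
  d <- abs(ipl - ideal) %% 100
  pmin(d, 100 - d)
}

#' Duty factor of the stance phase
#'
#' `stance / (stance + swing) * 100` percent.
#'
#' @param stance_duration Stance durations in seconds (>= 0).
#' @param swing_duration Swing durations in seconds (>= 0).
#' @return Duty factors in percent, same length as the inputs.
#' @examples
#' duty_factor(1.4, 0.6) # 70
#' @export
duty_factor <- function(stance_duration, swing_duration) {
  if (any(stance_duration < 0) || any(swing_duration < 0)) {
    stop("durations must be nonnegative", call. = FALSE)
  }
  tot <- stance_duration + swing_duration
  if (any(tot == 0)) stop("stance and swing cannot both be zero", call. = FALSE)
  stance_duration / tot * 100
}

#' Categorize IPL values into the three classical gaits
#'
#' Assigns each IPL to the nearest ideal value among 0, 25, 50, 75, 100
#' (with 100 equivalent to 0): 0/100 is pace, 50 is trot, 25/75 is
#' no-limb-pairing. Exact midpoints (12.5, 37.5, 62.5, 87.5) break toward the
#' larger ideal and are flagged in the `boundary` column.
#'
#' @param ipl IPL values in percent, in `[0, 100]` (100 wraps to 0).
#' @return A tibble with columns `ipl`, `category` (factor with levels pace,
#'   trot, no-limb-pairing), `boundary` (logical midpoint flag).
#' @examples
#' categorize_ipl(c(3, 50, 75, 37.5))
#' @export
categorize_ipl <- function(ipl) {
  if (any(ipl < 0 | ipl > 100)) stop("IPL must lie in [0, 100]", call. = FALSE)
  ideals <- c(0, 25, 50, 75, 100)
  gait <- c("pace", "no-limb-pairing", "trot", "no-limb-pairing", "pace")
  pick <- vapply(ipl, function(x) {
    d <- abs(x - ideals)
    max(which(d == min(d))) # midpoint ties break toward the larger ideal
  }, 0L)
  tibble::tibble(
    ipl = ipl,
    category = factor(gait[pick], levels = c("pace", "trot", "no-limb-pairing")),
    boundary = (ipl %% 25) == 12.5
  )
}

#' Export / import the ILCM catalogue as JSON
#'
#' The JSON document carries, per mode, the id, the ordered event groups and
#' the ideal touchdown phases, so the catalogue can be consumed outside R.
#'
#' @param path File path to write to or read from.
#' @return `ilcm_write_json()` returns `path` invisibly; `ilcm_read_json()`
#'   returns a tibble with the same columns as [ilcm_catalog()].
#' @export
ilcm_write_json <- function(path) {
  cat <- ilcm_catalog()
  doc <- purrr::pmap(cat, function(mode_id, landing_order, ideal_phase, ideal_ipl) {
    list(
      mode_id = mode_id,
      landing_order = landing_order,
      ideal_phase = as.list(ideal_phase),
      ideal_ipl = ideal_ipl
    )
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname ilcm_write_json
#' @export
ilcm_read_json <- function(path) {
  doc <- jsonlite::read_json(path)
  tibble::tibble(
    mode_id = purrr::map_chr(doc, "mode_id"),
    landing_order = purrr::map(doc, function(m) {
      purrr::map(m$landing_order, ~ unlist(.x, use.names = FALSE))
    }),
    ideal_phase = purrr::map(doc, ~ unlist(.x$ideal_phase)),
    ideal_ipl = purrr::map_dbl(doc, "ideal_ipl")
  )
}
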