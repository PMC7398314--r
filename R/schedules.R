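#' A year band of a transition schedule
#'
#' Published transition probabilities are reported over multi-year windows
#' (e.g. a local-recurrence probability of 6.5% over the first five years
#' after treatment). A `year_band` records the window in 1-based cycle
#' indices (the first year after treatment is cycle 1), the probability, and
#' the convention under which it is read:
#'
#' * `"period_cumulative"` -- the value is the total probability accumulated
#'   over the whole window; the per-cycle probability is
#'   `value / (end - start + 1)`.
#' * `"annual"` -- the value is already a per-cycle probability and is applied
#'   unchanged in every cycle of the window.
#'
#' @param start,end First and last cycle of the window (inclusive),
#'   `1 <= start <= end`.
#' @param value Probability in `[0, 1]`.
#' @param convention `"period_cumulative"` (default) or `"annual"`.
#' @return An object of class `year_band`.
#' @seealso [annualize()], [transition_schedule()]
#' @export
#' @examples
#' # 5.84% cumulative over cycles 11-15 -> 1.168% per cycle
#' annualize(year_band(11, 15, 0.0584))
year_band <- function(start, end, value,
                      convention = c("period_cumulative", "annual")) {
  convention <- match.arg(convention)
  if (!(is.numeric(start) && is.numeric(end) &&
        start == round(start) && end == round(end))) {
    stop("year_band: start and end must be integers", call. = FALSE)
  }
  if (start < 1 || end < start) {
    stop("year_band: invalid band [", start, ", ", end,
         "]; need 1 <= start <= end", call. = FALSE)
  }
  if (!is.numeric(value) || length(value) != 1L || value < 0 || value > 1) {
    stop("year_band: value must be a probability in [0, 1], got ",
         value, call. = FALSE)
  }
  structure(
    list(start = as.integer(start), end = as.integer(end),
         value = as.numeric(value), convention = convention),
    class = "year_band"
  )
}

#' Per-cycle probability of a year band
#'
#' Converts a band to the probability applied in each cycle of its window:
#' period-cumulative values are divided by the number of years in the window,
#' annual values are returned unchanged.
#'
#' @param band A [year_band()].
#' @return A single probability in `[0, 1]`.
#' @export
annualize <- function(band) {
  stopifnot(inherits(band, "year_band"))
  len <- band$end - band$start + 1L
  if (len < 1L) stop("annualize: invalid band length ", len, call. = FALSE)
  if (band$convention == "annual") band$value else band$value / len
}

#' A piecewise-constant per-cycle transition schedule
#'
#' Collects non-overlapping [year_band()]s into one schedule; cycles outside
#' every band take `default` (0 unless the transition is always active).
#'
#' @param bands List of [year_band()] objects (possibly empty).
#' @param default Probability used outside all bands.
#' @return An object of class `transition_schedule`.
#' @export
#' @examples
#' s <- transition_schedule(list(
#'   year_band(1, 5, 0.181),
#'   year_band(6, 10, 0.092),
#'   year_band(11, 15, 0.0568)
#' ))
#' annual_probability(s, 3)   # 0.181 / 5
#' annual_probability(s, 12)  # 0.0568 / 5
transition_schedule <- function(bands = list(), default = 0) {
  if (inherits(bands, "year_band")) bands <- list(bands)
  stopifnot(is.list(bands))
  for (b in bands) {
    if (!inherits(b, "year_band")) {
      stop("transition_schedule: every element of bands must be a year_band",
           call. = FALSE)
    }
  }
  if (!is.numeric(default) || default < 0 || default > 1) {
    stop("transition_schedule: default must be a probability in [0, 1]",
         call. = FALSE)
  }
  if (length(bands) > 1L) {
    o <- order(vapply(bands, `[[`, integer(1), "start"))
    bands <- bands[o]
    for (i in seq_len(length(bands) - 1L)) {
      if (bands[[i + 1L]]$start <= bands[[i]]$end) {
        stop(sprintf(
          "transition_schedule: bands [%d, %d] and [%d, %d] overlap",
          bands[[i]]$start, bands[[i]]$end,
          bands[[i + 1L]]$start, bands[[i + 1L]]$end), call. = FALSE)
      }
    }
  }
  structure(list(bands = bands, default = as.numeric(default)),
            class = "transition_schedule")
}

#' Per-cycle probability of a schedule at given cycles
#'
#' @param schedule A [transition_schedule()].
#' @param cycle Integer vector of cycle indices (1-based).
#' @return Numeric vector of per-cycle probabilities.
#' @export
annual_probability <- function(schedule, cycle) {
  stopifnot(inherits(schedule, "transition_schedule"))
  out <- rep(schedule$default, length(cycle))
  for (b in schedule$bands) {
    hit <- cycle >= b$start & cycle <= b$end
    if (any(hit)) out[hit] <- annualize(b)
  }
  out
}

#' @export
print.transition_schedule <- function(x, ...) {
  if (length(x$bands) == 0L) {
    cat("<transition_schedule> constant", x$default, "\n")
    return(invisible(x))
  }
  cat("<transition_schedule>\n")
  for (b in x$bands) {
    cat(sprintf("  cycles %2d-%2d: %-8s (%s -> %.6g/cycle)\n",
                b$start, b$end, format(b$value), b$convention, annualize(b)))
  }
  if (x$default != 0) cat("  elsewhere:", x$default, "\n")
  invisible(x)
}

# Highest cycle index covered by any band (0 when empty).
schedule_span <- function(schedule) {
  if (length(schedule$bands) == 0L) return(0L)
  max(vapply(schedule$bands, `[[`, integer(1), "end"))
}
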