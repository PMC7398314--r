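#' A point estimate with an uncertainty range
#'
#' Utilities, event costs and technique-specific late-effect probabilities
#' carry a base-case value plus a (low, high) range used by the one-way and
#' probabilistic sensitivity analyses. A value without published uncertainty
#' is represented as a degenerate range (`low == base == high`) and is held
#' fixed in both analyses.
#'
#' @param base Base-case value.
#' @param low,high Range bounds; default to `base` (degenerate range).
#' @return An object of class `ranged_value`.
#' @export
#' @examples
#' ranged_value(0.85, 0.80, 0.90)
#' ranged_value(20577, 17837, 23317)
ranged_value <- function(base, low = base, high = base) {
  stopifnot(is.numeric(base), length(base) == 1L,
            is.numeric(low), length(low) == 1L,
            is.numeric(high), length(high) == 1L)
  if (!(low <= base && base <= high)) {
    stop("ranged_value: requires low <= base <= high (got ",
         low, " / ", base, " / ", high, ")", call. = FALSE)
  }
  structure(list(base = as.numeric(base), low = as.numeric(low),
                 high = as.numeric(high)),
            class = "ranged_value")
}

#' @export
print.ranged_value <- function(x, ...) {
  if (is_degenerate(x)) {
    cat(format(x$base), "\n")
  } else {
    cat(sprintf("%s (%s-%s)\n", format(x$base), format(x$low), format(x$high)))
  }
  invisible(x)
}

#' Is a ranged value degenerate (no uncertainty)?
#'
#' @param x A [ranged_value()].
#' @return `TRUE` when `low == high`.
#' @export
is_degenerate <- function(x) {
  stopifnot(inherits(x, "ranged_value"))
  x$low == x$high
}

# Coerce plain numbers to degenerate ranged values; pass ranged_value through.
as_ranged <- function(x, what = "value") {
  if (inherits(x, "ranged_value")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(ranged_value(x))
  stop(what, ": expected a single number or a ranged_value", call. = FALSE)
}
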