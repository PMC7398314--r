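# One-way (tornado) sensitivity analysis
# --------------------------------------
# Each swept parameter is set to its published low and high bound with all
# other parameters at base, the full model is rerun for the technique and
# the reference strategy (SOC), and the ICER of the technique versus SOC is
# recorded at each setting. The tornado bar is |icer_high - icer_low|.

#' Full-precision ICER of a strategy versus the reference strategy
#'
#' Runs the base case for `strategy` and for SOC under `ps` and returns the
#' incremental cost over incremental QALY. The raw signed ratio is returned
#' (a negative value indicates the strategy is dominated or dominating).
#'
#' @param ps A [parameter_set()].
#' @param strategy Strategy name or [strategy_spec()]; not SOC.
#' @return USD/QALY, a single number.
#' @export
icer_vs_reference <- function(ps, strategy) {
  strategy <- .resolve_strategy(ps, strategy)
  if (identical(strategy$name, "SOC"))
    stop("strategy must differ from the reference strategy SOC", call. = FALSE)
  a <- accumulate(run_cohort(ps, strategy), ps, strategy)
  b <- accumulate(run_cohort(ps, "SOC"), ps, "SOC")
  (a$cost - b$cost) / (a$qaly - b$qaly)
}

#' The parameters swept for one technique
#'
#' The nine quantities with published ranges that drive a technique's ICER:
#' its three late-effect probabilities and the shared utilities and
#' treatment costs of the three late effects.
#'
#' @param strategy Strategy name.
#' @return Named character vector of parameter paths; names are the display
#'   labels (`P_*` probability, `U_*` utility, `C_*` cost).
#' @export
sweep_targets <- function(strategy) {
  c(P_cardiac = sprintf("strategies/%s/p_cardiac", strategy),
    P_cl_breast = sprintf("strategies/%s/p_cl_breast", strategy),
    P_lung = sprintf("strategies/%s/p_lung", strategy),
    U_cardiac = "utilities/cardiac",
    U_cl_breast = "utilities/cl_breast",
    U_lung = "utilities/lung",
    C_cardiac = "event_costs/cardiac",
    C_cl_breast = "event_costs/cl_breast",
    C_lung = "event_costs/lung")
}

#' One-way sensitivity of an ICER to one parameter
#'
#' @param ps A [parameter_set()].
#' @param strategy Strategy name or [strategy_spec()]; compared against SOC.
#' @param target Parameter path (see [get_parameter()]); must carry a range.
#' @return List with `target`, `icer_low`, `icer_base`, `icer_high` (ICER of
#'   `strategy` vs SOC with the target at its low / base / high bound) and
#'   `width = abs(icer_high - icer_low)`.
#' @export
#' @examples
#' ps <- pmrt_parameters()
#' one_way(ps, "IMPT", "strategies/IMPT/p_cardiac")
one_way <- function(ps, strategy, target) {
  strategy <- .resolve_strategy(ps, strategy)
  rv <- get_parameter(ps, target)
  # resolve by name inside the modified set so swept strategy fields apply
  at <- function(v) icer_vs_reference(set_parameter(ps, target, v), strategy$name)
  out <- list(target = target,
              icer_low = at(rv$low),
              icer_base = icer_vs_reference(ps, strategy),
              icer_high = at(rv$high))
  out$width <- abs(out$icer_high - out$icer_low)
  out
}

#' Tornado analysis for one technique
#'
#' Sweeps all nine range-carrying parameters (see [sweep_targets()]) one at
#' a time and reports the ICER versus SOC at each bound, sorted by
#' decreasing bar width.
#'
#' @inheritParams one_way
#' @return A data.frame of class `tornado_result` with columns `label`,
#'   `target`, `icer_low`, `icer_base`, `icer_high`, `width`.
#' @export
#' @examples
#' \donttest{
#' tornado(pmrt_parameters(), "IMRT")
#' }
tornado <- function(ps, strategy) {
  strategy <- .resolve_strategy(ps, strategy)
  targets <- sweep_targets(strategy$name)
  rows <- lapply(seq_along(targets), function(i) {
    ow <- one_way(ps, strategy, targets[[i]])
    data.frame(label = names(targets)[i], target = ow$target,
               icer_low = ow$icer_low, icer_base = ow$icer_base,
               icer_high = ow$icer_high, width = ow$width)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy$name
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' @export
print.tornado_result <- function(x, ...) {
  cat(sprintf("<tornado_result> %s vs SOC (base ICER %s $/QALY)\n",
              attr(x, "strategy"),
              format(round(x$icer_base[1]), big.mark = ",")))
  out <- data.frame(
    parameter = x$label,
    `icer at low` = round(x$icer_low),
    `icer at high` = round(x$icer_high),
    width = round(x$width),
    check.names = FALSE
  )
  print.data.frame(out, row.names = FALSE)
  invisible(x)
}
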