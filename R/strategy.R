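#' A radiotherapy strategy
#'
#' One treatment technique: its label, the one-time cost of the radiotherapy
#' course (booked at cycle 0, undiscounted), and the total probabilities of
#' the three late radiogenic side effects over their event windows
#' (cardiac toxicity and lung cancer over cycles 11-15, contralateral breast
#' cancer over cycles 6-15, by default; see [parameter_set()] settings).
#'
#' @param name Strategy label, e.g. `"SOC"`, `"IMRT"`, `"IMPT"`.
#' @param rt_cost Cost of the radiotherapy course in USD, `> 0`.
#' @param p_cardiac,p_cl_breast,p_lung Total late-effect probabilities over
#'   the event window, as [ranged_value()]s (plain numbers are accepted and
#'   treated as degenerate ranges). Fractions, not percentages.
#' @return An object of class `strategy_spec`.
#' @export
#' @examples
#' strategy_spec("IMPT", 33547,
#'   p_cardiac = ranged_value(0.0040, 0.0004, 0.0084),
#'   p_cl_breast = ranged_value(0.00003, 0, 0.00007),
#'   p_lung = ranged_value(0.0022, 0.0003, 0.0060)
#' )
strategy_spec <- function(name, rt_cost, p_cardiac, p_cl_breast, p_lung) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(rt_cost) || length(rt_cost) != 1L || rt_cost <= 0) {
    stop("strategy_spec [", name, "]: rt_cost must be a positive number",
         call. = FALSE)
  }
  ps <- list(p_cardiac = as_ranged(p_cardiac, "p_cardiac"),
             p_cl_breast = as_ranged(p_cl_breast, "p_cl_breast"),
             p_lung = as_ranged(p_lung, "p_lung"))
  for (nm in names(ps)) {
    p <- ps[[nm]]
    if (p$low < 0 || p$high > 1) {
      stop("strategy_spec [", name, "]: ", nm,
           " must lie in [0, 1] (got range ", p$low, "-", p$high, ")",
           call. = FALSE)
    }
  }
  structure(c(list(name = name, rt_cost = as.numeric(rt_cost)), ps),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("<strategy_spec> %s  (RT course $%s)\n", x$name,
              format(x$rt_cost, big.mark = ",")))
  fmt <- function(p) {
    if (is_degenerate(p)) sprintf("%.4g%%", 100 * p$base)
    else sprintf("%.4g%% (%.4g-%.4g%%)", 100 * p$base, 100 * p$low, 100 * p$high)
  }
  cat("  cardiac:  ", fmt(x$p_cardiac), "\n")
  cat("  CL breast:", fmt(x$p_cl_breast), "\n")
  cat("  lung:     ", fmt(x$p_lung), "\n")
  invisible(x)
}
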