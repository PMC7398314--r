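# Discounted cost / QALY accumulation
# -----------------------------------
# QALYs: sum over cycles t = 1..H of (1 + r)^-t times the utility-weighted
# occupancy at the end of cycle t (dead states weigh 0). With the half-cycle
# toggle the start- and end-of-cycle occupancies are averaged instead.
# Costs: the radiotherapy course is booked at cycle 0 undiscounted; each
# clinical event (recurrence, metastasis, cardiac, CL breast, lung) is
# charged once, at the discounted cycle of state entry.

.utility_vector <- function(ps) {
  u <- ps$utilities
  c(ned = u$ned$base, local_recurrence = u$recurrence$base,
    metastasis = u$metastasis$base, cardiac = u$cardiac$base,
    cl_breast = u$cl_breast$base, lung = u$lung$base,
    death_cancer = 0, death_other = 0, death_toxicity = 0)
}

.event_cost_vector <- function(ps) {
  ec <- ps$event_costs
  c(ned = 0, local_recurrence = ec$recurrence$base,
    metastasis = ec$metastasis$base, cardiac = ec$cardiac$base,
    cl_breast = ec$cl_breast$base, lung = ec$lung$base,
    death_cancer = 0, death_other = 0, death_toxicity = 0)
}

#' Discounted cost and QALY for one strategy
#'
#' Accumulates the discounted lifetime cost and quality-adjusted life-years
#' of a cohort trace under the utilities, event costs and discount rate of
#' the parameter set.
#'
#' @param trace A [run_cohort()] result for `strategy`.
#' @param ps The [parameter_set()] the trace was run under.
#' @param strategy The [strategy_spec()] (or name) the trace belongs to.
#' @return An object of class `cea_result`: list with `strategy`, `cost`
#'   (USD, discounted) and `qaly` (years, discounted).
#' @export
#' @examples
#' ps <- pmrt_parameters()
#' accumulate(run_cohort(ps, "SOC"), ps, "SOC")
accumulate <- function(trace, ps, strategy) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(ps, "parameter_set"))
  strategy <- .resolve_strategy(ps, strategy)
  if (!identical(trace$strategy, strategy$name)) {
    stop("trace was run for strategy '", trace$strategy,
         "', not '", strategy$name, "'", call. = FALSE)
  }
  H <- ps$settings$horizon
  if (trace$horizon != H)
    stop("trace horizon differs from parameter-set horizon", call. = FALSE)
  disc <- (1 + ps$settings$discount_rate)^-(seq_len(H))
  u <- .utility_vector(ps)
  util_end <- as.vector(trace$occupancy[2:(H + 1L), , drop = FALSE] %*% u)
  util <- if (isTRUE(ps$settings$half_cycle)) {
    (util_end + as.vector(trace$occupancy[1:H, , drop = FALSE] %*% u)) / 2
  } else {
    util_end
  }
  qaly <- sum(disc * util)
  ec <- .event_cost_vector(ps)
  cost <- strategy$rt_cost + sum(disc * as.vector(trace$entries %*% ec))
  structure(list(strategy = strategy$name, cost = cost, qaly = qaly),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s: cost $%s, QALY %.3f\n", x$strategy,
              format(round(x$cost), big.mark = ","), x$qaly))
  invisible(x)
}

#' Incremental cost-effectiveness ratio between two results
#'
#' Incremental cost divided by incremental QALY of the more costly strategy
#' over the less costly one. When the more costly strategy gains no QALYs it
#' is dominated and `NA` is returned (with a message attribute); equal costs
#' make the comparison undefined and raise an error.
#'
#' @param more_costly,less_costly [accumulate()] results (or any list with
#'   `cost` and `qaly`).
#' @return USD/QALY as a single number, or `NA` when dominated.
#' @export
#' @examples
#' a <- list(strategy = "A", cost = 20543, qaly = 9.404)
#' b <- list(strategy = "B", cost = 19131, qaly = 9.330)
#' icer(a, b)  # 19081
icer <- function(more_costly, less_costly) {
  dc <- more_costly$cost - less_costly$cost
  dq <- more_costly$qaly - less_costly$qaly
  if (dc == 0) stop("ICER undefined: strategies have equal cost", call. = FALSE)
  if (dc < 0) stop("icer: first argument must be the more costly strategy",
                   call. = FALSE)
  if (dq <= 0) {
    return(structure(NA_real_, dominated = TRUE))
  }
  dc / dq
}

#' Run the base case for every strategy
#'
#' Convenience wrapper: runs the cohort and accumulates discounted cost and
#' QALY for each strategy in the parameter set, then ranks the strategies on
#' the cost-effectiveness frontier.
#'
#' @param ps A [parameter_set()].
#' @return A [frontier()] result (data.frame) for all strategies.
#' @export
#' @examples
#' run_base_case(pmrt_parameters())
run_base_case <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  res <- lapply(ps$strategies, function(st)
    accumulate(run_cohort(ps, st), ps, st))
  frontier(res)
}
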