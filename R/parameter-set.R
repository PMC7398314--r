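#' The complete parameter set of the cohort model
#'
#' Bundles every number the Markov cohort model consumes: the treatment
#' strategies with their late-effect probabilities, the disease transition
#' schedules shared by all strategies, background and toxicity-specific
#' mortality, state utilities, one-time event costs, and the run settings
#' (discount rate, horizon, cohort start age, event windows and model
#' toggles).
#'
#' @param strategies List of [strategy_spec()]s; exactly one must be named
#'   `"SOC"` (the reference comparator for ICERs, tornado diagrams and
#'   acceptability curves).
#' @param disease Named list of [transition_schedule()]s:
#'   `local_recurrence` (well state to local recurrence), `metastasis`
#'   (well state to distant metastasis), `metastasis_death` (metastasis to
#'   cancer death).
#' @param mortality Named list of [transition_schedule()]s: `background`
#'   (other-cause death, applied to every alive state), `heart`, `cl_breast`,
#'   `lung` (toxicity-specific death, applied in the corresponding
#'   late-effect state).
#' @param utilities Named list of [ranged_value()]s in `[0, 1]` for states
#'   `ned`, `recurrence`, `metastasis`, `cardiac`, `cl_breast`, `lung`.
#'   Dead states have utility 0.
#' @param event_costs Named list of non-negative [ranged_value()]s (USD) for
#'   events `recurrence`, `metastasis`, `cardiac`, `cl_breast`, `lung`,
#'   charged once when the state is entered.
#' @param settings Named list; recognised fields (with defaults):
#'   `discount_rate` (0.03 per year), `horizon` (15 cycles), `start_age`
#'   (55 years), `cycle_length` (1 year), `half_cycle` (`FALSE`; when `TRUE`
#'   cycle rewards average start- and end-of-cycle occupancy),
#'   `recurrence_progression` (`FALSE`; when `TRUE` local recurrence
#'   progresses to metastasis at the metastasis schedule), and `windows`, a
#'   list with the late-effect event windows in cycles
#'   (`cardiac = c(11, 15)`, `lung = c(11, 15)`, `cl_breast = c(6, 15)`).
#' @return A validated object of class `parameter_set`.
#' @seealso [pmrt_parameters()] for the bundled reference set,
#'   [load_parameters()] / [write_parameters()] for file I/O.
#' @export
parameter_set <- function(strategies, disease, mortality, utilities,
                          event_costs, settings = list()) {
  defaults <- list(
    discount_rate = 0.03, horizon = 15L, start_age = 55, cycle_length = 1,
    half_cycle = FALSE, recurrence_progression = FALSE,
    windows = list(cardiac = c(11L, 15L), lung = c(11L, 15L),
                   cl_breast = c(6L, 15L))
  )
  settings <- modifyList(defaults, settings)
  settings$horizon <- as.integer(settings$horizon)
  for (nm in c("discount_rate", "start_age", "cycle_length"))
    settings[[nm]] <- as.numeric(settings[[nm]])
  settings$half_cycle <- isTRUE(settings$half_cycle)
  settings$recurrence_progression <- isTRUE(settings$recurrence_progression)
  settings$windows <- lapply(settings$windows, as.integer)

  if (inherits(strategies, "strategy_spec")) strategies <- list(strategies)
  names(strategies) <- vapply(strategies, `[[`, character(1), "name")

  utilities <- lapply(utilities, as_ranged, what = "utility")
  event_costs <- lapply(event_costs, as_ranged, what = "event cost")

  ps <- structure(
    list(strategies = strategies, disease = disease, mortality = mortality,
         utilities = utilities, event_costs = event_costs,
         settings = settings),
    class = "parameter_set"
  )
  validate_parameter_set(ps)
  ps
}

#' Validate a parameter set
#'
#' Checks every structural invariant and reports violations with the path of
#' the offending entry (e.g. `utilities/metastasis`). Called by
#' [parameter_set()] and [load_parameters()]; exported so hand-edited objects
#' can be rechecked.
#'
#' @param ps A `parameter_set`.
#' @return `ps`, invisibly; errors on the first violation found.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  s <- ps$settings
  fail <- function(path, msg) {
    stop("invalid parameter set at ", path, ": ", msg, call. = FALSE)
  }

  if (!is.numeric(s$discount_rate) || s$discount_rate < 0 || s$discount_rate >= 1)
    fail("settings/discount_rate", "must lie in [0, 1)")
  if (s$horizon < 1L) fail("settings/horizon", "must be >= 1")
  for (w in c("cardiac", "lung", "cl_breast")) {
    win <- s$windows[[w]]
    if (is.null(win) || length(win) != 2L || win[1] < 1 || win[2] < win[1])
      fail(paste0("settings/windows/", w), "must be c(first, last) with 1 <= first <= last")
  }

  if (length(ps$strategies) < 1L) fail("strategies", "need at least one strategy")
  if (sum(names(ps$strategies) == "SOC") != 1L)
    fail("strategies", "exactly one strategy must be named 'SOC'")
  for (st in ps$strategies) {
    if (!inherits(st, "strategy_spec"))
      fail(paste0("strategies/", st$name), "not a strategy_spec")
  }
  if (anyDuplicated(names(ps$strategies)))
    fail("strategies", "strategy names must be distinct")

  need_sched <- list(disease = c("local_recurrence", "metastasis", "metastasis_death"),
                     mortality = c("background", "heart", "cl_breast", "lung"))
  for (sec in names(need_sched)) {
    for (nm in need_sched[[sec]]) {
      sch <- ps[[sec]][[nm]]
      if (!inherits(sch, "transition_schedule"))
        fail(paste0(sec, "/", nm), "missing or not a transition_schedule")
      if (schedule_span(sch) > s$horizon)
        fail(paste0(sec, "/", nm),
             paste0("band extends beyond the ", s$horizon, "-cycle horizon"))
    }
  }

  for (nm in c("ned", "recurrence", "metastasis", "cardiac", "cl_breast", "lung")) {
    u <- ps$utilities[[nm]]
    if (is.null(u)) fail(paste0("utilities/", nm), "missing")
    if (u$low < 0 || u$high > 1)
      fail(paste0("utilities/", nm), "utilities must lie in [0, 1]")
  }
  for (nm in c("recurrence", "metastasis", "cardiac", "cl_breast", "lung")) {
    ec <- ps$event_costs[[nm]]
    if (is.null(ec)) fail(paste0("event_costs/", nm), "missing")
    if (ec$low < 0) fail(paste0("event_costs/", nm), "costs must be >= 0")
  }
  invisible(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  s <- x$settings
  cat("<parameter_set>\n")
  cat(sprintf("  %d strategies: %s\n", length(x$strategies),
              paste(names(x$strategies), collapse = ", ")))
  cat(sprintf("  horizon %d cycles of %g year(s), start age %g, discount %g/year\n",
              s$horizon, s$cycle_length, s$start_age, s$discount_rate))
  cat(sprintf("  event windows: cardiac %d-%d, lung %d-%d, CL breast %d-%d\n",
              s$windows$cardiac[1], s$windows$cardiac[2],
              s$windows$lung[1], s$windows$lung[2],
              s$windows$cl_breast[1], s$windows$cl_breast[2]))
  cat(sprintf("  toggles: half_cycle=%s, recurrence_progression=%s\n",
              s$half_cycle, s$recurrence_progression))
  invisible(x)
}

#' Look up or replace a ranged value inside a parameter set by path
#'
#' Paths address the quantities swept by the sensitivity analyses:
#' `"utilities/<state>"`, `"event_costs/<event>"`, and
#' `"strategies/<name>/<p_cardiac|p_cl_breast|p_lung>"`.
#'
#' @param ps A `parameter_set`.
#' @param path Character path, `/`-separated.
#' @param value Replacement: a number (sets the base, keeps the range) or a
#'   [ranged_value()].
#' @return `get_parameter()` returns the [ranged_value()]; `set_parameter()`
#'   returns a modified copy of `ps`.
#' @export
get_parameter <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  node <- ps
  for (p in parts) {
    node <- node[[p]]
    if (is.null(node)) stop("no parameter at path '", path, "'", call. = FALSE)
  }
  if (!inherits(node, "ranged_value"))
    stop("path '", path, "' does not address a ranged value", call. = FALSE)
  node
}

#' @rdname get_parameter
#' @export
set_parameter <- function(ps, path, value) {
  old <- get_parameter(ps, path)
  new <- if (inherits(value, "ranged_value")) value else {
    stopifnot(is.numeric(value), length(value) == 1L)
    ranged_value(value, min(old$low, value), max(old$high, value))
  }
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  ps[[parts]] <- new
  validate_parameter_set(ps)
  ps
}
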