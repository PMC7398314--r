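# Cohort propagation
# ------------------
# One hypothetical cohort starts in the well state (NED) after treatment and
# moves through annual cycles. The NED row carries all incidence exits
# (local recurrence, metastasis, the three late-effect states inside their
# event windows) plus background mortality; each downstream state carries its
# own mortality. Competing risks within a row are additive -- the per-cycle
# exit probabilities are subtracted from the stay probability without a
# rate-to-probability conversion -- and feasibility (row sums <= 1) is
# checked every cycle.

# Per-cycle schedules for one strategy's late effects, built from the total
# window probabilities and the event windows in settings.
.toxicity_schedules <- function(ps, strategy) {
  w <- ps$settings$windows
  mk <- function(p, win) transition_schedule(list(
    year_band(win[1], win[2], p$base, convention = "period_cumulative")))
  list(cardiac = mk(strategy$p_cardiac, w$cardiac),
       cl_breast = mk(strategy$p_cl_breast, w$cl_breast),
       lung = mk(strategy$p_lung, w$lung))
}

# All per-cycle exit probabilities for one strategy as a list of numeric
# vectors of length horizon. Shared by the scalar and the vectorised engines.
.cycle_probabilities <- function(ps, strategy) {
  t <- seq_len(ps$settings$horizon)
  tox <- .toxicity_schedules(ps, strategy)
  list(
    lr = annual_probability(ps$disease$local_recurrence, t),
    met = annual_probability(ps$disease$metastasis, t),
    met_death = annual_probability(ps$disease$metastasis_death, t),
    bg = annual_probability(ps$mortality$background, t),
    heart_death = annual_probability(ps$mortality$heart, t),
    clb_death = annual_probability(ps$mortality$cl_breast, t),
    lung_death = annual_probability(ps$mortality$lung, t),
    cardiac = annual_probability(tox$cardiac, t),
    cl_breast = annual_probability(tox$cl_breast, t),
    lung = annual_probability(tox$lung, t)
  )
}

.check_feasible <- function(p, strategy, horizon) {
  ned_exit <- p$lr + p$met + p$cardiac + p$cl_breast + p$lung + p$bg
  rows <- rbind(ned = ned_exit,
                metastasis = p$met_death + p$bg,
                cardiac = p$heart_death + p$bg,
                cl_breast = p$clb_death + p$bg,
                lung = p$lung_death + p$bg)
  bad <- which(rows > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "infeasible parameters for strategy %s: %s row exit probabilities sum to %.4f > 1 in cycle %d",
      strategy$name, rownames(rows)[bad[1, 1]],
      rows[bad[1, , drop = FALSE]], bad[1, 2]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Transition matrix for one strategy and cycle
#'
#' Builds the row-stochastic transition matrix over [health_states()] for a
#' given cycle, with per-cycle probabilities taken from the annualized
#' schedules. Late-effect entries are zero outside their event windows; the
#' three death states are absorbing.
#'
#' @param ps A [parameter_set()].
#' @param strategy A [strategy_spec()] (or the name of one in `ps`).
#' @param cycle Cycle index in `1:horizon`.
#' @return A 9 x 9 row-stochastic matrix with dimnames [health_states()].
#' @export
#' @examples
#' ps <- pmrt_parameters()
#' M <- transition_matrix(ps, "SOC", 3)
#' rowSums(M)  # all 1
transition_matrix <- function(ps, strategy, cycle) {
  stopifnot(inherits(ps, "parameter_set"))
  strategy <- .resolve_strategy(ps, strategy)
  H <- ps$settings$horizon
  if (cycle < 1 || cycle > H)
    stop("cycle must lie in 1..", H, call. = FALSE)
  p <- .cycle_probabilities(ps, strategy)
  .check_feasible(p, strategy, H)
  t <- cycle
  lrp <- if (isTRUE(ps$settings$recurrence_progression)) p$met[t] else 0

  M <- matrix(0, 9, 9, dimnames = list(.states, .states))
  M["ned", "local_recurrence"] <- p$lr[t]
  M["ned", "metastasis"] <- p$met[t]
  M["ned", "cardiac"] <- p$cardiac[t]
  M["ned", "cl_breast"] <- p$cl_breast[t]
  M["ned", "lung"] <- p$lung[t]
  M["ned", "death_other"] <- p$bg[t]
  M["local_recurrence", "metastasis"] <- lrp
  M["local_recurrence", "death_other"] <- p$bg[t]
  M["metastasis", "death_cancer"] <- p$met_death[t]
  M["metastasis", "death_other"] <- p$bg[t]
  M["cardiac", "death_toxicity"] <- p$heart_death[t]
  M["cardiac", "death_other"] <- p$bg[t]
  M["cl_breast", "death_toxicity"] <- p$clb_death[t]
  M["cl_breast", "death_other"] <- p$bg[t]
  M["lung", "death_toxicity"] <- p$lung_death[t]
  M["lung", "death_other"] <- p$bg[t]
  diag(M) <- 0
  diag(M) <- 1 - rowSums(M)
  M
}

.resolve_strategy <- function(ps, strategy) {
  if (inherits(strategy, "strategy_spec")) return(strategy)
  if (is.character(strategy) && length(strategy) == 1L) {
    st <- ps$strategies[[strategy]]
    if (is.null(st)) stop("unknown strategy '", strategy, "'", call. = FALSE)
    return(st)
  }
  stop("strategy must be a strategy_spec or a strategy name", call. = FALSE)
}

#' Run the cohort through the full horizon
#'
#' Starts the whole cohort in the well state at cycle 0 and propagates it
#' through [transition_matrix()] for each cycle, recording state occupancy
#' at every cycle boundary and the fraction newly entering each state during
#' each cycle (the quantity one-time event costs are charged on).
#'
#' @inheritParams transition_matrix
#' @return An object of class `cohort_trace`: a list with `occupancy`
#'   (`(horizon + 1) x 9` matrix, rows = cycle boundaries `0:horizon`),
#'   `entries` (`horizon x 9` matrix of incident entries per cycle), and the
#'   strategy name.
#' @export
#' @examples
#' tr <- run_cohort(pmrt_parameters(), "SOC")
#' survival_summary(tr)
run_cohort <- function(ps, strategy) {
  stopifnot(inherits(ps, "parameter_set"))
  strategy <- .resolve_strategy(ps, strategy)
  H <- ps$settings$horizon
  occ <- matrix(0, H + 1L, 9L, dimnames = list(0:H, .states))
  ent <- matrix(0, H, 9L, dimnames = list(1:H, .states))
  occ[1L, "ned"] <- 1
  for (t in seq_len(H)) {
    M <- transition_matrix(ps, strategy, t)
    o <- occ[t, ]
    occ[t + 1L, ] <- o %*% M
    inflow <- o %*% M - o * diag(M)   # arrivals: total next minus stayers
    ent[t, ] <- pmax(inflow, 0)
    ent[t, "ned"] <- 0
  }
  structure(list(occupancy = occ, entries = ent, strategy = strategy$name,
                 horizon = H),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  last <- x$occupancy[nrow(x$occupancy), ]
  cat(sprintf("<cohort_trace> strategy %s, %d cycles\n", x$strategy, x$horizon))
  cat(sprintf("  final: alive %.1f%% (NED %.1f%%), cancer death %.1f%%, other %.1f%%, toxicity %.2f%%\n",
              100 * sum(last[.alive_states]), 100 * last["ned"],
              100 * last["death_cancer"], 100 * last["death_other"],
              100 * last["death_toxicity"]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  H <- x$horizon
  data.frame(
    strategy = x$strategy,
    cycle = rep(0:H, times = 9L),
    state = rep(.states, each = H + 1L),
    occupancy = as.vector(x$occupancy),
    incident_entry = as.vector(rbind(NA_real_, x$entries)),
    row.names = NULL
  )
}

#' Survival summary of a cohort trace
#'
#' Splits the cohort at the end of the horizon into survivors and deaths by
#' attributed cause. Overall survival is 1 minus total dead-state occupancy;
#' breast-cancer mortality is the occupancy of the cancer-death state
#' (deaths via the metastasis pathway).
#'
#' @param trace A [run_cohort()] result.
#' @return Named list with `overall_survival`, `cancer_mortality`,
#'   `other_mortality`, `toxicity_mortality` (fractions summing to 1).
#' @export
survival_summary <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  last <- trace$occupancy[nrow(trace$occupancy), ]
  list(
    overall_survival = unname(1 - sum(last[.dead_states])),
    cancer_mortality = unname(last["death_cancer"]),
    other_mortality = unname(last["death_other"]),
    toxicity_mortality = unname(last["death_toxicity"])
  )
}
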