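# Synthetic parameter sets
# ------------------------
# Random, always-valid parameter sets mirroring the band structure of the
# reference set (three 5-year disease/mortality bands, late-effect windows
# 11-15 and 6-15), plus named degenerate scenarios with closed-form
# outcomes. Feasibility is guaranteed by construction: per-exit draws are
# scaled so that no transition-matrix row can exceed 1, so property tests
# over generated sets never stall on rejection.

#' Generate a random, valid parameter set
#'
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @param n_strategies Number of strategies including the reference (>= 1);
#'   the first is named `"SOC"`, the rest `"SYN-1"`, `"SYN-2"`, ...
#' @param probability_scale Multiplier in `[0, 1]` applied to all incidence
#'   magnitudes; 0 gives all-zero dynamics (the cohort never leaves the well
#'   state).
#' @param with_ranges Give utilities, event costs and late-effect
#'   probabilities nontrivial ranges (default `TRUE`); otherwise all ranges
#'   are degenerate.
#' @return A validated [parameter_set()].
#' @export
#' @examples
#' ps <- random_parameter_set(seed = 7, n_strategies = 3)
#' run_base_case(ps)
random_parameter_set <- function(seed, n_strategies = 3L,
                                 probability_scale = 1, with_ranges = TRUE) {
  stopifnot(n_strategies >= 1L,
            probability_scale >= 0, probability_scale <= 1)
  set.seed(as.integer(seed))
  sc <- probability_scale
  H <- 15L

  # each NED exit per cycle is at most 0.1 * scale, so the six-exit row sum
  # never exceeds 0.6; downstream rows hold at most two exits <= 0.5 each
  rband <- function(starts, ends, max_total) {
    transition_schedule(lapply(seq_along(starts), function(i)
      year_band(starts[i], ends[i], runif(1, 0, max_total) * sc)))
  }
  band3 <- function(max_per_cycle)
    rband(c(1, 6, 11), c(5, 10, 15), max_total = max_per_cycle * 5)
  disease <- list(
    local_recurrence = band3(0.1),
    metastasis = band3(0.1),
    metastasis_death = transition_schedule(list(
      year_band(1, 5, runif(1, 0, 0.4) * sc, convention = "annual"),
      year_band(6, 15, runif(1, 0, 0.3) * sc, convention = "annual")))
  )
  mortality <- list(
    background = band3(0.05),
    heart = rband(11, 15, 0.4),
    cl_breast = rband(11, 15, 0.4),
    lung = rband(11, 15, 0.4)
  )

  rv <- function(base, spread, lo = 0, hi = 1) {
    if (!with_ranges || spread == 0) return(ranged_value(base))
    d <- runif(2, 0, spread)
    ranged_value(base, max(lo, base - d[1]), min(hi, base + d[2]))
  }
  # window totals <= 0.5 => per-cycle <= 0.1 (5-cycle window), 0.05 (10-cycle)
  rstrat <- function(nm) {
    strategy_spec(nm, rt_cost = round(runif(1, 5000, 40000)),
                  p_cardiac = rv(runif(1, 0, 0.4) * sc, 0.05 * sc, hi = 0.5),
                  p_cl_breast = rv(runif(1, 0, 0.4) * sc, 0.05 * sc, hi = 0.5),
                  p_lung = rv(runif(1, 0, 0.4) * sc, 0.05 * sc, hi = 0.5))
  }
  names_ <- c("SOC", if (n_strategies > 1L) paste0("SYN-", seq_len(n_strategies - 1L)))
  strategies <- lapply(names_, rstrat)

  utilities <- list(
    ned = ranged_value(1),
    recurrence = rv(runif(1, 0.5, 1), 0.05),
    metastasis = rv(runif(1, 0.3, 0.9), 0.05),
    cardiac = rv(runif(1, 0.5, 0.95), 0.05),
    cl_breast = rv(runif(1, 0.5, 0.95), 0.05),
    lung = rv(runif(1, 0.5, 0.95), 0.05)
  )
  event_costs <- lapply(setNames(nm = c("recurrence", "metastasis", "cardiac",
                                        "cl_breast", "lung")), function(nm) {
    base <- round(runif(1, 1000, 30000))
    rv(base, 0.2 * base, lo = 0, hi = Inf)
  })

  parameter_set(strategies, disease, mortality, utilities, event_costs,
                settings = list(horizon = H))
}

#' Named degenerate scenarios with closed-form outcomes
#'
#' Small parameter sets whose results can be computed by hand, used to
#' anchor the engine and the cost/QALY accumulation:
#'
#' * `immortal` -- no deaths, no events: every strategy's QALY equals the
#'   discounted annuity over the horizon and its cost equals its RT cost.
#' * `pure_background_death` -- only background mortality (0.64% / 0.94% /
#'   1.16% per cycle over the three 5-year bands): 15-year survival is the
#'   closed-form product of the per-cycle stay probabilities.
#' * `two_strategy_known_icer` -- SOC sends half the cohort to the
#'   contralateral-breast state at cycle 1 (utility 0.8, event cost $1,000);
#'   the $1,000-more-expensive alternative is event-free. The ICER has a
#'   closed form (see the examples in the test suite).
#' * `certain_metastasis` -- the whole surviving cohort enters metastasis in
#'   cycle 1 (no other transitions active).
#'
#' @return Named list of [parameter_set()]s.
#' @export
degenerate_scenarios <- function() {
  zero_sched <- transition_schedule()
  zero_rv <- ranged_value(0)
  utilities <- list(ned = ranged_value(1), recurrence = ranged_value(0.85),
                    metastasis = ranged_value(0.62), cardiac = ranged_value(0.85),
                    cl_breast = ranged_value(0.8), lung = ranged_value(0.72))
  costs <- lapply(setNames(nm = c("recurrence", "metastasis", "cardiac",
                                  "cl_breast", "lung")),
                  function(nm) ranged_value(1000))
  base_strats <- function(p_soc_clb = 0, rt_soc = 1000, rt_alt = 2000) list(
    strategy_spec("SOC", rt_soc, zero_rv, ranged_value(p_soc_clb), zero_rv),
    strategy_spec("ALT", rt_alt, zero_rv, zero_rv, zero_rv)
  )
  zeros <- list(local_recurrence = zero_sched, metastasis = zero_sched,
                metastasis_death = zero_sched)
  no_mort <- list(background = zero_sched, heart = zero_sched,
                  cl_breast = zero_sched, lung = zero_sched)

  immortal <- parameter_set(base_strats(), zeros, no_mort, utilities, costs)

  bg_mort <- no_mort
  bg_mort$background <- transition_schedule(list(
    year_band(1, 5, 0.032), year_band(6, 10, 0.047),
    year_band(11, 15, 0.058)))
  bg <- parameter_set(base_strats(), zeros, bg_mort, utilities, costs)

  known_icer <- parameter_set(
    base_strats(p_soc_clb = 0.5), zeros, no_mort, utilities, costs,
    settings = list(windows = list(cardiac = c(11, 15), lung = c(11, 15),
                                   cl_breast = c(1, 1))))

  certain_disease <- zeros
  certain_disease$metastasis <- transition_schedule(list(
    year_band(1, 15, 1, convention = "annual")))
  certain_met <- parameter_set(base_strats(), certain_disease, no_mort,
                               utilities, costs)

  list(immortal = immortal, pure_background_death = bg,
       two_strategy_known_icer = known_icer,
       certain_metastasis = certain_met)
}
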