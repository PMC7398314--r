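test_that("an event-free cohort accrues the discounted annuity in QALYs", {
  sc <- degenerate_scenarios()$immortal
  res <- accumulate(run_cohort(sc, "SOC"), sc, "SOC")
  expect_equal(res$qaly, annuity(15, 0.03), tolerance = 1e-12)
  expect_equal(round(res$qaly, 4), 11.9379)
  expect_equal(res$cost, sc$strategies$SOC$rt_cost)  # RT course only
  # undiscounted: exactly the horizon in years
  sc$settings$discount_rate <- 0
  res0 <- accumulate(run_cohort(sc, "SOC"), sc, "SOC")
  expect_equal(res0$qaly, 15)
})

test_that("event costs are charged once at the discounted entry cycle", {
  sc <- degenerate_scenarios()$two_strategy_known_icer
  soc <- accumulate(run_cohort(sc, "SOC"), sc, "SOC")
  alt <- accumulate(run_cohort(sc, "ALT"), sc, "ALT")
  # SOC: half the cohort enters the CL-breast state at cycle 1
  # (event cost $1,000, utility 0.8 thereafter)
  expect_equal(soc$cost, 1000 + 0.5 * 1000 / 1.03, tolerance = 1e-12)
  expect_equal(soc$qaly, 0.9 * annuity(15, 0.03), tolerance = 1e-12)
  expect_equal(alt$cost, 2000)
  expect_equal(alt$qaly, annuity(15, 0.03), tolerance = 1e-12)
  # hand-computable ICER of the $1,000-more-expensive event-free arm
  expected_icer <- (1000 - 500 / 1.03) / (0.1 * annuity(15, 0.03))
  expect_equal(icer(alt, soc), expected_icer, tolerance = 1e-12)
})

test_that("accumulate guards against trace/strategy mismatches", {
  ps <- pmrt_parameters()
  tr <- run_cohort(ps, "SOC")
  expect_error(accumulate(tr, ps, "IMRT"), "run for strategy")
})

test_that("ICERs follow incremental cost over incremental QALY", {
  # published pairs: arithmetic must reproduce the printed ratios exactly
  imrt <- list(cost = 20543, qaly = 9.404)
  stdv <- list(cost = 19131, qaly = 9.330)
  impt <- list(cost = 38145, qaly = 9.520)
  expect_equal(round(icer(imrt, stdv)), 19081)
  expect_equal(round(icer(impt, imrt)), 151741)
  # zero QALY gain -> dominated marker
  d <- icer(list(cost = 10, qaly = 1), list(cost = 5, qaly = 1))
  expect_true(is.na(d))
  expect_true(attr(d, "dominated"))
  expect_error(icer(list(cost = 5, qaly = 2), list(cost = 5, qaly = 1)),
               "equal cost")
  expect_error(icer(list(cost = 4, qaly = 2), list(cost = 5, qaly = 1)),
               "more costly")
})

test_that("the frontier flags published dominance exactly", {
  fr <- frontier(published_base_case())
  expect_equal(fr$strategy,
               c("SOC", "STD-VMAT", "TOMO", "IMRT", "MA-VMAT", "NC-VMAT",
                 "MIXED", "IMPT"))
  expect_equal(frontier_strategies(fr), c("SOC", "STD-VMAT", "IMRT", "IMPT"))
  dom <- setNames(fr$dominated_by, fr$strategy)
  expect_equal(unname(dom["TOMO"]), "STD-VMAT")
  expect_equal(unname(dom[c("MA-VMAT", "NC-VMAT", "MIXED")]),
               rep("IMRT", 3))
  icers <- setNames(fr$icer, fr$strategy)
  expect_equal(round(unname(icers["IMRT"])), 19081)
  expect_equal(round(unname(icers["IMPT"])), 151741)
  expect_true(is.na(icers["SOC"]))
})

test_that("frontier handles single strategies and cost ties", {
  one <- frontier(data.frame(strategy = "SOC", cost = 100, qaly = 1))
  expect_equal(nrow(one), 1)
  expect_false(one$dominated)
  expect_true(is.na(one$icer))
  # equal cost, higher QALY dominates
  tie <- frontier(data.frame(strategy = c("A", "B"), cost = c(10, 10),
                             qaly = c(2, 1)))
  expect_equal(tie$strategy[tie$dominated], "B")
  expect_equal(tie$dominated_by[tie$dominated], "A")
})

test_that("frontier agrees with a brute-force dominance oracle", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    tab <- data.frame(strategy = paste0("S", seq_len(n)),
                      cost = round(runif(n, 1000, 50000)),
                      qaly = round(runif(n, 5, 12), 3))
    tab <- tab[!duplicated(tab[, c("cost", "qaly")]), ]
    fr <- frontier(tab)
    oracle <- brute_force_dominated(fr)
    expect_equal(fr$dominated, oracle)
    # non-dominated subsequence strictly increases in both cost and QALY
    nd <- fr[!fr$dominated, ]
    if (nrow(nd) > 1) {
      expect_true(all(diff(nd$cost) > 0))
      expect_true(all(diff(nd$qaly) > 0))
      expect_equal(fr$icer[!fr$dominated][-1],
                   diff(nd$cost) / diff(nd$qaly))
    }
  }
})

test_that("shifting every cost by a constant preserves dominance and ICER gaps", {
  tab <- published_base_case()
  fr0 <- frontier(tab)
  tab2 <- transform(tab, cost = cost + 5000)
  fr2 <- frontier(tab2)
  expect_equal(fr0$dominated, fr2$dominated)
  expect_equal(fr0$strategy, fr2$strategy)
  expect_equal(fr0$icer, fr2$icer)  # increments unchanged
})

test_that("extended dominance removes strategies with out-of-order ICERs", {
  # B has a higher ICER than the next frontier step -> extended dominance
  tab <- data.frame(strategy = c("A", "B", "C"),
                    cost = c(0, 100, 120),
                    qaly = c(0, 0.001, 1))
  fr <- frontier(tab, extended = TRUE)
  expect_equal(fr$strategy[fr$dominated], "B")
  expect_equal(fr$dominated_by[fr$dominated], "extended dominance")
  expect_equal(fr$icer[fr$strategy == "C"], 120 / 1)
  # off by default: B stays on the frontier
  expect_false(frontier(tab)$dominated[2])
})

test_that("raising toxicity lowers QALY and raises event cost monotonically", {
  ps <- pmrt_parameters()
  base <- accumulate(run_cohort(ps, "IMRT"), ps, "IMRT")
  worse <- set_parameter(ps, "strategies/IMRT/p_cardiac", 0.10)
  res <- accumulate(run_cohort(worse, "IMRT"), worse, "IMRT")
  expect_true(res$qaly < base$qaly)
  expect_true(res$cost > base$cost)
})

test_that("every strategy's QALY respects the annuity upper bound", {
  ps <- pmrt_parameters()
  fr <- run_base_case(ps)
  expect_true(all(fr$qaly <= annuity(15, 0.03) + 1e-12))
  expect_true(all(fr$cost >= vapply(ps$strategies[fr$strategy], `[[`,
                                    numeric(1), "rt_cost")))
})

test_that("the half-cycle toggle raises QALYs toward the cycle-start value", {
  ps <- pmrt_parameters()
  off <- accumulate(run_cohort(ps, "SOC"), ps, "SOC")
  ps$settings$half_cycle <- TRUE
  on <- accumulate(run_cohort(ps, "SOC"), ps, "SOC")
  expect_true(on$qaly > off$qaly)   # start-of-cycle occupancy is healthier
  expect_equal(on$cost, off$cost)   # event charging is unaffected
})
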