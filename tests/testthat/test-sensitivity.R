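test_that("beta and gamma distributions match the published moments rule", {
  ps <- pmrt_parameters()
  d <- build_distributions(ps)
  names(d) <- vapply(d, `[[`, character(1), "target")
  # utility 0.85 (0.8-0.9) -> beta, mean 0.85, sd (0.9-0.8)/4 = 0.025
  uc <- d[["utilities/cardiac"]]
  expect_equal(uc$family, "beta")
  expect_equal(uc$mean, 0.85)
  expect_equal(uc$sd, 0.025)
  # method of moments: analytic mean/sd of the fitted beta reproduce them
  expect_equal(uc$shape1 / (uc$shape1 + uc$shape2), 0.85)
  bvar <- uc$shape1 * uc$shape2 /
    ((uc$shape1 + uc$shape2)^2 * (uc$shape1 + uc$shape2 + 1))
  expect_equal(sqrt(bvar), 0.025)
  # cost 11,570 (8,165-14,975) -> gamma, mean 11,570, sd 1,702.5
  cc <- d[["event_costs/cardiac"]]
  expect_equal(cc$family, "gamma")
  expect_equal(cc$mean, 11570)
  expect_equal(cc$sd, (14975 - 8165) / 4)
  expect_equal(cc$shape / cc$rate, 11570)
  expect_equal(sqrt(cc$shape) / cc$rate, 1702.5)
  # values without published ranges are degenerate and held fixed
  expect_equal(d[["utilities/ned"]]$family, "degenerate")
  expect_equal(d[["strategies/SOC/p_cardiac"]]$family, "degenerate")
  expect_equal(d[["event_costs/recurrence"]]$family, "degenerate")
  # technique-specific probabilities are beta
  expect_equal(d[["strategies/IMRT/p_cardiac"]]$family, "beta")
})

test_that("infeasible beta moments are rejected with the target named", {
  sc <- degenerate_scenarios()$immortal
  # sd greater than sqrt(m(1-m)) cannot come from any beta
  sc$utilities$lung <- ranged_value(0.999, 0.1, 1)
  expect_error(build_distributions(sc), "utilities/lung")
})

test_that("quantile sampling reproduces distribution means", {
  ps <- pmrt_parameters()
  d <- build_distributions(ps)
  names(d) <- vapply(d, `[[`, character(1), "target")
  set.seed(99)
  u <- runif(10000)
  for (tg in c("utilities/cardiac", "event_costs/lung",
               "strategies/IMRT/p_cardiac")) {
    x <- pmrtcea:::.sample_distribution(d[[tg]], u)
    # sample mean within 5 standard errors of the base value
    expect_lt(abs(mean(x) - d[[tg]]$mean), 5 * d[[tg]]$sd / sqrt(length(u)))
  }
  # degenerate: point mass at the base
  x <- pmrtcea:::.sample_distribution(d[["utilities/ned"]], u)
  expect_equal(unique(x), 1)
})

test_that("one-way sweeps bracket the base ICER and collapse when degenerate", {
  ps <- pmrt_parameters()
  ow <- one_way(ps, "IMPT", "strategies/IMPT/p_cardiac")
  lo <- min(ow$icer_low, ow$icer_high)
  hi <- max(ow$icer_low, ow$icer_high)
  expect_true(lo <= ow$icer_base && ow$icer_base <= hi)
  expect_gt(ow$width, 0)
  # degenerate target: all three ICERs identical
  ow0 <- one_way(ps, "IMPT", "event_costs/recurrence")
  expect_equal(ow0$icer_low, ow0$icer_base)
  expect_equal(ow0$icer_high, ow0$icer_base)
  expect_equal(ow0$width, 0)
  expect_error(one_way(ps, "SOC", "utilities/cardiac"), "reference")
})

test_that("tornado covers nine parameters per technique, sorted by width", {
  ps <- pmrt_parameters()
  to <- tornado(ps, "IMRT")
  expect_equal(nrow(to), 9)
  expect_setequal(to$label, c("P_cardiac", "P_cl_breast", "P_lung",
                              "U_cardiac", "U_cl_breast", "U_lung",
                              "C_cardiac", "C_cl_breast", "C_lung"))
  expect_true(all(diff(to$width) <= 0))
  # sweeping a technique probability must move the ICER
  expect_gt(to$width[to$label == "P_cardiac"], 0)
})

test_that("PSA is reproducible bit for bit under a fixed seed", {
  ps <- pmrt_parameters()
  a <- psa(ps, 300, seed = 11)
  b <- psa(ps, 300, seed = 11)
  expect_identical(a$samples, b$samples)
  c <- psa(ps, 300, seed = 12)
  expect_false(identical(a$samples, c$samples))
})

test_that("iteration substreams are stable when the count grows", {
  ps <- pmrt_parameters()
  small <- psa(ps, 50, seed = 4)$samples
  big <- psa(ps, 200, seed = 4)$samples
  first50 <- big[big$iteration <= 50, ]
  rownames(first50) <- NULL
  expect_identical(small, first50)
})

test_that("degenerate distributions reproduce the base case in every draw", {
  sc <- degenerate_scenarios()$two_strategy_known_icer
  pr <- psa(sc, 25, seed = 3)
  base <- run_base_case(sc)
  for (nm in c("SOC", "ALT")) {
    s <- pr$samples[pr$samples$strategy == nm, ]
    expect_equal(unique(s$cost), base$cost[base$strategy == nm])
    expect_equal(unique(s$qaly), base$qaly[base$strategy == nm])
  }
})

test_that("PSA cloud means approach the base case as iterations grow", {
  ps <- pmrt_parameters()
  base <- run_base_case(ps)
  base_soc_cost <- base$cost[base$strategy == "SOC"]
  base_soc_qaly <- base$qaly[base$strategy == "SOC"]
  dev <- function(n) {
    s <- psa(ps, n, seed = 21)$samples
    s <- s[s$strategy == "SOC", ]
    c(cost = abs(mean(s$cost) - base_soc_cost),
      qaly = abs(mean(s$qaly) - base_soc_qaly))
  }
  d_small <- dev(100)
  d_big <- dev(8000)
  expect_lt(d_big["cost"], 25)      # dollars, against a ~17k base
  expect_lt(d_big["qaly"], 0.002)
  expect_lt(d_big["cost"], d_small["cost"] + 25)
})

test_that("vectorised PSA engine agrees with the scalar cohort engine", {
  ps <- pmrt_parameters()
  set.seed(8)
  for (i in 1:3) {
    vals <- list(
      "strategies/IMRT/p_cardiac" = runif(1, 0.001, 0.02),
      "strategies/IMRT/p_cl_breast" = runif(1, 2e-4, 6e-4),
      "strategies/IMRT/p_lung" = runif(1, 0.001, 0.008),
      "utilities/cardiac" = runif(1, 0.8, 0.9),
      "utilities/cl_breast" = runif(1, 0.71, 0.81),
      "utilities/lung" = runif(1, 0.6, 0.85),
      "event_costs/cardiac" = runif(1, 8200, 14900),
      "event_costs/cl_breast" = runif(1, 13300, 15600),
      "event_costs/lung" = runif(1, 17900, 23300)
    )
    vec <- pmrtcea:::.simulate_many(
      ps, ps$strategies$IMRT, 1,
      vals[["strategies/IMRT/p_cardiac"]],
      vals[["strategies/IMRT/p_cl_breast"]],
      vals[["strategies/IMRT/p_lung"]],
      vals[["utilities/cardiac"]], vals[["utilities/cl_breast"]],
      vals[["utilities/lung"]],
      vals[["event_costs/cardiac"]], vals[["event_costs/cl_breast"]],
      vals[["event_costs/lung"]])
    ps2 <- ps
    for (p in names(vals)) ps2 <- set_parameter(ps2, p, vals[[p]])
    ref <- accumulate(run_cohort(ps2, "IMRT"), ps2, "IMRT")
    expect_equal(vec$cost, ref$cost, tolerance = 1e-10)
    expect_equal(vec$qaly, ref$qaly, tolerance = 1e-10)
  }
})

test_that("acceptability curves are monotone when the QALY gain is certain", {
  sc <- degenerate_scenarios()$two_strategy_known_icer
  # widen the alternative's advantage stochastically but keep it positive:
  # ALT is event-free, SOC always loses 0.1 * annuity QALYs
  sc$utilities$cl_breast <- ranged_value(0.8, 0.75, 0.85)
  sc$event_costs$cl_breast <- ranged_value(1000, 600, 1400)
  pr <- psa(sc, 500, seed = 6)
  cc <- ceac(pr, seq(0, 2000, by = 100))
  p <- cc$probability[cc$strategy == "ALT"]
  expect_true(all(diff(p) >= 0))
  # step location: base ICER ~ $431/QALY separates 0 from 1
  expect_equal(p[1], 0)                       # wtp 0: ALT costs more
  expect_equal(p[length(p)], 1)               # far above the ICER
})

test_that("with no uncertainty the CEAC is the base-case INMB step function", {
  sc <- degenerate_scenarios()$two_strategy_known_icer
  pr <- psa(sc, 20, seed = 1)
  expected_icer <- (1000 - 500 / 1.03) / (0.1 * annuity(15, 0.03))
  below <- floor(expected_icer) ; above <- ceiling(expected_icer) + 1
  cc <- ceac(pr, c(0, below, above, 1e5))
  p <- cc$probability[cc$strategy == "ALT"]
  expect_equal(p, c(0, 0, 1, 1))
})

test_that("a WTP of zero reduces the CEAC to a cost comparison", {
  ps <- pmrt_parameters()
  pr <- psa(ps, 400, seed = 13)
  cc <- ceac(pr, c(0))
  s <- pr$samples
  soc <- s[s$strategy == "SOC", ]
  for (nm in unique(cc$strategy)) {
    frac_cheaper <- mean(s[s$strategy == nm, "cost"] < soc$cost)
    expect_equal(cc$probability[cc$strategy == nm], frac_cheaper)
  }
  expect_error(ceac(pr, numeric(0)), "empty")
  expect_error(ceac(pr, c(2, 1)), "increasing")
})
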