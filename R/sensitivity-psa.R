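# Probabilistic sensitivity analysis (second-order Monte Carlo)
# -------------------------------------------------------------
# Every parameter with a published range gets a distribution: beta for
# probabilities and utilities, gamma for costs, parameterised by the method
# of moments with mean = base and sd = (high - low) / 4 (the range is read
# as an approximate 95% interval). Per iteration one joint parameter vector
# is drawn -- shared quantities (utilities, event costs) once and applied to
# all strategies, technique-specific late-effect probabilities per strategy
# -- and the full Markov model plus accumulation is rerun for every
# strategy.
#
# Draws are generated as a K x n uniform matrix filled column-major
# (iteration-major) and mapped through quantile functions, so iteration i
# always consumes the same RNG substream regardless of the total iteration
# count.

#' Parameter distributions for the probabilistic sensitivity analysis
#'
#' @param ps A [parameter_set()].
#' @return A list of `param_distribution` objects, one per
#'   [ranged_value()] in the set (utilities, event costs, and each
#'   strategy's late-effect probabilities), each with fields `target`,
#'   `family` (`"beta"`, `"gamma"` or `"degenerate"`), `mean`, `sd` and the
#'   family parameters.
#' @export
#' @examples
#' d <- build_distributions(pmrt_parameters())
#' d[[which(vapply(d, `[[`, character(1), "target") == "utilities/cardiac")]]
build_distributions <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  targets <- c(
    paste0("utilities/", c("ned", "recurrence", "metastasis",
                           "cardiac", "cl_breast", "lung")),
    paste0("event_costs/", c("recurrence", "metastasis", "cardiac",
                             "cl_breast", "lung")),
    unlist(lapply(names(ps$strategies), function(nm)
      sprintf("strategies/%s/%s", nm,
              c("p_cardiac", "p_cl_breast", "p_lung"))))
  )
  lapply(targets, function(tg) {
    rv <- get_parameter(ps, tg)
    m <- rv$base
    s <- (rv$high - rv$low) / 4
    if (s == 0) {
      return(structure(list(target = tg, family = "degenerate",
                            mean = m, sd = 0), class = "param_distribution"))
    }
    if (startsWith(tg, "event_costs/")) {
      # gamma by method of moments: shape = m^2/v, rate = m/v
      v <- s^2
      d <- list(target = tg, family = "gamma", mean = m, sd = s,
                shape = m^2 / v, rate = m / v)
    } else {
      # beta by method of moments; feasible iff v < m(1 - m)
      v <- s^2
      if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
        stop("cannot parameterise beta distribution for '", tg,
             "': mean ", m, ", sd ", s, " incompatible", call. = FALSE)
      }
      nu <- m * (1 - m) / v - 1
      d <- list(target = tg, family = "beta", mean = m, sd = s,
                shape1 = m * nu, shape2 = (1 - m) * nu)
    }
    structure(d, class = "param_distribution")
  })
}

#' @export
print.param_distribution <- function(x, ...) {
  cat(sprintf("<param_distribution> %s: %s(mean %.4g, sd %.4g)\n",
              x$target, x$family, x$mean, x$sd))
  invisible(x)
}

# Map uniforms through the quantile function of a distribution.
.sample_distribution <- function(d, u) {
  switch(d$family,
         degenerate = rep(d$mean, length(u)),
         beta = qbeta(u, d$shape1, d$shape2),
         gamma = qgamma(u, shape = d$shape, rate = d$rate),
         stop("unknown family ", d$family))
}

# Vectorised cohort simulation: propagates n parameter draws at once for one
# strategy. p_card/p_clb/p_lung are total window probabilities (length n or
# 1); u_* and c_* likewise. Returns discounted cost and QALY per draw.
# Must agree with run_cohort() + accumulate() draw by draw (tested).
.simulate_many <- function(ps, strategy, n, p_card, p_clb, p_lung,
                           u_card, u_clb, u_lung,
                           c_card, c_clb, c_lung) {
  H <- ps$settings$horizon
  w <- ps$settings$windows
  t <- seq_len(H)
  lr <- annual_probability(ps$disease$local_recurrence, t)
  met <- annual_probability(ps$disease$metastasis, t)
  metd <- annual_probability(ps$disease$metastasis_death, t)
  bg <- annual_probability(ps$mortality$background, t)
  hd <- annual_probability(ps$mortality$heart, t)
  cbd <- annual_probability(ps$mortality$cl_breast, t)
  lud <- annual_probability(ps$mortality$lung, t)
  lrp <- if (isTRUE(ps$settings$recurrence_progression)) met else rep(0, H)

  expand <- function(x) if (length(x) == n) x else rep(x, length.out = n)
  p_card <- expand(p_card); p_clb <- expand(p_clb); p_lung <- expand(p_lung)
  u_card <- expand(u_card); u_clb <- expand(u_clb); u_lung <- expand(u_lung)
  c_card <- expand(c_card); c_clb <- expand(c_clb); c_lung <- expand(c_lung)

  in_win <- function(win, tt) tt >= win[1] & tt <= win[2]
  len <- function(win) win[2] - win[1] + 1

  u <- ps$utilities
  ec <- ps$event_costs
  disc <- (1 + ps$settings$discount_rate)^-t
  half <- isTRUE(ps$settings$half_cycle)

  ned <- rep(1, n); lrS <- mets <- card <- clb <- lung <- numeric(n)
  dcan <- doth <- dtox <- numeric(n)
  qaly <- numeric(n)
  cost <- rep(strategy$rt_cost, n)
  util_prev <- rep(u$ned$base, n)  # utility-weighted occupancy at cycle 0

  for (tt in t) {
    pc <- if (in_win(w$cardiac, tt)) p_card / len(w$cardiac) else 0
    pb <- if (in_win(w$cl_breast, tt)) p_clb / len(w$cl_breast) else 0
    pl <- if (in_win(w$lung, tt)) p_lung / len(w$lung) else 0

    e_lr <- ned * lr[tt]
    e_met <- ned * met[tt] + lrS * lrp[tt]
    e_card <- ned * pc
    e_clb <- ned * pb
    e_lung <- ned * pl
    e_dcan <- mets * metd[tt]
    e_dtox <- card * hd[tt] + clb * cbd[tt] + lung * lud[tt]
    e_doth <- (ned + lrS + mets + card + clb + lung) * bg[tt]

    ned <- ned * (1 - lr[tt] - met[tt] - bg[tt]) - e_card - e_clb - e_lung
    lrS <- lrS * (1 - lrp[tt] - bg[tt]) + e_lr
    mets <- mets * (1 - metd[tt] - bg[tt]) + e_met
    card <- card * (1 - hd[tt] - bg[tt]) + e_card
    clb <- clb * (1 - cbd[tt] - bg[tt]) + e_clb
    lung <- lung * (1 - lud[tt] - bg[tt]) + e_lung
    dcan <- dcan + e_dcan
    doth <- doth + e_doth
    dtox <- dtox + e_dtox

    util <- ned * u$ned$base + lrS * u$recurrence$base +
      mets * u$metastasis$base + card * u_card + clb * u_clb + lung * u_lung
    qaly <- qaly + disc[tt] * (if (half) (util + util_prev) / 2 else util)
    util_prev <- util

    cost <- cost + disc[tt] *
      (e_lr * ec$recurrence$base + e_met * ec$metastasis$base +
         e_card * c_card + e_clb * c_clb + e_lung * c_lung)
  }
  list(cost = cost, qaly = qaly)
}

# Worst-case feasibility of the NED row over all cycles for drawn window
# probabilities; returns a logical vector of infeasible iterations.
.infeasible_draws <- function(ps, p_card, p_clb, p_lung) {
  H <- ps$settings$horizon
  w <- ps$settings$windows
  t <- seq_len(H)
  base_exit <- annual_probability(ps$disease$local_recurrence, t) +
    annual_probability(ps$disease$metastasis, t) +
    annual_probability(ps$mortality$background, t)
  bad <- rep(FALSE, length(p_card))
  for (tt in t) {
    ex <- base_exit[tt] +
      (if (tt >= w$cardiac[1] && tt <= w$cardiac[2])
        p_card / (w$cardiac[2] - w$cardiac[1] + 1) else 0) +
      (if (tt >= w$cl_breast[1] && tt <= w$cl_breast[2])
        p_clb / (w$cl_breast[2] - w$cl_breast[1] + 1) else 0) +
      (if (tt >= w$lung[1] && tt <= w$lung[2])
        p_lung / (w$lung[2] - w$lung[1] + 1) else 0)
    bad <- bad | ex > 1
  }
  bad
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: draws `n_iterations` joint parameter vectors
#' from the distributions of [build_distributions()] and reruns the full
#' Markov model and cost/QALY accumulation for every strategy under each
#' draw. Shared parameters (utilities, event costs) are drawn once per
#' iteration and applied to all strategies; technique-specific late-effect
#' probabilities are drawn independently per strategy. Draws that would make
#' a transition-matrix row infeasible are rejected and redrawn (the count is
#' reported).
#'
#' @param ps A [parameter_set()].
#' @param n_iterations Number of Monte Carlo iterations.
#' @param seed Integer seed; the same seed and iteration count reproduce the
#'   samples bit for bit.
#' @return An object of class `psa_result`: list with `samples` (data.frame
#'   `iteration`, `strategy`, `cost`, `qaly` in long form), `n_iterations`,
#'   `seed`, `n_redrawn`.
#' @seealso [ceac()], [psa_summary()]
#' @export
#' @examples
#' p <- psa(pmrt_parameters(), 100, seed = 1)
#' head(p$samples)
psa <- function(ps, n_iterations, seed) {
  stopifnot(inherits(ps, "parameter_set"),
            n_iterations >= 1, is.numeric(seed))
  set.seed(as.integer(seed))
  n <- as.integer(n_iterations)
  dists <- build_distributions(ps)
  names(dists) <- vapply(dists, `[[`, character(1), "target")
  varied <- dists[vapply(dists, function(d) d$family != "degenerate", logical(1))]
  K <- length(varied)

  draw_all <- function(m) {
    if (K == 0L) return(list())
    U <- matrix(runif(K * m), nrow = K)  # column-major: one column per iteration
    out <- lapply(seq_len(K), function(k) .sample_distribution(varied[[k]], U[k, ]))
    names(out) <- names(varied)
    out
  }
  draws <- draw_all(n)
  value_of <- function(target, idx = NULL) {
    if (!is.null(draws[[target]])) {
      if (is.null(idx)) draws[[target]] else draws[[target]][idx]
    } else {
      dists[[target]]$mean
    }
  }

  # reject-and-redraw iterations with an infeasible row for any strategy
  n_redrawn <- 0L
  for (round in seq_len(100L)) {
    bad <- rep(FALSE, n)
    for (nm in names(ps$strategies)) {
      bad <- bad | .infeasible_draws(
        ps,
        value_of(sprintf("strategies/%s/p_cardiac", nm)),
        value_of(sprintf("strategies/%s/p_cl_breast", nm)),
        value_of(sprintf("strategies/%s/p_lung", nm)))
    }
    if (!any(bad)) break
    idx <- which(bad)
    n_redrawn <- n_redrawn + length(idx)
    redraw <- draw_all(length(idx))
    for (nm in names(redraw)) draws[[nm]][idx] <- redraw[[nm]]
  }

  samples <- lapply(names(ps$strategies), function(nm) {
    st <- ps$strategies[[nm]]
    sim <- .simulate_many(
      ps, st, n,
      p_card = value_of(sprintf("strategies/%s/p_cardiac", nm)),
      p_clb = value_of(sprintf("strategies/%s/p_cl_breast", nm)),
      p_lung = value_of(sprintf("strategies/%s/p_lung", nm)),
      u_card = value_of("utilities/cardiac"),
      u_clb = value_of("utilities/cl_breast"),
      u_lung = value_of("utilities/lung"),
      c_card = value_of("event_costs/cardiac"),
      c_clb = value_of("event_costs/cl_breast"),
      c_lung = value_of("event_costs/lung"))
    data.frame(iteration = seq_len(n), strategy = nm,
               cost = sim$cost, qaly = sim$qaly)
  })
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  structure(list(samples = samples, n_iterations = n, seed = as.integer(seed),
                 n_redrawn = n_redrawn),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations x %d strategies (seed %d, %d redrawn)\n",
              x$n_iterations, length(unique(x$samples$strategy)), x$seed,
              x$n_redrawn))
  agg <- aggregate(cbind(cost, qaly) ~ strategy, data = x$samples, FUN = mean)
  agg$cost <- round(agg$cost)
  agg$qaly <- round(agg$qaly, 3)
  print.data.frame(agg, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curve versus the reference strategy
#'
#' For each willingness-to-pay threshold and each strategy other than SOC,
#' the probability of being more cost-effective than SOC is the fraction of
#' iterations in which the strategy's net monetary benefit
#' (WTP x QALY - cost) exceeds SOC's.
#'
#' @param psa_result A [psa()] result.
#' @param wtp_grid Strictly increasing vector of WTP thresholds (USD/QALY).
#' @return A data.frame of class `ceac_curve` with columns `wtp`,
#'   `strategy`, `probability`.
#' @export
#' @examples
#' p <- psa(pmrt_parameters(), 200, seed = 1)
#' ceac(p, c(0, 50000, 100000))
ceac <- function(psa_result, wtp_grid) {
  stopifnot(inherits(psa_result, "psa_result"))
  if (length(wtp_grid) == 0L) stop("empty WTP grid", call. = FALSE)
  if (is.unsorted(wtp_grid, strictly = TRUE))
    stop("WTP grid must be strictly increasing", call. = FALSE)
  s <- psa_result$samples
  ref <- s[s$strategy == "SOC", ]
  ref <- ref[order(ref$iteration), ]
  others <- setdiff(unique(s$strategy), "SOC")
  out <- do.call(rbind, lapply(others, function(nm) {
    x <- s[s$strategy == nm, ]
    x <- x[order(x$iteration), ]
    probs <- vapply(wtp_grid, function(l)
      mean(l * x$qaly - x$cost > l * ref$qaly - ref$cost), numeric(1))
    data.frame(wtp = wtp_grid, strategy = nm, probability = probs)
  }))
  rownames(out) <- NULL
  structure(out, class = c("ceac_curve", "data.frame"))
}

#' Acceptability summary at selected WTP thresholds
#'
#' @param psa_result A [psa()] result.
#' @param wtp WTP thresholds (default the two conventional ones, $50,000 and
#'   $100,000 per QALY).
#' @return A data.frame with one row per threshold and one column per
#'   non-reference strategy giving the probability (in %) of being more
#'   cost-effective than SOC.
#' @export
psa_summary <- function(psa_result, wtp = c(50000, 100000)) {
  cc <- ceac(psa_result, sort(wtp))
  wide <- reshape(as.data.frame(cc), idvar = "wtp", timevar = "strategy",
                  direction = "wide")
  names(wide) <- sub("^probability\\.", "", names(wide))
  for (j in seq_along(wide)[-1]) wide[[j]] <- 100 * wide[[j]]
  rownames(wide) <- NULL
  wide
}
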