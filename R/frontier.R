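# Dominance and the cost-effectiveness frontier
# ---------------------------------------------
# Strategies are listed in order of increasing cost. A strategy is dominated
# when some other strategy costs no more and yields no fewer QALYs, with at
# least one strict inequality. ICERs are computed between consecutive
# non-dominated strategies in cost order. An extended-dominance pass
# (removal of strategies whose ICER exceeds that of the next, more effective
# frontier member) is available but off by default.

#' Cost-effectiveness frontier with dominance flags and ICERs
#'
#' @param results A list of [accumulate()] results, or a data.frame with
#'   columns `strategy`, `cost`, `qaly`.
#' @param extended Also apply extended dominance (default `FALSE`).
#' @return A data.frame of class `frontier_result`, sorted by ascending
#'   cost, with columns `strategy`, `cost`, `qaly`, `dominated`,
#'   `dominated_by` (`NA` for frontier members) and `icer` (`NA` for the
#'   cheapest frontier member and for dominated strategies). Extended
#'   dominance, when applied, is reported in `dominated_by` as
#'   `"extended dominance"`.
#' @export
#' @examples
#' tab <- data.frame(
#'   strategy = c("SOC", "A", "B"),
#'   cost = c(15352, 19131, 20267),
#'   qaly = c(9.214, 9.330, 9.314)
#' )
#' frontier(tab)
frontier <- function(results, extended = FALSE) {
  if (is.data.frame(results)) {
    stopifnot(all(c("strategy", "cost", "qaly") %in% names(results)))
    tab <- results[, c("strategy", "cost", "qaly")]
  } else {
    tab <- data.frame(
      strategy = vapply(results, `[[`, character(1), "strategy"),
      cost = vapply(results, `[[`, numeric(1), "cost"),
      qaly = vapply(results, `[[`, numeric(1), "qaly")
    )
  }
  if (anyDuplicated(tab$strategy))
    stop("frontier: strategy labels must be distinct", call. = FALSE)
  n <- nrow(tab)
  tab <- tab[order(tab$cost, -tab$qaly), ]
  rownames(tab) <- NULL

  tab$dominated <- FALSE
  tab$dominated_by <- NA_character_
  for (i in seq_len(n)) {
    dom <- tab$cost <= tab$cost[i] & tab$qaly >= tab$qaly[i] &
      (tab$cost < tab$cost[i] | tab$qaly > tab$qaly[i])
    if (any(dom)) {
      tab$dominated[i] <- TRUE
      cand <- which(dom)
      best <- cand[order(-tab$qaly[cand], tab$cost[cand])][1]
      tab$dominated_by[i] <- tab$strategy[best]
    }
  }

  if (isTRUE(extended)) {
    repeat {
      idx <- which(!tab$dominated)
      if (length(idx) < 3L) break
      ic <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
      worse <- which(ic[-length(ic)] > ic[-1])  # ICER above the next one's
      if (length(worse) == 0L) break
      drop <- idx[worse[1] + 1L]
      tab$dominated[drop] <- TRUE
      tab$dominated_by[drop] <- "extended dominance"
    }
  }

  tab$icer <- NA_real_
  idx <- which(!tab$dominated)
  if (length(idx) > 1L) {
    tab$icer[idx[-1]] <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
  }
  structure(tab, class = c("frontier_result", "data.frame"))
}

#' @export
print.frontier_result <- function(x, ...) {
  out <- data.frame(
    strategy = x$strategy,
    cost = format(round(x$cost), big.mark = ","),
    qaly = sprintf("%.3f", x$qaly),
    icer = ifelse(
      x$dominated, paste("dominated by", x$dominated_by),
      ifelse(is.na(x$icer), "-", format(round(x$icer), big.mark = ","))
    )
  )
  names(out) <- c("Strategy", "Cost ($)", "QALY", "ICER ($/QALY)")
  print.data.frame(out, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Non-dominated strategies of a frontier in cost order
#'
#' @param x A [frontier()] result.
#' @return Character vector of strategy labels on the frontier.
#' @export
frontier_strategies <- function(x) {
  stopifnot(inherits(x, "frontier_result"))
  x$strategy[!x$dominated]
}
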