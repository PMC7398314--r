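# Shared fixtures and closed forms used across the suite.

# Discounted annuity over the horizon: the QALY of a cohort that never
# leaves the well state (utility 1).
annuity <- function(horizon = 15, rate = 0.03) {
  sum((1 + rate)^-(seq_len(horizon)))
}

# Published base-case cost/QALY table used by the ICER-arithmetic and
# dominance tests (costs in USD, QALYs discounted years).
published_base_case <- function() {
  data.frame(
    strategy = c("SOC", "STD-VMAT", "TOMO", "IMRT", "MA-VMAT", "NC-VMAT",
                 "MIXED", "IMPT"),
    cost = c(15352, 19131, 20267, 20543, 20617, 20633, 22985, 38145),
    qaly = c(9.214, 9.330, 9.314, 9.404, 9.365, 9.402, 9.385, 9.520)
  )
}

# Independent O(n^2) dominance scan, written separately from frontier():
# a strategy is dominated when any other strategy costs no more and yields
# no fewer QALYs, with at least one strict inequality.
brute_force_dominated <- function(tab) {
  vapply(seq_len(nrow(tab)), function(i) {
    any(vapply(seq_len(nrow(tab)), function(j) {
      if (i == j) return(FALSE)
      (tab$cost[j] <= tab$cost[i] && tab$qaly[j] >= tab$qaly[i]) &&
        (tab$cost[j] < tab$cost[i] || tab$qaly[j] > tab$qaly[i])
    }, logical(1)))
  }, logical(1))
}
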