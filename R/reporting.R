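# Report writers
# --------------
# Each report writes a delimited table plus a machine-readable JSON twin and
# a provenance record (parameter-file hash, seed, conventions, package
# version). Display rounding: dollars to the nearest dollar, QALYs to three
# decimals, probabilities to one decimal percent; JSON keeps full precision.

.provenance <- function(ps, extra = list()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameters(ps, tmp)
  c(list(
    package = "pmrtcea",
    version = as.character(utils::packageVersion("pmrtcea")),
    parameter_hash = unname(tools::md5sum(tmp)),
    horizon = ps$settings$horizon,
    discount_rate = ps$settings$discount_rate,
    half_cycle = ps$settings$half_cycle,
    recurrence_progression = ps$settings$recurrence_progression,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), extra)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write the base-case report
#'
#' Runs every strategy, writes the cost/QALY/ICER table (`base_case.csv`
#' and `base_case.json`), the survival validation summary under the
#' reference strategy (`survival.json`), and a provenance record.
#'
#' @param ps A [parameter_set()].
#' @param dir Output directory (created if missing).
#' @return The [frontier()] result, invisibly.
#' @export
report_base_case <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fr <- run_base_case(ps)
  tab <- as.data.frame(fr)
  tab_disp <- transform(tab, cost = round(cost), qaly = round(qaly, 3),
                        icer = round(icer))
  write.csv(tab_disp, file.path(dir, "base_case.csv"), row.names = FALSE,
            na = "")
  .write_json(tab, file.path(dir, "base_case.json"))
  surv <- survival_summary(run_cohort(ps, "SOC"))
  .write_json(surv, file.path(dir, "survival.json"))
  .write_json(.provenance(ps), file.path(dir, "provenance.json"))
  invisible(fr)
}

#' Write the tornado report
#'
#' One-way sweeps of all nine range-carrying parameters for each
#' non-reference strategy (`tornado.csv` / `tornado.json`), bars sorted by
#' width within each strategy.
#'
#' @inheritParams report_base_case
#' @return A data.frame with all strategies' tornado rows, invisibly.
#' @export
report_tornado <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strategies <- setdiff(names(ps$strategies), "SOC")
  rows <- do.call(rbind, lapply(strategies, function(nm) {
    tor <- tornado(ps, nm)
    cbind(strategy = nm, as.data.frame(tor))
  }))
  rownames(rows) <- NULL
  write.csv(transform(rows, icer_low = round(icer_low),
                      icer_base = round(icer_base),
                      icer_high = round(icer_high), width = round(width)),
            file.path(dir, "tornado.csv"), row.names = FALSE)
  .write_json(rows, file.path(dir, "tornado.json"))
  .write_json(.provenance(ps), file.path(dir, "provenance.json"))
  invisible(rows)
}

#' Write the PSA report
#'
#' Runs the probabilistic sensitivity analysis, writes the per-iteration
#' samples (`psa_samples.csv`), the acceptability curves over the WTP grid
#' (`ceac.csv` / `ceac.json`), the acceptability summary at $50,000 and
#' $100,000 per QALY (`psa_summary.csv`), and a provenance record including
#' the seed.
#'
#' @inheritParams report_base_case
#' @param n_iterations,seed Passed to [psa()].
#' @param wtp_grid WTP thresholds for the acceptability curves.
#' @return The [psa()] result, invisibly.
#' @export
report_psa <- function(ps, dir, n_iterations = 10000, seed = 1,
                       wtp_grid = seq(0, 150000, by = 5000)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pr <- psa(ps, n_iterations, seed)
  write.csv(pr$samples, file.path(dir, "psa_samples.csv"), row.names = FALSE)
  cc <- ceac(pr, wtp_grid)
  write.csv(as.data.frame(cc), file.path(dir, "ceac.csv"), row.names = FALSE)
  .write_json(as.data.frame(cc), file.path(dir, "ceac.json"))
  write.csv(psa_summary(pr), file.path(dir, "psa_summary.csv"),
            row.names = FALSE)
  .write_json(.provenance(ps, list(seed = pr$seed,
                                   n_iterations = pr$n_iterations,
                                   n_redrawn = pr$n_redrawn)),
              file.path(dir, "provenance.json"))
  invisible(pr)
}

#' Export a cohort trace as a tidy table
#'
#' @param trace A [run_cohort()] result.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE, na = "")
  invisible(path)
}
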