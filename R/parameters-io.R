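# YAML parameter file format
# --------------------------
# Sections: settings / strategies / disease / mortality / utilities / costs.
# Every probability-like scalar is a map {base, low, high, scale} where
# scale is "percent" or "fraction" (default "fraction"); low/high default to
# base. Schedules are {bands: [{start, end, value, scale, convention}], default}.
# The bundled reference file (inst/extdata) stores percentages exactly as
# published; write_parameters() always writes fractions so that a
# write -> load round trip reproduces the in-memory object exactly.

# Numeric leaves may arrive as quoted 17-digit strings (written by
# write_parameters for doubles whose decimal form needs more precision than
# the YAML emitter keeps); accept both.
.num <- function(x) if (is.character(x)) as.numeric(x) else x

.unscale <- function(x, scale, path) {
  x <- .num(x)
  if (is.null(scale) || identical(scale, "fraction")) return(x)
  if (identical(scale, "percent")) return(x / 100)
  stop("invalid parameter file at ", path,
       ": unknown scale '", scale, "'", call. = FALSE)
}

.parse_ranged <- function(node, path, unit = c("fraction", "raw")) {
  unit <- match.arg(unit)
  if (is.numeric(node) && length(node) == 1L) node <- list(base = node)
  if (!is.list(node) || is.null(node$base))
    stop("invalid parameter file at ", path, ": expected {base, low, high}",
         call. = FALSE)
  f <- function(v) {
    if (unit == "fraction") .unscale(v, node$scale, path) else .num(v)
  }
  out <- tryCatch(
    ranged_value(f(node$base),
                 if (is.null(node$low)) f(node$base) else f(node$low),
                 if (is.null(node$high)) f(node$base) else f(node$high)),
    error = function(e) stop("invalid parameter file at ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  out
}

.parse_schedule <- function(node, path) {
  if (is.null(node))
    stop("invalid parameter file at ", path, ": missing schedule", call. = FALSE)
  bands <- lapply(seq_along(node$bands), function(i) {
    b <- node$bands[[i]]
    bp <- paste0(path, "/bands[", i, "]")
    for (f in c("start", "end", "value")) {
      if (is.null(b[[f]]))
        stop("invalid parameter file at ", bp, ": missing '", f, "'",
             call. = FALSE)
    }
    tryCatch(
      year_band(.num(b$start), .num(b$end), .unscale(b$value, b$scale, bp),
                convention = if (is.null(b$convention)) "period_cumulative"
                             else b$convention),
      error = function(e) stop("invalid parameter file at ", bp, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  default <- if (is.null(node$default)) 0 else .unscale(node$default, node$scale, path)
  tryCatch(transition_schedule(bands, default = default),
           error = function(e) stop("invalid parameter file at ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Load a parameter set from a YAML file
#'
#' Reads and fully validates a model parameter file; every invariant
#' violation is reported with the path of the offending entry. Percentages
#' (entries tagged `scale: percent`) are converted to fractions on load.
#'
#' @param path Path to a YAML parameter file.
#' @return A validated [parameter_set()].
#' @seealso [write_parameters()], [pmrt_parameters()]
#' @export
load_parameters <- function(path) {
  doc <- yaml::read_yaml(path)
  for (sec in c("strategies", "disease", "mortality", "utilities", "costs")) {
    if (is.null(doc[[sec]]))
      stop("invalid parameter file at ", sec, ": missing section", call. = FALSE)
  }

  strategies <- lapply(seq_along(doc$strategies), function(i) {
    st <- doc$strategies[[i]]
    sp <- paste0("strategies[", i, "]")
    if (is.null(st$name))
      stop("invalid parameter file at ", sp, ": missing 'name'", call. = FALSE)
    for (f in c("rt_cost", "p_cardiac", "p_cl_breast", "p_lung")) {
      if (is.null(st[[f]]))
        stop("invalid parameter file at ", sp, "/", f, ": missing", call. = FALSE)
    }
    tryCatch(
      strategy_spec(st$name, .num(st$rt_cost),
                    p_cardiac = .parse_ranged(st$p_cardiac, paste0(sp, "/p_cardiac")),
                    p_cl_breast = .parse_ranged(st$p_cl_breast, paste0(sp, "/p_cl_breast")),
                    p_lung = .parse_ranged(st$p_lung, paste0(sp, "/p_lung"))),
      error = function(e) stop("invalid parameter file at ", sp, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })

  disease <- lapply(setNames(nm = c("local_recurrence", "metastasis",
                                    "metastasis_death")), function(nm)
    .parse_schedule(doc$disease[[nm]], paste0("disease/", nm)))
  mortality <- lapply(setNames(nm = c("background", "heart", "cl_breast",
                                      "lung")), function(nm)
    .parse_schedule(doc$mortality[[nm]], paste0("mortality/", nm)))
  utilities <- lapply(setNames(nm = c("ned", "recurrence", "metastasis",
                                      "cardiac", "cl_breast", "lung")), function(nm) {
    if (is.null(doc$utilities[[nm]]))
      stop("invalid parameter file at utilities/", nm, ": missing", call. = FALSE)
    .parse_ranged(doc$utilities[[nm]], paste0("utilities/", nm))
  })
  event_costs <- lapply(setNames(nm = c("recurrence", "metastasis", "cardiac",
                                        "cl_breast", "lung")), function(nm) {
    if (is.null(doc$costs[[nm]]))
      stop("invalid parameter file at costs/", nm, ": missing", call. = FALSE)
    .parse_ranged(doc$costs[[nm]], paste0("costs/", nm), unit = "raw")
  })

  settings <- doc$settings
  if (!is.null(settings$windows))
    settings$windows <- lapply(settings$windows, as.integer)

  parameter_set(strategies, disease, mortality, utilities, event_costs,
                settings = if (is.null(settings)) list() else settings)
}

.emit_ranged <- function(rv) {
  out <- list(base = rv$base)
  if (!is_degenerate(rv)) { out$low <- rv$low; out$high <- rv$high }
  out
}

.emit_schedule <- function(sch) {
  out <- list(bands = lapply(sch$bands, function(b)
    list(start = b$start, end = b$end, value = b$value,
         convention = b$convention)))
  if (sch$default != 0) out$default <- sch$default
  out
}


# Recursively replace doubles that the YAML emitter cannot represent
# losslessly at 15 significant digits with quoted 17-digit strings, which
# .num() parses back bit-exactly on load.
.quote_exact <- function(x) {
  if (is.list(x)) return(lapply(x, .quote_exact))
  if (is.double(x)) {
    out <- as.list(x)
    for (i in seq_along(out)) {
      v <- out[[i]]
      emitted <- yaml::yaml.load(yaml::as.yaml(v, precision = 15L))
      if (is.finite(v) && !identical(as.numeric(emitted), v)) {
        out[[i]] <- sprintf("%.17g", v)
      }
    }
    if (length(out) == 1L) return(out[[1L]])
    return(out)
  }
  x
}

#' Write a parameter set to a YAML file
#'
#' The writer emits all probabilities as fractions (`scale` omitted), so
#' `load_parameters(write_parameters(ps, f))` reproduces `ps` exactly.
#'
#' @param ps A [parameter_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  s <- ps$settings
  doc <- list(
    settings = list(
      discount_rate = s$discount_rate, horizon = s$horizon,
      start_age = s$start_age, cycle_length = s$cycle_length,
      half_cycle = s$half_cycle,
      recurrence_progression = s$recurrence_progression,
      windows = lapply(s$windows, as.integer)
    ),
    strategies = lapply(unname(ps$strategies), function(st)
      list(name = st$name, rt_cost = st$rt_cost,
           p_cardiac = .emit_ranged(st$p_cardiac),
           p_cl_breast = .emit_ranged(st$p_cl_breast),
           p_lung = .emit_ranged(st$p_lung))),
    disease = lapply(ps$disease, .emit_schedule),
    mortality = lapply(ps$mortality, .emit_schedule),
    utilities = lapply(ps$utilities, .emit_ranged),
    costs = lapply(ps$event_costs, .emit_ranged)
  )
  # 17 significant digits round-trip IEEE doubles losslessly
  doc <- .quote_exact(doc)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' The bundled reference parameter set
#'
#' Loads the parameter file shipped with the package: the published
#' transition probabilities, utilities and costs for a 55-year-old
#' post-mastectomy cohort treated with one of eight radiotherapy techniques
#' (SOC, IMRT, STD-VMAT, NC-VMAT, MA-VMAT, TOMO, MIXED, IMPT), a 15-year
#' horizon and a 3% annual discount rate.
#'
#' @return A validated [parameter_set()] with 8 strategies.
#' @export
#' @examples
#' ps <- pmrt_parameters()
#' names(ps$strategies)
pmrt_parameters <- function() {
  load_parameters(system.file("extdata", "pmrt_reference.yaml",
                              package = "pmrtcea", mustWork = TRUE))
}
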