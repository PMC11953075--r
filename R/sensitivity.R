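# Univariate (tornado) and probabilistic sensitivity analyses.
#
# Table-valued inputs (onset, progression, mortality) are varied through a
# single multiplicative factor applied to the whole table, preserving the
# age/grade shape; scalar inputs (regression, clinical detection,
# sensitivity, participation) are varied directly.  Bounds are
# user-supplied; the shipped `intervals_example.csv` carries illustrative
# +/-10% bounds.

.param_kind <- c(onset = "multiplier", progression = "multiplier",
                 mortality = "multiplier", regression = "scalar",
                 clinical = "scalar", sensitivity = "scalar",
                 participation = "scalar")

#' Base value of a sensitivity parameter in a scenario
#'
#' Multiplier parameters (`onset`, `progression`, `mortality`) have base
#' value 1; scalar parameters return the scenario's value.  For
#' `regression` the three grades must share one value to be varied as a
#' scalar.
#'
#' @param scn a `dcis_scenario`.
#' @param parameter one of `onset`, `progression`, `mortality`
#'   (multipliers), `regression`, `clinical`, `sensitivity`,
#'   `participation` (scalars).
#' @return the base value.
#' @export
parameter_base <- function(scn, parameter) {
  parameter <- match.arg(parameter, names(.param_kind))
  if (.param_kind[[parameter]] == "multiplier") return(1)
  switch(parameter,
    regression = {
      if (length(unique(scn$regression)) != 1L)
        stop("regression varies by grade; cannot vary it as one scalar")
      scn$regression[1]
    },
    clinical = scn$clinical,
    sensitivity = ,
    participation = {
      if (is.null(scn$screening)) stop("scenario has no screening policy")
      scn$screening[[parameter]]
    })
}

#' Apply one sensitivity-parameter value to a scenario
#'
#' @param scn a `dcis_scenario`.
#' @param parameter parameter name, see [parameter_base()].
#' @param value multiplier (table parameters) or replacement value (scalar
#'   parameters).  Mortality probabilities are capped at 1 after scaling.
#' @return the modified, re-validated scenario.
#' @export
apply_parameter <- function(scn, parameter, value) {
  parameter <- match.arg(parameter, names(.param_kind))
  scale_bands <- function(b) {
    if (is.null(b)) return(NULL)
    for (g in c("g1", "g2", "g3")) b[[g]] <- b[[g]] * value
    b
  }
  switch(parameter,
    onset = {
      scn$onset <- scn$onset * value
      scn$bands$onset <- scale_bands(scn$bands$onset)
    },
    progression = {
      scn$progression <- scn$progression * value
      scn$bands$progression <- scale_bands(scn$bands$progression)
    },
    mortality = {
      scn$life <- pmin(scn$life * value, 1)
      scn$bands$life <- NULL
    },
    regression = scn$regression <- rep(value, 3L),
    clinical = scn$clinical <- value,
    sensitivity = scn$screening$sensitivity <- value,
    participation = scn$screening$participation <- value)
  validate_scenario(scn)
  scn
}

#' Read or validate a table of sensitivity intervals
#'
#' @param x a data.frame or CSV path with columns `parameter`, `low`,
#'   `high`.
#' @param scn optional scenario; when given, each interval is checked to
#'   bracket the scenario's base value.
#' @return the validated data.frame.
#' @export
dcis_intervals <- function(x, scn = NULL) {
  iv <- if (is.character(x)) read.csv(x) else x
  if (!all(c("parameter", "low", "high") %in% names(iv)))
    stop("intervals need columns parameter, low, high")
  bad <- setdiff(iv$parameter, names(.param_kind))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(iv$parameter))
    stop("duplicated parameter in intervals")
  if (!is.null(scn)) {
    for (i in seq_len(nrow(iv))) {
      b <- parameter_base(scn, iv$parameter[i])
      if (iv$low[i] > b || iv$high[i] < b)
        stop("interval for `", iv$parameter[i], "` (", iv$low[i], ", ",
             iv$high[i], ") does not bracket the base value ", b)
    }
  }
  iv
}

# Outcomes of one scenario: screen- and all-detection rates per 1,000
# examinations, fate fractions and screen-detected grade fractions.
.scenario_outcomes <- function(scn, engine, women, iterations, seed) {
  x <- if (engine == "expect") dcis_expect(scn)
       else dcis_simulate(scn, women = women, iterations = iterations,
                          seed = seed)
  fd <- fate_distribution(x)
  scr <- if (inherits(x, "dcis_expect")) sum(x$screens) else sum(x$mamm)
  det <- if (inherits(x, "dcis_expect")) sum(x$det) else sum(x$det)
  clin <- if (inherits(x, "dcis_expect")) sum(x$fate_mass["clin_detected", ])
          else sum(x$fates[, "clin_detected", ])
  gd <- grade_distribution(x)
  c(screen_rate = 1000 * det / scr,
    all_rate = 1000 * (det + clin) / scr,
    setNames(fd$fraction, paste0("fate_", fd$fate)),
    setNames(gd$fraction, paste0("grade", 1:3, "_screen_detected")))
}

#' Univariate sensitivity analysis (tornado)
#'
#' Re-evaluates the scenario with each parameter set to its lower and
#' upper bound, all other parameters at base.  With `engine = "simulate"`
#' the low, high and base runs share the same seeds (common random
#' numbers), so differences are due to the varied parameter only;
#' `engine = "expect"` evaluates the deterministic expectation oracle and
#' is noise-free.
#'
#' @param scn the base `dcis_scenario`.
#' @param intervals see [dcis_intervals()]; each interval must bracket the
#'   base value.
#' @param engine `"simulate"` or `"expect"`.
#' @param women,iterations,seed simulation controls (defaults from the
#'   scenario); ignored for the expectation engine.
#' @return a `dcis_usa` data.frame, one row per parameter ordered by
#'   tornado spread (largest first): bounds, screen-detection rate at
#'   base/low/high, deltas, and `spread` (largest absolute delta).
#' @export
dcis_usa <- function(scn, intervals, engine = c("simulate", "expect"),
                     women = NULL, iterations = NULL, seed = NULL) {
  engine <- match.arg(engine)
  iv <- dcis_intervals(intervals, scn)
  base_out <- .scenario_outcomes(scn, engine, women, iterations,
                                 if (is.null(seed)) scn$seed else seed)
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    p <- iv$parameter[i]
    lo <- .scenario_outcomes(apply_parameter(scn, p, iv$low[i]), engine,
                             women, iterations,
                             if (is.null(seed)) scn$seed else seed)
    hi <- .scenario_outcomes(apply_parameter(scn, p, iv$high[i]), engine,
                             women, iterations,
                             if (is.null(seed)) scn$seed else seed)
    data.frame(parameter = p, low = iv$low[i], high = iv$high[i],
               base_rate = base_out[["screen_rate"]],
               rate_low = lo[["screen_rate"]],
               rate_high = hi[["screen_rate"]],
               delta_low = lo[["screen_rate"]] - base_out[["screen_rate"]],
               delta_high = hi[["screen_rate"]] - base_out[["screen_rate"]],
               all_rate_low = lo[["all_rate"]],
               all_rate_high = hi[["all_rate"]])
  })
  out <- do.call(rbind, rows)
  out$spread <- pmax(abs(out$delta_low), abs(out$delta_high))
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, class = c("dcis_usa", "data.frame"), engine = engine)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_scenarios` parameter vectors independently and uniformly
#' within the intervals, evaluates each resulting scenario, and collects
#' detection rates, fate fractions and grade fractions per scenario.  The
#' sampled design is fully determined by `(seed, intervals)`.
#'
#' @inheritParams dcis_usa
#' @param n_scenarios number of random scenarios (default 100).
#' @param seed seed for the design draw and the per-scenario child seeds.
#' @return a `dcis_psa` list with `design` (sampled parameter values per
#'   scenario plus the child seed used) and `outcomes` (one row per
#'   scenario).
#' @export
dcis_psa <- function(scn, intervals, n_scenarios = 100L, seed = 1L,
                     engine = c("simulate", "expect"),
                     women = NULL, iterations = NULL) {
  engine <- match.arg(engine)
  iv <- dcis_intervals(intervals, scn)
  set.seed(seed)
  p <- nrow(iv)
  u <- matrix(runif(n_scenarios * p), n_scenarios, p)
  design <- as.data.frame(
    sweep(sweep(u, 2, iv$high - iv$low, "*"), 2, iv$low, "+"))
  names(design) <- iv$parameter
  design$scenario <- seq_len(n_scenarios)
  design$seed <- vapply(seq_len(n_scenarios),
                        function(j) .child_seed(seed, j), 1L)
  outcomes <- lapply(seq_len(n_scenarios), function(j) {
    s <- scn
    for (i in seq_len(p))
      s <- apply_parameter(s, iv$parameter[i], design[[iv$parameter[i]]][j])
    as.data.frame(as.list(.scenario_outcomes(
      s, engine, women, iterations, design$seed[j])))
  })
  outcomes <- cbind(scenario = seq_len(n_scenarios),
                    do.call(rbind, outcomes))
  structure(list(design = design[, c("scenario", "seed", iv$parameter)],
                 outcomes = outcomes, seed = seed, engine = engine),
            class = "dcis_psa")
}

#' @export
print.dcis_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d scenarios (engine %s, seed %d)\n",
              nrow(x$outcomes), x$engine, x$seed))
  r <- x$outcomes$screen_rate
  cat(sprintf("  screen-detection rate: median %.2f, range %.2f-%.2f per 1,000 (spread %.0f%%)\n",
              median(r), min(r), max(r),
              100 * (max(r) - min(r)) / median(r)))
  invisible(x)
}

#' @export
plot.dcis_psa <- function(x, ...) {
  fd <- x$outcomes[, grep("^fate_", names(x$outcomes))]
  names(fd) <- sub("^fate_", "", names(fd))
  boxplot(100 * fd, ylab = "percentage of total DCIS", las = 2, ...)
  invisible(x)
}

#' @export
plot.dcis_usa <- function(x, ...) {
  op <- par(mar = c(4, 9, 1, 1)); on.exit(par(op))
  n <- nrow(x)
  ord <- rev(seq_len(n))  # largest spread on top
  barplot(rbind(x$delta_low[ord], x$delta_high[ord]), beside = TRUE,
          horiz = TRUE, names.arg = x$parameter[ord], las = 1,
          col = c("steelblue", "firebrick"),
          xlab = "change in screen-detection rate per 1,000 screens", ...)
  legend("bottomright", c("lower bound", "upper bound"),
         fill = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Long-format export of PSA fate distributions
#'
#' Box-plot-ready data: one row per scenario and fate.
#'
#' @param x a `dcis_psa`.
#' @return data.frame with `scenario`, `fate`, `fraction`.
#' @export
psa_fate_long <- function(x) {
  fd <- x$outcomes[, grep("^fate_", names(x$outcomes))]
  data.frame(scenario = rep(x$outcomes$scenario, times = ncol(fd)),
             fate = rep(sub("^fate_", "", names(fd)), each = nrow(fd)),
             fraction = unlist(fd, use.names = FALSE))
}
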