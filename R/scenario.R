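# Scenario construction, file IO and validation.
#
# All probabilities are stored internally as plain per-year probabilities.
# The delimited fixture files keep the printed units of the source tables
# (mortality x 1e-2, onset x 1e-3, progression as printed); scaling happens
# once, at load time.

#' Expand a banded life table to per-year death probabilities
#'
#' Mortality is commonly published as per-band endpoint values.  Within each
#' band the endpoints are pinned to the band's first and last integer age and
#' intermediate ages are log-linearly interpolated, reflecting the
#' approximately exponential growth of all-cause mortality with age.
#' Single-age bands take their single value.
#'
#' @param bands data.frame with columns `lower`, `upper` (integer ages,
#'   closed intervals) and `first`, `last` (annual death probabilities at the
#'   band's first and last age, before scaling).
#' @param max_age largest age in the model; bands must jointly cover
#'   `0..max_age` without overlap.
#' @param scale multiplier applied to `first`/`last` (e.g. `1e-2` for tables
#'   printed in units of 10^-2 per year).
#' @return numeric vector of length `max_age + 1`; element `a + 1` is the
#'   annual probability of death at age `a`.
#' @examples
#' b <- data.frame(lower = c(0, 1), upper = c(0, 4),
#'                 first = c(0.3, 0.05), last = c(0.3, 0.01))
#' expand_life_table(b, max_age = 4, scale = 1e-2)
#' @export
expand_life_table <- function(bands, max_age = 100L, scale = 1) {
  .check_bands(bands, max_age, what = "life table")
  v <- rep(NA_real_, max_age + 1L)
  for (i in seq_len(nrow(bands))) {
    lo <- bands$lower[i]; up <- bands$upper[i]
    f <- bands$first[i] * scale; l <- bands$last[i] * scale
    if (lo == up) {
      v[lo + 1L] <- f
    } else {
      if (f <= 0 || l <= 0)
        stop("life table band ", lo, "-", up,
             ": log-linear interpolation needs positive endpoints")
      k <- up - lo
      v[(lo:up) + 1L] <- f * (l / f)^((0:k) / k)
    }
  }
  if (any(v < 0 | v > 1))
    stop("life table: probability outside [0,1] after scaling")
  v
}

# Banded grade table (columns lower, upper, g1, g2, g3) -> (max_age+1) x 3
# matrix of per-year probabilities; values constant within a band.
.expand_grade_table <- function(bands, max_age, scale = 1, what = "table") {
  .check_bands(bands, max_age, what = what)
  m <- matrix(NA_real_, max_age + 1L, 3L)
  for (i in seq_len(nrow(bands))) {
    rows <- (bands$lower[i]:bands$upper[i]) + 1L
    for (g in 1:3) m[rows, g] <- bands[[paste0("g", g)]][i] * scale
  }
  if (any(m < 0 | m > 1))
    stop(what, ": probability outside [0,1] after scaling")
  m
}

.check_bands <- function(bands, max_age, what = "table") {
  if (!all(c("lower", "upper") %in% names(bands)))
    stop(what, ": band table needs `lower` and `upper` columns")
  if (any(bands$lower > bands$upper))
    stop(what, ": band with lower > upper")
  hit <- integer(max_age + 1L)
  for (i in seq_len(nrow(bands))) {
    ages <- bands$lower[i]:min(bands$upper[i], max_age)
    hit[ages + 1L] <- hit[ages + 1L] + 1L
  }
  if (any(hit == 0L))
    stop(what, ": no band covers age ", which(hit == 0L)[1] - 1L)
  if (any(hit > 1L))
    stop(what, ": overlapping bands at age ", which(hit > 1L)[1] - 1L)
  invisible(TRUE)
}

#' Define a screening policy
#'
#' @param start_age,end_age first and last age at which screening rounds are
#'   offered (years).
#' @param interval years between rounds.
#' @param participation probability that a woman attends any given round
#'   (drawn independently per round).
#' @param sensitivity probability that a mammogram detects a present DCIS.
#' @return a `dcis_policy` list.
#' @examples
#' screening_policy(50, 74, 2, participation = 0.76, sensitivity = 0.86)
#' @export
screening_policy <- function(start_age, end_age, interval,
                             participation, sensitivity) {
  pol <- list(start_age = as.integer(start_age),
              end_age = as.integer(end_age),
              interval = as.integer(interval),
              participation = participation,
              sensitivity = sensitivity)
  if (pol$start_age > pol$end_age)
    stop("screening: start_age must not exceed end_age")
  if (pol$interval < 1L) stop("screening: interval must be >= 1 year")
  for (f in c("participation", "sensitivity"))
    if (pol[[f]] < 0 || pol[[f]] > 1)
      stop("screening: ", f, " outside [0,1]")
  structure(pol, class = "dcis_policy")
}

#' Construct a simulation scenario
#'
#' Bundles every model input: per-year transition probabilities, the
#' screening policy, and run controls.  Inputs may be given either as
#' per-year vectors/matrices of plain probabilities or as banded data frames
#' (life: `lower,upper,first,last`; onset/progression: `lower,upper,g1,g2,g3`)
#' already on the plain probability scale.  Use [read_scenario()] for files
#' in the printed units of the source tables.
#'
#' @param label scenario name used in outputs.
#' @param cohort_size default number of women per cohort.
#' @param iterations default number of independent cohorts.
#' @param seed default master seed.
#' @param max_age oldest modelled age; women alive beyond it are censored.
#' @param life per-year annual death probability (length `max_age + 1`) or a
#'   band endpoint data.frame (log-linearly interpolated).
#' @param onset per-year `(max_age + 1) x 3` matrix of annual DCIS onset
#'   probabilities per grade, or a banded data.frame.
#' @param regression annual probability of spontaneous regression to healthy,
#'   scalar or per-grade length-3 vector.
#' @param progression per-year `(max_age + 1) x 3` matrix of annual
#'   DCIS-to-IBC progression probabilities, or a banded data.frame.
#' @param clinical annual probability that a present DCIS is detected outside
#'   the screening programme.
#' @param screening a [screening_policy()], or `NULL` for no screening.
#' @param event_order within-year event ordering: `"screen_last"` (default;
#'   death, then onset/competing transitions, then the screening round, so
#'   lesions arising during the year are detectable at that year's round) or
#'   `"screen_first"` (the round precedes death and transitions).
#' @return a validated `dcis_scenario` object.
#' @seealso [read_scenario()], [dcis_simulate()], [dcis_expect()]
#' @export
dcis_scenario <- function(label = "scenario", cohort_size = 1000L,
                          iterations = 1L, seed = 1L, max_age = 100L,
                          life, onset, regression, progression,
                          clinical = 0, screening = NULL,
                          event_order = c("screen_last", "screen_first")) {
  max_age <- as.integer(max_age)
  A <- max_age + 1L
  if (is.data.frame(life))
    life <- expand_life_table(life, max_age, scale = 1)
  if (is.data.frame(onset))
    onset <- .expand_grade_table(onset, max_age, what = "onset")
  if (is.data.frame(progression))
    progression <- .expand_grade_table(progression, max_age,
                                       what = "progression")
  if (length(regression) == 1L) regression <- rep(regression, 3L)
  if (!is.null(screening) && !inherits(screening, "dcis_policy"))
    screening <- do.call(screening_policy, screening)
  scn <- structure(list(
    label = label, cohort_size = as.integer(cohort_size),
    iterations = as.integer(iterations), seed = as.integer(seed),
    max_age = max_age,
    life = as.numeric(life),
    onset = matrix(as.numeric(onset), A, 3L),
    regression = as.numeric(regression),
    progression = matrix(as.numeric(progression), A, 3L),
    clinical = as.numeric(clinical),
    screening = screening,
    event_order = match.arg(event_order),
    bands = list()), class = "dcis_scenario")
  validate_scenario(scn)
  scn
}

#' Validate a scenario against the model invariants
#'
#' Checks full age coverage of every table, probability ranges, per-age
#' competing-risk budgets (regression + progression + clinical detection
#' must not exceed 1 for any age and grade; probabilities are used as
#' printed, never renormalised), and screening-policy sanity.  Violations
#' raise an error naming the offending entry.
#'
#' @param scn a `dcis_scenario`.
#' @return `scn`, invisibly, if valid.
#' @export
validate_scenario <- function(scn) {
  stopifnot(inherits(scn, "dcis_scenario"))
  A <- scn$max_age + 1L
  if (scn$cohort_size < 1L) stop("cohort_size must be >= 1")
  if (scn$iterations < 1L) stop("iterations must be >= 1")
  if (length(scn$life) != A || anyNA(scn$life))
    stop("life table does not cover every age 0..", scn$max_age)
  if (any(scn$life < 0 | scn$life > 1))
    stop("life table: probability outside [0,1] at age ",
         which(scn$life < 0 | scn$life > 1)[1] - 1L)
  for (nm in c("onset", "progression")) {
    m <- scn[[nm]]
    if (!is.matrix(m) || nrow(m) != A || ncol(m) != 3L || anyNA(m))
      stop(nm, " table does not cover every age 0..", scn$max_age)
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(bad))
      stop(nm, ": probability outside [0,1] at age ", bad[1, 1] - 1L,
           ", grade ", bad[1, 2])
  }
  os <- rowSums(scn$onset)
  if (any(os > 1 + 1e-12))
    stop("onset: grade probabilities sum above 1 at age ",
         which(os > 1 + 1e-12)[1] - 1L)
  if (length(scn$regression) != 3L ||
      any(scn$regression < 0 | scn$regression > 1))
    stop("regression: needs one probability in [0,1] per grade")
  if (scn$clinical < 0 || scn$clinical > 1)
    stop("clinical detection probability outside [0,1]")
  # competing transitions out of the DCIS state must leave a non-negative
  # residual "remain" mass at every age and grade
  for (g in 1:3) {
    tot <- scn$regression[g] + scn$progression[, g] + scn$clinical
    if (any(tot > 1 + 1e-12))
      stop("regression + progression + clinical detection exceeds 1 ",
           "at age ", which(tot > 1 + 1e-12)[1] - 1L, ", grade ", g)
  }
  if (!is.null(scn$screening)) {
    pol <- scn$screening
    if (pol$end_age > scn$max_age)
      stop("screening end_age exceeds max_age")
  }
  invisible(scn)
}

#' Read a scenario from a structured config file
#'
#' The YAML file holds run controls, scalar parameters and the screening
#' policy, and references delimited band tables (paths relative to the
#' config file).  File units follow the printed source tables: the life
#' table columns `first`/`last` are in units of 10^-2 per year, onset
#' `g1..g3` in 10^-3 per year, progression as plain fractions.  A life
#' table may alternatively be given per year with columns `age`, `value`
#' (units 10^-2), overriding interpolation.
#'
#' @param path path to a scenario YAML file.
#' @return a validated `dcis_scenario`.
#' @examples
#' scn <- read_scenario(dcis_example("nl_base.yaml"))
#' scn
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)
  need <- function(f) {
    if (is.null(cfg[[f]])) stop("scenario config: missing field `", f, "`")
    cfg[[f]]
  }
  tabs <- need("tables")
  tfile <- function(nm) {
    p <- file.path(dir, tabs[[nm]])
    if (!file.exists(p)) stop("scenario config: table file not found: ", p)
    read.csv(p)
  }
  max_age <- as.integer(if (is.null(cfg$max_age)) 100L else cfg$max_age)
  lt <- tfile("life")
  life_bands <- NULL
  if (all(c("age", "value") %in% names(lt))) {
    life <- rep(NA_real_, max_age + 1L)
    life[lt$age + 1L] <- lt$value * 1e-2
  } else {
    life_bands <- lt
    life <- expand_life_table(lt, max_age, scale = 1e-2)
  }
  onset_bands <- tfile("onset")
  prog_bands <- tfile("progression")
  reg <- need("regression")
  if (is.list(reg)) reg <- unlist(reg[c("g1", "g2", "g3")])
  scn <- dcis_scenario(
    label = if (is.null(cfg$label)) "scenario" else cfg$label,
    cohort_size = need("cohort_size"), iterations = need("iterations"),
    seed = if (is.null(cfg$seed)) 1L else cfg$seed,
    max_age = max_age,
    life = life,
    onset = .expand_grade_table(onset_bands, max_age, scale = 1e-3,
                                what = "onset"),
    regression = as.numeric(reg),
    progression = .expand_grade_table(prog_bands, max_age, what = "progression"),
    clinical = need("clinical"),
    screening = cfg$screening,
    event_order = if (is.null(cfg$event_order)) "screen_last"
                  else cfg$event_order)
  scn$bands <- list(life = life_bands, onset = onset_bands,
                    progression = prog_bands)
  scn$source <- normalizePath(path)
  scn
}

#' Write a scenario to a config file plus band tables
#'
#' Inverse of [read_scenario()]: emits `scenario.yaml` and the referenced
#' CSV tables (in printed units) into `dir`.  Scenarios constructed
#' programmatically from per-year arrays are written as degenerate
#' single-age bands.
#'
#' @param scn a `dcis_scenario`.
#' @param dir output directory (created if needed).
#' @return the path of the written YAML file, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  validate_scenario(scn)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ages <- 0:scn$max_age
  lb <- scn$bands$life
  if (is.null(lb))
    lb <- data.frame(lower = ages, upper = ages,
                     first = scn$life * 1e2, last = scn$life * 1e2)
  ob <- scn$bands$onset
  if (is.null(ob))
    ob <- data.frame(lower = ages, upper = ages,
                     g1 = scn$onset[, 1] * 1e3, g2 = scn$onset[, 2] * 1e3,
                     g3 = scn$onset[, 3] * 1e3)
  pb <- scn$bands$progression
  if (is.null(pb))
    pb <- data.frame(lower = ages, upper = ages,
                     g1 = scn$progression[, 1], g2 = scn$progression[, 2],
                     g3 = scn$progression[, 3])
  put <- function(df, file) {
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  put(lb, "life.csv")
  put(ob, "onset.csv")
  put(pb, "progression.csv")
  cfg <- list(label = scn$label, cohort_size = scn$cohort_size,
              iterations = scn$iterations, seed = scn$seed,
              max_age = scn$max_age, event_order = scn$event_order,
              tables = list(life = "life.csv", onset = "onset.csv",
                            progression = "progression.csv"),
              regression = list(g1 = scn$regression[1],
                                g2 = scn$regression[2],
                                g3 = scn$regression[3]),
              clinical = scn$clinical)
  if (!is.null(scn$screening))
    cfg$screening <- unclass(scn$screening)
  out <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(cfg, out, precision = 15)
  invisible(out)
}

#' Look up an annual transition probability
#'
#' @param scn a `dcis_scenario`.
#' @param age integer age in years, `0..max_age`.
#' @param grade DCIS grade 1, 2 or 3 (ignored for death).
#' @return the annual probability at that age (and grade).
#' @examples
#' scn <- read_scenario(dcis_example("nl_base.yaml"))
#' onset_probability(scn, 52, 3)        # 0.3250e-3
#' progression_probability(scn, 60, 2)  # 0.115
#' @name lookup
NULL

.check_age <- function(scn, age) {
  if (any(age < 0 | age > scn$max_age))
    stop("age outside 0..", scn$max_age)
  as.integer(age)
}

#' @rdname lookup
#' @export
onset_probability <- function(scn, age, grade) {
  scn$onset[.check_age(scn, age) + 1L, grade]
}

#' @rdname lookup
#' @export
progression_probability <- function(scn, age, grade) {
  scn$progression[.check_age(scn, age) + 1L, grade]
}

#' @rdname lookup
#' @export
death_probability <- function(scn, age) {
  scn$life[.check_age(scn, age) + 1L]
}

#' Paths to the scenario and reference fixtures shipped with the package
#'
#' `"nl_base.yaml"` is the Dutch base scenario (biennial screening 50-74,
#' participation 0.76, sensitivity 0.86); `"uk_base.yaml"` the UK setting
#' (triennial 50-71) using `uk_life_synthetic.csv`, a synthetic
#' approximation of UK female mortality.  `observed_nl2019.csv` and
#' `observed_nhs2021.csv` hold the registry screen-detection rates used for
#' validation; `intervals_example.csv` illustrative sensitivity bounds.
#'
#' @param file fixture file name; omit to list available fixtures.
#' @return a file path, or a character vector of fixture names.
#' @export
dcis_example <- function(file = NULL) {
  base <- system.file("extdata", package = "dcissim")
  if (is.null(file)) return(dir(base))
  p <- file.path(base, file)
  if (!file.exists(p)) stop("no such fixture: ", file)
  p
}

#' @export
print.dcis_scenario <- function(x, ...) {
  cat("DCIS natural-history scenario:", x$label, "\n")
  cat(sprintf("  cohort: %d women x %d iteration(s), seed %d, ages 0-%d\n",
              x$cohort_size, x$iterations, x$seed, x$max_age))
  if (is.null(x$screening)) {
    cat("  screening: none\n")
  } else {
    pol <- x$screening
    cat(sprintf(
      "  screening: every %d y at ages %d-%d, participation %.2f, sensitivity %.2f\n",
      pol$interval, pol$start_age, pol$end_age, pol$participation,
      pol$sensitivity))
  }
  cat(sprintf("  regression %.4f/%.4f/%.4f per year, clinical detection %.3f per year\n",
              x$regression[1], x$regression[2], x$regression[3], x$clinical))
  cat("  event order:", x$event_order, "\n")
  invisible(x)
}
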