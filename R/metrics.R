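# Reporting: registry-style detection-rate tables, episode fate and grade
# distributions, the per-iteration summary table, and comparison with
# observed reference data.
#
# Conventions: rates are screen-detected DCIS per 1,000 screening
# examinations; a woman contributes one examination per round attended
# while still in the model.  Age strata are defined by age at the
# screening round (registries report by age at detection), grade strata
# by lesion grade with all examinations as denominator, so the grade
# rates are additive to the total.  Across-iteration uncertainty is
# summarised by 2.5/97.5 percentile bounds.

# Default 5-year age groups covering the screening schedule.
.default_age_groups <- function(scn) {
  rounds <- schedule_screens(scn$screening)
  lo <- 5L * (min(rounds) %/% 5L)
  starts <- seq.int(lo, max(rounds), by = 5L)
  data.frame(label = sprintf("%d-%d", starts, starts + 4L),
             lower = starts, upper = starts + 4L)
}

# Core rate-table builder from arrays of detections and screens.
# det: k x A x 3 array, mamm: k x A matrix (k >= 1 iterations).
.rate_table <- function(det, mamm, age_groups, intervals = TRUE) {
  k <- dim(det)[1]
  strat <- list()
  add <- function(type, label, det_k, scr_k) {
    rate <- ifelse(scr_k > 0, 1000 * det_k / scr_k, NA_real_)
    strat[[length(strat) + 1L]] <<- data.frame(
      stratum = label, type = type,
      mean = mean(rate, na.rm = TRUE),
      lower = if (intervals && k > 1)
        unname(quantile(rate, 0.025, na.rm = TRUE)) else NA_real_,
      upper = if (intervals && k > 1)
        unname(quantile(rate, 0.975, na.rm = TRUE)) else NA_real_,
      se_mean = if (intervals && k > 1) sd(rate) / sqrt(k) else NA_real_,
      detections = sum(det_k), screens = sum(scr_k))
  }
  tot_det <- apply(det, 1, sum)
  tot_scr <- rowSums(mamm)
  add("total", "total", tot_det, tot_scr)
  for (i in seq_len(nrow(age_groups))) {
    cols <- (age_groups$lower[i]:age_groups$upper[i]) + 1L
    cols <- cols[cols <= dim(det)[2]]
    add("age", age_groups$label[i],
        apply(det[, cols, , drop = FALSE], 1, sum),
        rowSums(mamm[, cols, drop = FALSE]))
  }
  for (g in 1:3)
    add("grade", as.character(g), apply(det[, , g, drop = FALSE], 1, sum),
        tot_scr)
  out <- do.call(rbind, strat)
  out <- out[out$screens > 0, ]           # zero-examination strata are absent
  class(out) <- c("dcis_rates", "data.frame")
  out
}

#' Screen-detection rates per 1,000 examinations
#'
#' Stratifies screen-detected DCIS by age at the screening round, by lesion
#' grade, and in total.  For simulation output the across-iteration mean,
#' 2.5/97.5 percentile bounds and the standard error of the mean are
#' reported; for the expectation oracle the rates are exact and carry no
#' bounds.
#'
#' @param x a `dcis_sim` or `dcis_expect` object with screening enabled.
#' @param age_groups data.frame with columns `label`, `lower`, `upper`;
#'   default: 5-year groups covering the screening schedule.
#' @param ... unused.
#' @return a data.frame (class `dcis_rates`) with one row per stratum:
#'   `stratum`, `type` (total/age/grade), `mean`, `lower`, `upper`,
#'   `se_mean`, `detections`, `screens`.  Strata with no examinations are
#'   absent.
#' @export
detection_rates <- function(x, ...) UseMethod("detection_rates")

#' @rdname detection_rates
#' @export
detection_rates.dcis_sim <- function(x, age_groups = NULL, ...) {
  if (is.null(x$scenario$screening))
    stop("scenario has no screening policy; no examinations to report")
  if (is.null(age_groups)) age_groups <- .default_age_groups(x$scenario)
  .rate_table(x$det, x$mamm, age_groups)
}

#' @rdname detection_rates
#' @export
detection_rates.dcis_expect <- function(x, age_groups = NULL, ...) {
  if (is.null(x$scenario$screening))
    stop("scenario has no screening policy; no examinations to report")
  if (is.null(age_groups)) age_groups <- .default_age_groups(x$scenario)
  A <- length(x$screens)
  det <- array(x$det, c(1L, A, 3L))
  mamm <- matrix(x$screens, 1L, A)
  .rate_table(det, mamm, age_groups, intervals = FALSE)
}

#' Distribution of DCIS episode fates
#'
#' Every DCIS onset resolves in exactly one fate: regression to healthy,
#' progression to IBC, screen-detection, clinical detection, death from
#' another cause while the lesion is present, or censoring at the model
#' horizon.  Fractions are episodes per fate over all episodes and sum
#' to one.
#'
#' @param x a `dcis_sim` or `dcis_expect` object.
#' @param ... unused.
#' @return data.frame with `fate`, `fraction` (pooled across iterations),
#'   and for simulations `lower`/`upper` percentile bounds of the
#'   per-iteration fractions.
#' @export
fate_distribution <- function(x, ...) UseMethod("fate_distribution")

#' @rdname fate_distribution
#' @export
fate_distribution.dcis_sim <- function(x, ...) {
  tot <- rowSums(x$onsets)
  if (sum(tot) == 0) stop("no DCIS episodes; fate distribution undefined")
  counts <- apply(x$fates, c(1, 2), sum)          # k x 6
  frac_k <- counts / tot
  k <- nrow(counts)
  data.frame(fate = .fates,
             fraction = colSums(counts) / sum(tot),
             lower = if (k > 1) apply(frac_k, 2, quantile, 0.025)
                     else NA_real_,
             upper = if (k > 1) apply(frac_k, 2, quantile, 0.975)
                     else NA_real_,
             row.names = NULL)
}

#' @rdname fate_distribution
#' @export
fate_distribution.dcis_expect <- function(x, ...) {
  tot <- sum(x$onset_mass)
  if (tot == 0) stop("no DCIS onset mass; fate distribution undefined")
  data.frame(fate = .fates, fraction = rowSums(x$fate_mass) / tot,
             lower = NA_real_, upper = NA_real_, row.names = NULL)
}

#' Grade distribution of DCIS episodes
#'
#' @param x a `dcis_sim` or `dcis_expect` object.
#' @param among `"screen_detected"` (default) restricts to screen-detected
#'   episodes; `"onset"` uses all episodes.
#' @param ... unused.
#' @return data.frame with `grade` and `fraction` summing to one.
#' @export
grade_distribution <- function(x, among = c("screen_detected", "onset"),
                               ...) {
  among <- match.arg(among)
  counts <- switch(class(x)[1],
    dcis_sim = if (among == "onset") colSums(x$onsets)
               else apply(x$fates[, "screen_detected", , drop = FALSE], 3, sum),
    dcis_expect = if (among == "onset") x$onset_mass
                  else x$fate_mass["screen_detected", ],
    stop("unsupported object"))
  if (is.null(dim(counts))) counts <- as.numeric(counts)
  if (sum(counts) == 0) stop("no episodes in stratum '", among, "'")
  data.frame(grade = 1:3, fraction = counts / sum(counts))
}

#' Per-iteration summary table
#'
#' The raw reportables of one run: DCIS onsets per grade, regressed
#' episodes, women removed from the model per exit state, and mammograms,
#' per iteration and pooled, plus average ages at the main events.
#'
#' @param object a `dcis_sim`.
#' @param ... unused.
#' @return a `summary.dcis_sim` list with data.frame `per_iteration`,
#'   numeric vector `pooled`, and `mean_ages`.
#' @export
summary.dcis_sim <- function(object, ...) {
  k <- object$iterations
  per <- data.frame(
    iteration = seq_len(k), seed = object$child_seeds,
    onsets_g1 = object$onsets[, 1], onsets_g2 = object$onsets[, 2],
    onsets_g3 = object$onsets[, 3],
    regressed = rowSums(object$fates[, "regressed", , drop = FALSE]))
  for (e in .exits) per[[paste0("removed_", e)]] <- object$exits[, e]
  per$mammograms <- rowSums(object$mamm)
  pooled <- colSums(per[, -(1:2)])
  ev_age <- function(sums, counts) if (sum(counts) > 0)
    sum(sums) / sum(counts) else NA_real_
  mean_ages <- c(
    onset = ev_age(object$onset_agesum, object$onsets),
    regression = ev_age(object$fate_agesum[, "regressed", ],
                        object$fates[, "regressed", ]),
    progression_ibc = ev_age(object$fate_agesum[, "progressed_ibc", ],
                             object$fates[, "progressed_ibc", ]),
    screen_detection = ev_age(object$fate_agesum[, "screen_detected", ],
                              object$fates[, "screen_detected", ]),
    clinical_detection = ev_age(object$fate_agesum[, "clin_detected", ],
                                object$fates[, "clin_detected", ]),
    death = ev_age(object$exit_agesum[, "dead_other"],
                   object$exits[, "dead_other"]))
  structure(list(scenario = object$scenario$label, women = object$women,
                 per_iteration = per, pooled = pooled,
                 mean_ages = mean_ages),
            class = "summary.dcis_sim")
}

#' @export
print.summary.dcis_sim <- function(x, ...) {
  cat(sprintf("Summary of scenario '%s' (%d iterations x %s women)\n",
              x$scenario, nrow(x$per_iteration),
              format(x$women, big.mark = ",")))
  print(x$per_iteration, row.names = FALSE)
  cat("\npooled counts:\n")
  print(x$pooled)
  cat("\nmean event ages (years):\n")
  print(round(x$mean_ages, 1))
  invisible(x)
}

#' Observed reference detection rates
#'
#' Registry screen-detection rates per 1,000 examinations used for
#' validation: `"nl2019"` (Dutch national registry, by age group and
#' grade) and `"nhs2021"` (UK national programme, by age group).
#'
#' @param name `"nl2019"` or `"nhs2021"`, or a path to a CSV with columns
#'   `stratum`, `type`, `observed`.
#' @return data.frame with columns `stratum`, `type`, `observed`.
#' @export
observed_reference <- function(name = c("nl2019", "nhs2021")) {
  if (length(name) == 1L && file.exists(name)) return(read.csv(name))
  name <- match.arg(name)
  read.csv(dcis_example(sprintf("observed_%s.csv", name)))
}

#' Compare simulated detection rates with observed registry data
#'
#' Flags, per stratum, whether the observed rate lies inside the simulated
#' across-iteration interval, and the direction of any deviation.
#'
#' @param x a `dcis_sim`, or a rate table from [detection_rates()].
#' @param reference a reference name understood by [observed_reference()]
#'   or a data.frame with columns `stratum`, `type`, `observed`.
#' @param ... passed to [detection_rates()] when `x` is a simulation.
#' @return data.frame with `stratum`, `type`, `simulated`, `lower`,
#'   `upper`, `observed`, `inside`, and `direction` (`"over"` when the
#'   simulation overestimates the observation, `"under"` when it
#'   underestimates, `""` when inside).
#' @export
compare_to_observed <- function(x, reference, ...) {
  rates <- if (inherits(x, "dcis_sim")) detection_rates(x, ...) else x
  obs <- if (is.character(reference)) observed_reference(reference)
         else reference
  key <- paste(rates$type, rates$stratum)
  okey <- paste(obs$type, obs$stratum)
  miss <- setdiff(okey, key)
  if (length(miss))
    stop("reference strata absent from simulated rates: ",
         paste(miss, collapse = ", "))
  m <- match(okey, key)
  lo <- rates$lower[m]; hi <- rates$upper[m]
  if (anyNA(lo)) stop("simulated rates carry no intervals; ",
                      "run with more than one iteration")
  inside <- obs$observed >= lo & obs$observed <= hi
  data.frame(stratum = obs$stratum, type = obs$type,
             simulated = rates$mean[m], lower = lo, upper = hi,
             observed = obs$observed, inside = inside,
             direction = ifelse(inside, "",
                                ifelse(rates$mean[m] > obs$observed,
                                       "over", "under")))
}
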