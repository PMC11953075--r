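# Stochastic per-woman engine.
#
# One model year applies, in the scenario's configured order:
#   death      -- Bernoulli with the age-specific all-cause probability
#                 (identical in healthy and DCIS state);
#   transitions -- healthy women draw DCIS onset (one uniform against the
#                 cumulative per-grade onset probabilities, grades mutually
#                 exclusive); women with DCIS draw once among regression,
#                 progression to IBC, clinical detection, or remain
#                 (competing risks as a single multinomial, residual mass =
#                 remain; probabilities used exactly as printed);
#   screening  -- at a scheduled round, attendance is drawn per round; a
#                 present DCIS in an attending woman is detected with
#                 probability = sensitivity.
# Under the default "screen_last" order the round closes the year, so
# lesions with onset earlier in the same year are already detectable; under
# "screen_first" the round opens the year.  The expectation oracle
# (expectation.R) applies the identical ordered update to probability mass.

#' Ages at which screening rounds take place
#'
#' @param policy a [screening_policy()].
#' @return integer vector `start_age, start_age + interval, ... <= end_age`.
#' @examples
#' schedule_screens(screening_policy(50, 74, 2, 0.76, 0.86))
#' @export
schedule_screens <- function(policy) {
  stopifnot(inherits(policy, "dcis_policy"))
  seq.int(policy$start_age, policy$end_age, by = policy$interval)
}

# Deterministic child seed for iteration i of a run seeded with `seed`.
# Kept below 2^31 - 1; exact in double arithmetic.
.child_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 +
                i * 2654435769) %% 2147483647)
}

# Simulate one cohort of n women. Returns aggregate accumulators and,
# optionally, a per-event trace (only sensible for small n).
.run_cohort <- function(scn, n, seed, trace = FALSE) {
  set.seed(seed)
  ma <- scn$max_age; A <- ma + 1L
  p1 <- scn$life; p2 <- scn$onset; p3 <- scn$regression
  p4 <- scn$progression; p6 <- scn$clinical
  pol <- scn$screening
  is_round <- logical(A)
  if (!is.null(pol)) is_round[schedule_screens(pol) + 1L] <- TRUE

  state <- integer(n)                 # 0 healthy, 1:3 DCIS grade
  active <- seq_len(n)

  det <- matrix(0, A, 3L)             # screen-detections by age at screen
  mamm <- numeric(A)                  # mammograms by age at screen
  onsets <- numeric(3L); onset_agesum <- numeric(3L)
  fates <- matrix(0, 6L, 3L, dimnames = list(.fates, NULL))
  fate_agesum <- matrix(0, 6L, 3L, dimnames = list(.fates, NULL))
  exits <- setNames(numeric(5L), .exits)
  exit_agesum <- setNames(numeric(5L), .exits)

  tr <- if (trace) vector("list", 256L) else NULL
  tr_n <- 0L
  push <- function(age, woman, event, grade) {
    tr_n <<- tr_n + 1L
    if (tr_n > length(tr)) length(tr) <<- 2L * tr_n
    tr[[tr_n]] <<- data.frame(woman = woman, age = age, event = event,
                              grade = grade)
  }

  end_episode <- function(fate, g_tab, age) {
    fates[fate, ] <<- fates[fate, ] + g_tab
    fate_agesum[fate, ] <<- fate_agesum[fate, ] + g_tab * age
  }

  screen_step <- function(a) {
    m <- length(active)
    if (!m || !is_round[a + 1L]) return(invisible())
    att <- runif(m) < pol$participation
    mamm[a + 1L] <<- mamm[a + 1L] + sum(att)
    if (trace && any(att)) push(a, active[att], "mammogram", NA_integer_)
    cand <- att & state[active] > 0L
    if (!any(cand)) return(invisible())
    hit <- cand
    hit[cand] <- runif(sum(cand)) < pol$sensitivity
    if (!any(hit)) return(invisible())
    ids <- active[hit]
    g_tab <- tabulate(state[ids], 3L)
    det[a + 1L, ] <<- det[a + 1L, ] + g_tab
    end_episode("screen_detected", g_tab, a)
    exits["screen_detected"] <<- exits["screen_detected"] + length(ids)
    exit_agesum["screen_detected"] <<-
      exit_agesum["screen_detected"] + length(ids) * a
    if (trace) push(a, ids, "screen_detected", state[ids])
    active <<- active[!hit]
    invisible()
  }

  death_step <- function(a) {
    m <- length(active)
    q <- p1[a + 1L]
    if (!m || q <= 0) return(invisible())
    dd <- if (q >= 1) rep(TRUE, m) else runif(m) < q
    if (!any(dd)) return(invisible())
    ids <- active[dd]
    st <- state[ids]
    in_dcis <- st > 0L
    if (any(in_dcis))
      end_episode("died_other", tabulate(st[in_dcis], 3L), a)
    exits["dead_other"] <<- exits["dead_other"] + length(ids)
    exit_agesum["dead_other"] <<- exit_agesum["dead_other"] + length(ids) * a
    if (trace) push(a, ids, "died_other", ifelse(in_dcis, st, NA_integer_))
    active <<- active[!dd]
    invisible()
  }

  trans_step <- function(a) {
    m <- length(active)
    if (!m) return(invisible())
    st <- state[active]
    u <- runif(m)
    # onset among healthy women (grades mutually exclusive in a year)
    h <- st == 0L
    o <- p2[a + 1L, ]
    if (any(h) && sum(o) > 0) {
      uh <- u[h]
      g_new <- integer(length(uh))
      g_new[uh < o[1] + o[2] + o[3]] <- 3L
      g_new[uh < o[1] + o[2]] <- 2L
      g_new[uh < o[1]] <- 1L
      w <- g_new > 0L
      if (any(w)) {
        ids <- active[h][w]
        state[ids] <<- g_new[w]
        g_tab <- tabulate(g_new[w], 3L)
        onsets <<- onsets + g_tab
        onset_agesum <<- onset_agesum + g_tab * a
        if (trace) push(a, ids, "onset", g_new[w])
      }
    }
    # one competing-risk draw per woman in DCIS state at the start of the
    # step (fresh onsets above are excluded this year)
    gone <- logical(m)
    for (g in 1:3) {
      sel <- st == g
      if (!any(sel)) next
      ug <- u[sel]; ids <- active[sel]
      pr <- p3[g]; pp <- p4[a + 1L, g]; pc <- p6
      reg <- ug < pr
      prog <- !reg & ug < pr + pp
      clin <- !reg & !prog & ug < pr + pp + pc
      if (any(reg)) {
        state[ids[reg]] <<- 0L
        end_episode("regressed", setNames(tabulate(g, 3L) * sum(reg), NULL), a)
        if (trace) push(a, ids[reg], "regressed", g)
      }
      if (any(prog)) {
        k <- sum(prog)
        end_episode("progressed_ibc", tabulate(g, 3L) * k, a)
        exits["ibc"] <<- exits["ibc"] + k
        exit_agesum["ibc"] <<- exit_agesum["ibc"] + k * a
        if (trace) push(a, ids[prog], "progressed_ibc", g)
      }
      if (any(clin)) {
        k <- sum(clin)
        end_episode("clin_detected", tabulate(g, 3L) * k, a)
        exits["clin_detected"] <<- exits["clin_detected"] + k
        exit_agesum["clin_detected"] <<- exit_agesum["clin_detected"] + k * a
        if (trace) push(a, ids[clin], "clin_detected", g)
      }
      gone[sel] <- prog | clin
    }
    if (any(gone)) active <<- active[!gone]
    invisible()
  }

  steps <- if (identical(scn$event_order, "screen_first"))
    list(screen_step, death_step, trans_step)
  else
    list(death_step, trans_step, screen_step)

  for (a in 0:ma) {
    if (!length(active)) break
    for (f in steps) f(a)
  }

  # anyone still in the model past max_age is censored
  if (length(active)) {
    st <- state[active]
    k <- length(active)
    exits["censored"] <- exits["censored"] + k
    exit_agesum["censored"] <- exit_agesum["censored"] + k * ma
    if (any(st > 0L))
      end_episode("censored", tabulate(st[st > 0L], 3L), ma)
    if (trace) push(ma, active, "censored", ifelse(st > 0L, st, NA_integer_))
  }

  list(det = det, mamm = mamm, onsets = onsets, onset_agesum = onset_agesum,
       fates = fates, fate_agesum = fate_agesum, exits = exits,
       exit_agesum = exit_agesum,
       trace = if (trace) do.call(rbind, tr[seq_len(tr_n)]))
}

#' Run the stochastic microsimulation
#'
#' Simulates `iterations` independent cohorts of `women` women, each
#' followed yearly from birth until death, progression to IBC,
#' screen-detection, clinical detection, or censoring past `max_age`.
#' Iteration `i` uses a child seed derived deterministically from
#' `(seed, i)`, so a `(scenario, seed)` pair reproduces results exactly.
#'
#' @param scn a `dcis_scenario`.
#' @param women cohort size; default taken from the scenario.
#' @param iterations number of independent cohorts; default from scenario.
#' @param seed master seed; default from scenario.
#' @param trace if `TRUE`, keep a per-event trace (only for small cohorts).
#' @return a `dcis_sim` object holding per-iteration aggregates: onsets and
#'   episode fates by grade, screen-detections and mammograms by age at
#'   screen, and exits by state.  See [detection_rates()],
#'   [fate_distribution()], [grade_distribution()], [summary.dcis_sim()].
#' @examples
#' scn <- read_scenario(dcis_example("nl_base.yaml"))
#' sim <- dcis_simulate(scn, women = 2000, iterations = 2, seed = 7)
#' sim
#' @export
dcis_simulate <- function(scn, women = NULL, iterations = NULL, seed = NULL,
                          trace = FALSE) {
  validate_scenario(scn)
  n <- as.integer(if (is.null(women)) scn$cohort_size else women)
  k <- as.integer(if (is.null(iterations)) scn$iterations else iterations)
  seed <- as.integer(if (is.null(seed)) scn$seed else seed)
  if (n < 1L) stop("women must be >= 1")
  if (k < 1L) stop("iterations must be >= 1")
  A <- scn$max_age + 1L
  out <- list(
    scenario = scn, women = n, iterations = k, seed = seed,
    child_seeds = vapply(seq_len(k), function(i) .child_seed(seed, i), 1L),
    det = array(0, c(k, A, 3L)), mamm = matrix(0, k, A),
    onsets = matrix(0, k, 3L), onset_agesum = matrix(0, k, 3L),
    fates = array(0, c(k, 6L, 3L), dimnames = list(NULL, .fates, NULL)),
    fate_agesum = array(0, c(k, 6L, 3L), dimnames = list(NULL, .fates, NULL)),
    exits = matrix(0, k, 5L, dimnames = list(NULL, .exits)),
    exit_agesum = matrix(0, k, 5L, dimnames = list(NULL, .exits)),
    traces = if (trace) vector("list", k))
  for (i in seq_len(k)) {
    r <- .run_cohort(scn, n, out$child_seeds[i], trace = trace)
    out$det[i, , ] <- r$det; out$mamm[i, ] <- r$mamm
    out$onsets[i, ] <- r$onsets; out$onset_agesum[i, ] <- r$onset_agesum
    out$fates[i, , ] <- r$fates; out$fate_agesum[i, , ] <- r$fate_agesum
    out$exits[i, ] <- r$exits; out$exit_agesum[i, ] <- r$exit_agesum
    if (trace) out$traces[[i]] <- r$trace
  }
  structure(out, class = "dcis_sim")
}

#' @rdname dcis_simulate
#' @param object,nsim,... for the [stats::simulate()] method: the scenario,
#'   the number of cohort iterations, and arguments passed on.
#' @export
simulate.dcis_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  dcis_simulate(object, iterations = nsim, seed = seed, ...)
}

#' Simulate a single life history
#'
#' Runs the yearly kernel for one woman and returns her full trajectory:
#' exit state and age, every DCIS episode with its fate, and the screening
#' rounds attended.
#'
#' @param scn a `dcis_scenario`.
#' @param seed integer seed.
#' @return a `dcis_life` list with elements `exit_state`, `exit_age`,
#'   `episodes` (data.frame: `onset_age`, `grade`, `fate`, `fate_age`) and
#'   `screens_attended` (ages).
#' @export
simulate_woman <- function(scn, seed = 1L) {
  r <- .run_cohort(scn, 1L, as.integer(seed), trace = TRUE)
  ev <- r$trace
  exit_ev <- ev[ev$event %in% c("died_other", "progressed_ibc",
                                "screen_detected", "clin_detected",
                                "censored"), , drop = FALSE]
  exit_state <- c(died_other = "dead_other", progressed_ibc = "ibc",
                  screen_detected = "screen_detected",
                  clin_detected = "clin_detected",
                  censored = "censored")[[exit_ev$event[1]]]
  onsets <- ev[ev$event == "onset", , drop = FALSE]
  ends <- ev[ev$event %in% c("regressed", "progressed_ibc",
                             "screen_detected", "clin_detected") |
               (ev$event %in% c("died_other", "censored") & !is.na(ev$grade)),
             , drop = FALSE]
  episodes <- if (nrow(onsets)) {
    data.frame(onset_age = onsets$age, grade = onsets$grade,
               fate = .fates[match(ends$event,
                                   c("regressed", "progressed_ibc",
                                     "screen_detected", "clin_detected",
                                     "died_other", "censored"))],
               fate_age = ends$age)
  } else {
    data.frame(onset_age = integer(), grade = integer(),
               fate = character(), fate_age = integer())
  }
  structure(list(exit_state = exit_state, exit_age = exit_ev$age[1],
                 episodes = episodes,
                 screens_attended = ev$age[ev$event == "mammogram"]),
            class = "dcis_life")
}

#' @export
print.dcis_life <- function(x, ...) {
  cat("Life history: exit", x$exit_state, "at age", x$exit_age, "\n")
  cat("  screens attended:",
      if (length(x$screens_attended)) paste(x$screens_attended, collapse = ", ")
      else "none", "\n")
  if (nrow(x$episodes)) {
    cat("  DCIS episodes:\n")
    print(x$episodes, row.names = FALSE)
  } else cat("  DCIS episodes: none\n")
  invisible(x)
}

#' @export
print.dcis_sim <- function(x, ...) {
  cat(sprintf("DCIS microsimulation of scenario '%s': %d x %s women, seed %d\n",
              x$scenario$label, x$iterations,
              format(x$women, big.mark = ","), x$seed))
  tot <- colSums(x$exits)
  cat("  exits:", paste(sprintf("%s %s", names(tot),
                                format(tot, big.mark = ",", trim = TRUE)),
                        collapse = ", "), "\n")
  cat(sprintf("  DCIS onsets: %s (grades %s)\n",
              format(sum(x$onsets), big.mark = ","),
              paste(format(colSums(x$onsets), big.mark = ",", trim = TRUE),
                    collapse = "/")))
  if (!is.null(x$scenario$screening)) {
    cat(sprintf("  screens: %s, screen-detected DCIS: %s (%.2f per 1,000 screens)\n",
                format(sum(x$mamm), big.mark = ","),
                format(sum(x$det), big.mark = ","),
                1000 * sum(x$det) / sum(x$mamm)))
  }
  invisible(x)
}
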