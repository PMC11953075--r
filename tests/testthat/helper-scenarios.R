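# Shared fixtures and an independent brute-force oracle, built in code.

nl_scenario <- function() read_scenario(dcis_example("nl_base.yaml"))
uk_scenario <- function() read_scenario(dcis_example("uk_base.yaml"))

# Flat-parameter toy: constant hazards, optional mortality and screening.
# All inputs on the plain probability scale.
toy_scenario <- function(max_age = 100, life = 0, terminal_death = TRUE,
                         onset = c(0, 0, 0), onset_ages = NULL,
                         regression = 0, progression = 0, clinical = 0,
                         screening = NULL,
                         event_order = "screen_last", ...) {
  A <- max_age + 1
  lt <- rep(life, A)
  if (terminal_death) lt[A] <- 1
  om <- matrix(0, A, 3)
  rows <- if (is.null(onset_ages)) seq_len(A) else onset_ages + 1
  om[rows, ] <- matrix(onset, length(rows), 3, byrow = TRUE)
  pm <- matrix(progression, A, 3, byrow = length(progression) == 3)
  dcis_scenario(label = "toy", max_age = max_age, life = lt, onset = om,
                regression = regression, progression = pm,
                clinical = clinical, screening = screening,
                event_order = event_order, ...)
}

# Exhaustive enumeration of all individual-level event paths of a scenario,
# multiplying branch probabilities.  Independent of the mass-propagation
# code: every Bernoulli/multinomial branch of the yearly kernel is expanded
# explicitly.  Only feasible for short horizons.
brute_force_expect <- function(scn) {
  A <- scn$max_age + 1
  fates <- c("regressed", "progressed_ibc", "screen_detected",
             "clin_detected", "died_other", "censored")
  exits <- c("dead_other", "ibc", "screen_detected", "clin_detected",
             "censored")
  acc <- list(absorbed = setNames(numeric(5), exits),
              fate = matrix(0, 6, 3, dimnames = list(fates, NULL)),
              onset = numeric(3), screens = numeric(A),
              det = matrix(0, A, 3))
  pol <- scn$screening
  rounds <- if (is.null(pol)) integer(0) else schedule_screens(pol)

  step_screen <- function(a, state, p) {
    if (!(a %in% rounds)) return(list(list(p = p, state = state)))
    acc$screens[a + 1] <<- acc$screens[a + 1] + p * pol$participation
    out <- list(list(p = p * (1 - pol$participation), state = state))
    if (state == 0) {
      out[[2]] <- list(p = p * pol$participation, state = 0)
    } else {
      pd <- p * pol$participation * pol$sensitivity
      acc$det[a + 1, state] <<- acc$det[a + 1, state] + pd
      acc$fate["screen_detected", state] <<-
        acc$fate["screen_detected", state] + pd
      acc$absorbed["screen_detected"] <<- acc$absorbed["screen_detected"] + pd
      out[[2]] <- list(p = p * pol$participation * (1 - pol$sensitivity),
                       state = state)
    }
    out
  }
  step_death <- function(a, state, p) {
    q <- scn$life[a + 1]
    if (q > 0) {
      acc$absorbed["dead_other"] <<- acc$absorbed["dead_other"] + p * q
      if (state > 0)
        acc$fate["died_other", state] <<- acc$fate["died_other", state] + p * q
    }
    if (q >= 1) list() else list(list(p = p * (1 - q), state = state))
  }
  step_trans <- function(a, state, p) {
    if (state == 0) {
      o <- scn$onset[a + 1, ]
      out <- list(list(p = p * (1 - sum(o)), state = 0))
      for (g in 1:3) if (o[g] > 0) {
        acc$onset[g] <<- acc$onset[g] + p * o[g]
        out[[length(out) + 1]] <- list(p = p * o[g], state = g)
      }
      out
    } else {
      g <- state
      pr <- scn$regression[g]; pp <- scn$progression[a + 1, g]
      pc <- scn$clinical
      acc$fate["regressed", g] <<- acc$fate["regressed", g] + p * pr
      acc$fate["progressed_ibc", g] <<-
        acc$fate["progressed_ibc", g] + p * pp
      acc$absorbed["ibc"] <<- acc$absorbed["ibc"] + p * pp
      acc$fate["clin_detected", g] <<- acc$fate["clin_detected", g] + p * pc
      acc$absorbed["clin_detected"] <<-
        acc$absorbed["clin_detected"] + p * pc
      out <- list()
      if (pr > 0) out[[length(out) + 1]] <- list(p = p * pr, state = 0)
      rem <- 1 - pr - pp - pc
      if (rem > 0) out[[length(out) + 1]] <- list(p = p * rem, state = g)
      out
    }
  }
  steps <- if (identical(scn$event_order, "screen_first"))
    list(step_screen, step_death, step_trans)
  else
    list(step_death, step_trans, step_screen)

  recurse <- function(a, state, p) {
    if (p <= 0) return(invisible())
    if (a > scn$max_age) {
      acc$absorbed["censored"] <<- acc$absorbed["censored"] + p
      if (state > 0)
        acc$fate["censored", state] <<- acc$fate["censored", state] + p
      return(invisible())
    }
    conts <- list(list(p = p, state = state))
    for (f in steps) {
      nxt <- list()
      for (cc in conts) nxt <- c(nxt, f(a, cc$state, cc$p))
      conts <- nxt
    }
    for (cc in conts) recurse(a + 1, cc$state, cc$p)
    invisible()
  }
  recurse(0, 0, 1)
  acc
}
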