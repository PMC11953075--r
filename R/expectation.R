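# Deterministic expectation oracle.
#
# Propagates exact probability mass over age x state x grade through the
# same ordered yearly update as the stochastic engine: the screening round
# moves participation x sensitivity of each DCIS mass into the
# screen-detected absorber; death moves the age-specific fraction of every
# live mass into the death absorber; transitions move onset mass out of
# healthy and competing-risk mass out of each DCIS grade.  Competing
# transitions always act on the start-of-step DCIS mass, so mass that
# arises by onset within the step is not also transitioned in the same
# year (matching the single draw per woman per year in the engine).

#' Propagate the exact state distribution for a scenario
#'
#' Computes, without Monte Carlo error, the expected value of every
#' aggregate the engine estimates: age trajectories of state occupancy,
#' expected mammograms and screen-detections per round, DCIS onset mass and
#' episode-fate mass per grade.  Mass conservation is checked at every age
#' to within `tol`.
#'
#' @param scn a `dcis_scenario`.
#' @param tol permitted absolute mass leak per age (default `1e-12`).
#' @return a `dcis_expect` object with elements `trajectory` (matrix, one
#'   row per age at the start of the year: healthy, DCIS grades 1-3, and
#'   cumulative mass in each absorbing state), `det` and `screens`
#'   (expected detections by age x grade, expected mammograms by age, both
#'   per woman), `onset_mass` and `fate_mass` (per grade), and `absorbed`.
#' @examples
#' scn <- read_scenario(dcis_example("nl_base.yaml"))
#' exp <- dcis_expect(scn)
#' detection_rates(exp)
#' @export
dcis_expect <- function(scn, tol = 1e-12) {
  validate_scenario(scn)
  ma <- scn$max_age; A <- ma + 1L
  p1 <- scn$life; p2 <- scn$onset; p3 <- scn$regression
  p4 <- scn$progression; p6 <- scn$clinical
  pol <- scn$screening
  is_round <- logical(A)
  if (!is.null(pol)) is_round[schedule_screens(pol) + 1L] <- TRUE

  h <- 1; d <- c(0, 0, 0)
  absorbed <- setNames(numeric(5L), .exits)
  fate_mass <- matrix(0, 6L, 3L, dimnames = list(.fates, NULL))
  onset_mass <- numeric(3L)
  screens <- numeric(A)
  det <- matrix(0, A, 3L)
  traj <- matrix(0, A + 1L, 9L,
                 dimnames = list(NULL, c("healthy", "dcis_g1", "dcis_g2",
                                         "dcis_g3", .exits)))

  screen_step <- function(a) {
    if (!is_round[a + 1L]) return(invisible())
    screens[a + 1L] <<- pol$participation * (h + sum(d))
    dd <- pol$participation * pol$sensitivity * d
    det[a + 1L, ] <<- dd
    d <<- d - dd
    absorbed["screen_detected"] <<- absorbed["screen_detected"] + sum(dd)
    fate_mass["screen_detected", ] <<- fate_mass["screen_detected", ] + dd
    invisible()
  }
  death_step <- function(a) {
    q <- p1[a + 1L]
    if (q <= 0) return(invisible())
    absorbed["dead_other"] <<- absorbed["dead_other"] + q * (h + sum(d))
    fate_mass["died_other", ] <<- fate_mass["died_other", ] + q * d
    h <<- h * (1 - q); d <<- d * (1 - q)
    invisible()
  }
  trans_step <- function(a) {
    o <- h * p2[a + 1L, ]
    reg <- d * p3; prog <- d * p4[a + 1L, ]; clin <- d * p6
    h <<- h * (1 - sum(p2[a + 1L, ])) + sum(reg)
    d <<- d - (reg + prog + clin) + o
    absorbed["ibc"] <<- absorbed["ibc"] + sum(prog)
    absorbed["clin_detected"] <<- absorbed["clin_detected"] + sum(clin)
    fate_mass["regressed", ] <<- fate_mass["regressed", ] + reg
    fate_mass["progressed_ibc", ] <<- fate_mass["progressed_ibc", ] + prog
    fate_mass["clin_detected", ] <<- fate_mass["clin_detected", ] + clin
    onset_mass <<- onset_mass + o
    invisible()
  }
  steps <- if (identical(scn$event_order, "screen_first"))
    list(screen_step, death_step, trans_step)
  else
    list(death_step, trans_step, screen_step)

  for (a in 0:ma) {
    traj[a + 1L, ] <- c(h, d, absorbed)
    for (f in steps) f(a)
    leak <- abs(1 - (h + sum(d) + sum(absorbed)))
    if (leak > tol)
      stop("internal error: probability mass leak ", leak, " at age ", a)
  }
  # mass still in the model past max_age is censored
  absorbed["censored"] <- absorbed["censored"] + h + sum(d)
  fate_mass["censored", ] <- fate_mass["censored", ] + d
  traj[A + 1L, ] <- c(0, 0, 0, 0, absorbed)

  structure(list(scenario = scn, trajectory = traj, det = det,
                 screens = screens, onset_mass = onset_mass,
                 fate_mass = fate_mass, absorbed = absorbed),
            class = "dcis_expect")
}

#' @export
print.dcis_expect <- function(x, ...) {
  cat(sprintf("Expected state distribution for scenario '%s'\n",
              x$scenario$label))
  cat("  absorbed mass:",
      paste(sprintf("%s %.4f", names(x$absorbed), x$absorbed),
            collapse = ", "), "\n")
  cat(sprintf("  expected DCIS episodes per woman: %.5f\n",
              sum(x$onset_mass)))
  if (sum(x$screens) > 0)
    cat(sprintf("  expected screen-detection rate: %.3f per 1,000 screens\n",
                1000 * sum(x$det) / sum(x$screens)))
  invisible(x)
}

#' @export
plot.dcis_expect <- function(x, ...) {
  tr <- x$trajectory[seq_len(nrow(x$trajectory) - 1L), , drop = FALSE]
  ages <- seq_len(nrow(tr)) - 1L
  dcis <- rowSums(tr[, 2:4])
  matplot(ages, cbind(tr[, "healthy"], dcis * 100),
          type = "l", lty = 1, col = c("grey40", "firebrick"),
          xlab = "age (years)",
          ylab = "probability mass (DCIS scaled x100)", ...)
  legend("left", legend = c("healthy", "DCIS present (x100)"),
         col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
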