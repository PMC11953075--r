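# Stochastic engine: schedules, forced paths, determinism, distributional
# checks of the yearly kernel.

test_that("screening schedules are arithmetic progressions within the policy", {
  expect_identical(schedule_screens(screening_policy(50, 74, 2, 0.76, 0.86)),
                   seq(50L, 74L, 2L))
  expect_length(schedule_screens(screening_policy(50, 74, 2, 0.76, 0.86)), 13)
  expect_identical(schedule_screens(screening_policy(50, 71, 3, 0.76, 0.86)),
                   seq(50L, 71L, 3L))
  expect_length(schedule_screens(screening_policy(50, 71, 3, 0.76, 0.86)), 8)
  expect_identical(schedule_screens(screening_policy(50, 50, 2, 1, 1)), 50L)
})

test_that("forced parameter values produce the forced life history", {
  # onset certain at 50, progression certain: one episode, IBC at 51
  scn <- toy_scenario(onset = c(0, 0, 1), onset_ages = 50, progression = 1)
  w <- simulate_woman(scn, seed = 5)
  expect_identical(w$exit_state, "ibc")
  expect_identical(nrow(w$episodes), 1L)
  expect_identical(w$episodes$grade, 3L)
  expect_identical(w$episodes$onset_age, 50L)
  expect_identical(w$episodes$fate, "progressed_ibc")
  expect_identical(w$episodes$fate_age, 51L)

  # no onset anywhere: no episodes, death from other causes
  w0 <- simulate_woman(toy_scenario(), seed = 5)
  expect_identical(w0$exit_state, "dead_other")
  expect_identical(nrow(w0$episodes), 0L)

  # prevalent DCIS at a fully attended, fully sensitive round is always found
  scn2 <- toy_scenario(onset = c(0, 1, 0), onset_ages = 50,
                       screening = list(start_age = 52, end_age = 52,
                                        interval = 2, participation = 1,
                                        sensitivity = 1))
  sim2 <- dcis_simulate(scn2, women = 200, iterations = 1, seed = 9)
  expect_identical(unname(sim2$exits[1, "screen_detected"]), 200)
  # and under the screen-first ordering as well
  scn3 <- toy_scenario(onset = c(0, 1, 0), onset_ages = 50,
                       screening = list(start_age = 52, end_age = 52,
                                        interval = 2, participation = 1,
                                        sensitivity = 1),
                       event_order = "screen_first")
  sim3 <- dcis_simulate(scn3, women = 200, iterations = 1, seed = 9)
  expect_identical(unname(sim3$exits[1, "screen_detected"]), 200)
})

test_that("every woman exits exactly once and every episode has one fate", {
  scn <- nl_scenario()
  sim <- dcis_simulate(scn, women = 5000, iterations = 3, seed = 21)
  # conservation of women
  expect_identical(unname(rowSums(sim$exits)), rep(5000, 3))
  # conservation of episodes: onsets match fates per iteration and grade
  for (i in 1:3)
    expect_identical(unname(colSums(sim$fates[i, , ])),
                     unname(sim$onsets[i, ]))
  # no screening policy means no screen-detections
  scn_ns <- scn; scn_ns$screening <- NULL
  sim_ns <- dcis_simulate(scn_ns, women = 5000, iterations = 1, seed = 21)
  expect_identical(sum(sim_ns$exits[, "screen_detected"]), 0)
  expect_identical(sum(sim_ns$mamm), 0)
})

test_that("identical seeds reproduce bit-identical results, different seeds agree statistically", {
  scn <- nl_scenario()
  a <- dcis_simulate(scn, women = 4000, iterations = 2, seed = 42)
  b <- dcis_simulate(scn, women = 4000, iterations = 2, seed = 42)
  expect_identical(a$det, b$det)
  expect_identical(a$fates, b$fates)
  expect_identical(a$exits, b$exits)
  expect_identical(a$mamm, b$mamm)
  expect_identical(a$child_seeds, b$child_seeds)

  c_ <- dcis_simulate(scn, women = 4000, iterations = 2, seed = 43)
  expect_false(identical(a$det, c_$det))
  ra <- detection_rates(a); rc <- detection_rates(c_)
  se <- sqrt(ra$se_mean[1]^2 + rc$se_mean[1]^2) * sqrt(2)  # 2 iterations
  expect_lt(abs(ra$mean[1] - rc$mean[1]), 4 * max(se, 0.2))
})

test_that("the yearly competing-risk draw is the specified multinomial", {
  # all women hold grade-3 DCIS for exactly one transition year; the
  # outcome frequencies must match (regression, progression, clinical)
  # within 3 binomial standard errors
  p <- c(reg = 0.0488, prog = 0.134, clin = 0.05)
  scn <- toy_scenario(max_age = 3, onset = c(0, 0, 1), onset_ages = 1,
                      regression = p["reg"], progression = p["prog"],
                      clinical = p["clin"])
  n <- 1e6
  sim <- dcis_simulate(scn, women = n, iterations = 1, seed = 99)
  got <- c(reg = sum(sim$fates[, "regressed", ]),
           prog = sum(sim$fates[, "progressed_ibc", ]),
           clin = sum(sim$fates[, "clin_detected", ]))
  for (k in names(p)) {
    se <- sqrt(n * p[[k]] * (1 - p[[k]]))
    expect_lt(abs(got[[k]] - n * p[[k]]), 3 * se)
  }
  # the remainder died with DCIS at the horizon's certain death
  expect_identical(unname(got[["reg"]] + got[["prog"]] + got[["clin"]] +
                            sum(sim$fates[, "died_other", ])), n)
})

test_that("time from onset to progression is geometric when unopposed", {
  # no other exit: P(progression each year) = p, mean dwell 1/p
  p <- 0.3
  scn <- toy_scenario(onset = c(1, 0, 0), onset_ages = 20, progression = p)
  sim <- dcis_simulate(scn, women = 3000, iterations = 1, seed = 7,
                       trace = TRUE)
  tr <- sim$traces[[1]]
  dwell <- tr$age[tr$event == "progressed_ibc"] -
    tr$age[tr$event == "onset"][match(tr$woman[tr$event == "progressed_ibc"],
                                      tr$woman[tr$event == "onset"])]
  expect_gte(min(dwell), 1)
  se <- sqrt((1 - p) / p^2 / length(dwell))
  expect_lt(abs(mean(dwell) - 1 / p), 3 * se)
})

test_that("competing-risk fate fractions follow the geometric closed form", {
  # P(regressed) = P3 / (P3 + P4 + P6) with no death and no screening
  scn <- toy_scenario(onset = c(0, 1, 0), onset_ages = 20,
                      regression = 0.05, progression = 0.15, clinical = 0.05)
  n <- 20000
  sim <- dcis_simulate(scn, women = n, iterations = 1, seed = 13)
  fd <- fate_distribution(sim)
  frac <- fd$fraction[fd$fate == "regressed"]
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.20), 3 * se)
})

test_that("regressed women return to risk and can have further episodes", {
  # high onset and certain regression: many onsets per woman
  scn <- toy_scenario(max_age = 30, onset = c(0.5, 0, 0),
                      onset_ages = 10:29, regression = 1)
  sim <- dcis_simulate(scn, women = 500, iterations = 1, seed = 3)
  expect_gt(sum(sim$onsets), 500)  # more episodes than women
  expect_identical(unname(colSums(sim$fates[1, , ])),
                   unname(sim$onsets[1, ]))
})
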