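# Reporting: summary table, stratified rates, fate/grade distributions,
# validation against observed references.

test_that("the summary table reports counts that balance", {
  # one woman, no events: she dies of other causes, nothing else
  one <- dcis_simulate(toy_scenario(), women = 1, iterations = 1, seed = 2)
  s <- summary(one)
  expect_identical(unname(s$pooled["removed_dead_other"]), 1)
  expect_identical(unname(s$pooled[c("onsets_g1", "onsets_g2", "onsets_g3",
                                     "removed_ibc",
                                     "removed_screen_detected",
                                     "removed_clin_detected",
                                     "mammograms")]),
                   rep(0, 7))

  # forced path: one grade-3 onset removed as IBC
  forced <- dcis_simulate(toy_scenario(onset = c(0, 0, 1), onset_ages = 50,
                                       progression = 1),
                          women = 1, iterations = 1, seed = 2)
  sf <- summary(forced)
  expect_identical(unname(sf$pooled["onsets_g3"]), 1)
  expect_identical(unname(sf$pooled["removed_ibc"]), 1)

  # removed counts always sum to the cohort size
  sim <- dcis_simulate(nl_scenario(), women = 3000, iterations = 2, seed = 8)
  s2 <- summary(sim)
  rem <- s2$per_iteration[, grep("^removed_", names(s2$per_iteration))]
  expect_identical(unname(rowSums(rem)), rep(3000, 2))
  expect_identical(unname(s2$per_iteration$mammograms),
                   unname(rowSums(sim$mamm)))
})

test_that("stratified rates are screen-count-weighted consistent with the total", {
  sim <- dcis_simulate(nl_scenario(), women = 8000, iterations = 3, seed = 15)
  r <- detection_rates(sim)
  tot <- r[r$type == "total", ]
  age <- r[r$type == "age", ]
  grd <- r[r$type == "grade", ]
  # age strata partition detections and screens
  expect_equal(sum(age$detections), tot$detections)
  expect_equal(sum(age$screens), tot$screens)
  expect_equal(1000 * sum(age$detections) / sum(age$screens),
               1000 * tot$detections / tot$screens)
  # grade strata share the total denominator and are additive
  expect_identical(unique(grd$screens), tot$screens)
  expect_equal(sum(grd$detections), tot$detections)
  # bounds bracket the mean
  expect_true(all(r$lower <= r$mean + 1e-12 & r$mean <= r$upper + 1e-12))
})

test_that("fate fractions sum to one over the six enumerated fates", {
  sim <- dcis_simulate(nl_scenario(), women = 5000, iterations = 2, seed = 5)
  fd <- fate_distribution(sim)
  expect_identical(fd$fate, c("regressed", "progressed_ibc",
                              "screen_detected", "clin_detected",
                              "died_other", "censored"))
  expect_equal(sum(fd$fraction), 1, tolerance = 1e-9)
})

test_that("grade distributions reflect the episode mix", {
  # only grade 2 arises
  g2 <- dcis_simulate(toy_scenario(onset = c(0, 0.001, 0),
                                   onset_ages = 30:60,
                                   screening = list(start_age = 50,
                                                    end_age = 60,
                                                    interval = 2,
                                                    participation = 1,
                                                    sensitivity = 1)),
                      women = 20000, iterations = 1, seed = 6)
  gd <- grade_distribution(g2)
  expect_identical(gd$fraction, c(0, 1, 0))
  # symmetric onset and hazards give a symmetric distribution
  sym <- dcis_simulate(toy_scenario(onset = rep(0.002, 3),
                                    onset_ages = 30:60,
                                    regression = 0.05, progression = 0.1,
                                    clinical = 0.05,
                                    screening = list(start_age = 50,
                                                     end_age = 60,
                                                     interval = 2,
                                                     participation = 0.8,
                                                     sensitivity = 0.9)),
                       women = 20000, iterations = 1, seed = 6)
  gds <- grade_distribution(sym)
  expect_equal(sum(gds$fraction), 1)
  n_det <- sum(sym$fates[, "screen_detected", ])
  se <- sqrt(1 / 3 * 2 / 3 / n_det)
  expect_true(all(abs(gds$fraction - 1 / 3) < 4 * se))
})

test_that("comparison with observed references flags strata correctly", {
  sim <- dcis_simulate(nl_scenario(), women = 5000, iterations = 4, seed = 31)
  r <- detection_rates(sim)
  # a reference equal to our own means is inside everywhere
  self_ref <- data.frame(stratum = r$stratum, type = r$type,
                         observed = r$mean)
  cmp <- compare_to_observed(r, self_ref)
  expect_true(all(cmp$inside))
  expect_identical(unique(cmp$direction), "")
  # mismatched strata raise an error
  bad <- data.frame(stratum = "45-49", type = "age", observed = 1)
  expect_error(compare_to_observed(r, bad), "absent")
  # shipped references load with the expected shape
  obs <- observed_reference("nl2019")
  expect_identical(names(obs), c("stratum", "type", "observed"))
  expect_identical(obs$observed[obs$type == "total"], 1.38)
  expect_identical(observed_reference("nhs2021")$observed[
    observed_reference("nhs2021")$type == "total"], 1.7)
})

test_that("the standard error of the mean rate shrinks with more iterations", {
  scn <- nl_scenario()
  r10 <- detection_rates(dcis_simulate(scn, women = 1500, iterations = 10,
                                       seed = 77))
  r40 <- detection_rates(dcis_simulate(scn, women = 1500, iterations = 40,
                                       seed = 77))
  expect_lt(r40$se_mean[r40$type == "total"],
            r10$se_mean[r10$type == "total"])
})
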