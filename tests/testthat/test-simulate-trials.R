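test_that("trial generation is deterministic given a seed", {
  eff <- line_effects(4, 4, seed = 1)
  t1 <- simulate_trials(eff, seed = 99)
  t2 <- simulate_trials(eff, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_trials(eff, seed = 100)
  expect_false(identical(t1, t3))
})

test_that("censoring and record invariants hold on generated tables", {
  eff <- line_effects(5, 5, seed = 2)
  tr <- simulate_trials(eff, censor_time = 3600, seed = 3)

  courted <- tr[tr$courted, ]
  expect_true(all(courted$copulation_latency > 0))
  expect_true(all(courted$copulation_latency <= 3600))
  # censored <=> recorded at exactly the recording limit
  expect_true(all(courted$copulation_latency[!courted$mated] == 3600))
  expect_true(all(courted$copulation_latency[courted$mated] < 3600))
  # mated implies courted; duration defined iff mated
  expect_true(all(!tr$mated | tr$courted))
  expect_true(all(is.na(tr$copulation_duration) != tr$mated))
  expect_true(all(is.na(tr$courtship_latency) != tr$courted))
})

test_that("every cell reaches the mating quota or the trial cap", {
  eff <- line_effects(5, 5, seed = 4)
  tr <- simulate_trials(eff, min_matings = 10, max_trials = 27, seed = 5)
  per_cell <- dplyr::summarise(
    dplyr::group_by(tr, male_line, female_line),
    n = dplyr::n(), matings = sum(mated), .groups = "drop")
  expect_equal(nrow(per_cell), 25)
  expect_true(all(per_cell$matings >= 10 | per_cell$n == 27))
  # generation stops at the trial that achieves the quota
  expect_true(all(per_cell$n <= 27))
  expect_error(simulate_trials(eff, min_matings = 10, max_trials = 5),
               "infeasible")
})

test_that("a noise-free symmetric generator collapses to one latency per channel", {
  eff <- line_effects(3, 3, traits = c(8, 8, 8), y_sd = 0, nu_sd = 0,
                      responsiveness_sd = 0, choosiness_sd = 0,
                      courtship_propensity_sd = 0, courtship_attract_sd = 0,
                      duration_propensity_sd = 0, duration_attract_sd = 0,
                      seed = 6)
  tr <- simulate_trials(eff, min_matings = 3, max_trials = 3, noise_sd = 0,
                        courtship_noise_sd = 0, duration_noise_sd = 0, seed = 7)
  expect_equal(length(unique(tr$courtship_latency)), 1L)
  expect_equal(length(unique(tr$copulation_latency)), 1L)
  expect_equal(length(unique(na.omit(tr$copulation_duration))), 1L)
})

test_that("mating proportion matches the normal-CDF prediction at 1 SD", {
  # log censor limit exactly 1 SD above the mean log latency, log-normal
  # channel, no courtship censoring: P(mate) = Phi(1)
  eff <- line_effects(2, 2, traits = c(8, 8), y_sd = 0,
                      responsiveness_sd = 0, choosiness_sd = 0,
                      courtship_propensity_sd = 0, courtship_attract_sd = 0,
                      seed = 8)
  n_per_cell <- 2500
  tr <- simulate_trials(eff, min_matings = n_per_cell, max_trials = n_per_cell,
                        censor_time = 3600,
                        baseline_copulation = log(3600) - 1, noise_sd = 1,
                        baseline_courtship = log(30), courtship_noise_sd = 0,
                        copulation_noise = "normal", seed = 9)
  prop <- mean(tr$mated)
  se <- sqrt(pnorm(1) * (1 - pnorm(1)) / nrow(tr))
  expect_lt(abs(prop - pnorm(1)), 4 * se)
})

test_that("analytic cell means agree with the law of large numbers", {
  eff <- line_effects(3, 3, model = "open_ended", seed = 10)
  exp_cells <- expected_cell_means(eff)

  # open-ended females (y > 0): expected log copulation latency strictly
  # decreases with male trait for every female line
  stopifnot(all(eff$females$y > 0))
  ord <- order(eff$males$trait)
  by_f <- split(exp_cells, exp_cells$female_line)
  for (d in by_f) {
    expect_true(all(diff(d$e_log_copulation[match(eff$males$line[ord],
                                                  d$male_line)]) < 0))
  }

  # zero offsets + flat preferences -> constant expectation table
  flat <- line_effects(3, 3, traits = c(5, 5, 5), y_sd = 0,
                       responsiveness_sd = 0, choosiness_sd = 0,
                       courtship_propensity_sd = 0, courtship_attract_sd = 0,
                       duration_propensity_sd = 0, duration_attract_sd = 0,
                       seed = 11)
  flat_cells <- expected_cell_means(flat)
  expect_equal(length(unique(flat_cells$e_log_copulation)), 1L)
  expect_equal(length(unique(flat_cells$e_log_courtship)), 1L)

  # empirical log cell means converge on the analytic table (no censoring)
  tr <- simulate_trials(eff, min_matings = 1000, max_trials = 1000,
                        censor_time = 1e9, noise_sd = 0.1,
                        courtship_noise_sd = 0.1, copulation_noise = "normal",
                        seed = 12)
  emp <- dplyr::summarise(
    dplyr::group_by(tr, male_line, female_line),
    m = mean(log(copulation_latency)), .groups = "drop")
  joined <- dplyr::inner_join(emp, exp_cells, by = c("male_line", "female_line"))
  se <- 0.1 / sqrt(1000)
  expect_true(all(abs(joined$m - joined$e_log_copulation) < 4 * se))
})
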