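make_cells <- function(chooser, partner, means, channel = "copulation_latency") {
  structure(tibble::tibble(chooser_line = chooser, partner_line = partner,
                           channel = channel, n = 5L, mean = means,
                           sd = NA_real_),
            class = c("cell_summary", class(tibble::tibble())))
}

test_that("cell means, SDs and counts match hand computation", {
  tl <- data.frame(chooser = "C1", partner = "P1", value = c(10, 20))
  cm <- cell_means(as_copulation_trials(tl), "copulation_latency")
  expect_equal(cm$n, 2L)
  expect_equal(cm$mean, 15)
  expect_equal(cm$sd, sqrt(50), tolerance = 1e-12)  # 7.0711

  # all values equal -> sd 0
  tl2 <- data.frame(chooser = "C1", partner = "P1", value = c(7, 7, 7))
  expect_equal(cell_means(as_copulation_trials(tl2), "copulation_latency")$sd, 0)

  # mated_only toggle: 2 mated + 1 censored trial -> n 2 vs 3
  tr <- as_copulation_trials(data.frame(chooser = "C1", partner = "P1",
                                        value = c(100, 200, 3600)))
  tr$mated[3] <- FALSE
  tr$copulation_duration[3] <- NA_real_
  expect_equal(cell_means(tr, "copulation_latency", mated_only = TRUE)$n, 2L)
  expect_equal(cell_means(tr, "copulation_latency", mated_only = FALSE)$n, 3L)
})

test_that("responsiveness is the unweighted mean of cell means", {
  cells <- make_cells("C1", c("P1", "P2"), c(100, 200))
  expect_equal(responsiveness(cells)$responsiveness, 150)
  one <- make_cells("C1", "P1", 123)
  expect_equal(responsiveness(one)$responsiveness, 123)
})

test_that("choosiness measures match their definitions on hand fixtures", {
  cells <- make_cells("C1", c("P1", "P2", "P3"), c(100, 200, 300))
  expect_equal(choosiness(cells, "sd")$choosiness, 100)
  expect_equal(choosiness(cells, "cv")$choosiness, 0.5)
  expect_equal(choosiness(cells, "cv2")$choosiness, 0.25)

  flat <- make_cells("C1", c("P1", "P2", "P3"), c(150, 150, 150))
  expect_equal(choosiness(flat, "sd")$choosiness, 0)

  expect_error(choosiness(make_cells("C1", "P1", 100)), ">= 2 cells")
  zero <- make_cells("C1", c("P1", "P2"), c(-100, 100))
  expect_error(choosiness(zero, "cv"), "zero mean")
  expect_error(choosiness(cells, "strength_total_sd"), "must be supplied")
})

test_that("choosiness invariances: sd under shifts, cv under rescaling", {
  for (seed in 1:5) {
    set.seed(seed)
    means <- exp(rnorm(8, 5, 0.5))
    cells <- make_cells("C1", sprintf("P%d", 1:8), means)
    shifted <- make_cells("C1", sprintf("P%d", 1:8), means + 250)
    expect_equal(choosiness(cells, "sd")$choosiness,
                 choosiness(shifted, "sd")$choosiness)
    scaled <- make_cells("C1", sprintf("P%d", 1:8), means * 3.7)
    expect_equal(choosiness(cells, "cv")$choosiness,
                 choosiness(scaled, "cv")$choosiness)
  }
})

test_that("all component statistics match the brute-force oracle", {
  for (seed in 1:20) {
    tl <- random_trial_values(seed)
    trials <- as_copulation_trials(tl)
    cells <- cell_means(trials, "copulation_latency")
    oracle <- bf_components(tl)

    resp <- responsiveness(cells)
    att <- global_attractiveness(cells)
    for (ln in names(oracle)) {
      expect_equal(resp$responsiveness[resp$chooser_line == ln],
                   oracle[[ln]]$responsiveness)
      for (m in c("sd", "cv", "cv2", "strength_total_sd", "strength_max_sd")) {
        got <- choosiness(cells, m, trials = trials)
        expect_equal(got$choosiness[got$chooser_line == ln],
                     unname(oracle[[ln]][[m]]),
                     tolerance = 1e-12, label = paste(m, "line", ln, "seed", seed))
      }
    }
    # global attractiveness is the chooser-side statistic with roles flipped
    flipped <- bf_components(data.frame(chooser = tl$partner,
                                        partner = tl$chooser,
                                        value = tl$value))
    for (ln in names(flipped)) {
      expect_equal(att$attractiveness[att$partner_line == ln],
                   flipped[[ln]]$responsiveness)
      expect_equal(att$inverse_attractiveness[att$partner_line == ln],
                   1 / flipped[[ln]]$responsiveness)
    }
  }
})

test_that("attractiveness ranking by latency reverses under the inverse transform", {
  tl <- random_trial_values(33)
  att <- global_attractiveness(cell_means(as_copulation_trials(tl),
                                          "copulation_latency"))
  expect_equal(rank(att$attractiveness), rev(rank(rev(att$attractiveness))))
  expect_equal(order(att$attractiveness), rev(order(att$inverse_attractiveness)))
})

test_that("channel roles route choosers correctly and empty cells warn", {
  eff <- line_effects(3, 3, seed = 1)
  tr <- simulate_trials(eff, seed = 2)
  cop <- cell_means(tr, "copulation_latency")
  crt <- cell_means(tr, "courtship_latency")
  expect_setequal(unique(cop$chooser_line), unique(tr$female_line))
  expect_setequal(unique(crt$chooser_line), unique(tr$male_line))

  # dropping one cell entirely triggers the empty-cell warning
  tr_cut <- tr[!(tr$male_line == "L01" & tr$female_line == "L02"), ]
  expect_warning(cell_means(tr_cut, "copulation_latency"), "empty cell")
})

test_that("estimated responsiveness ranks track the generating offsets", {
  # known line effects at modest noise: Spearman correlation of true vs
  # estimated responsiveness ranks >= 0.9
  eff <- line_effects(10, 10, model = "open_ended", seed = 21)
  tr <- simulate_trials(eff, noise_sd = 0.2, seed = 22)
  est <- responsiveness(cell_means(tr, "copulation_latency", log = TRUE))
  truth <- eff$females$responsiveness_offset[
    match(est$chooser_line, eff$females$line)]
  expect_gte(cor(est$responsiveness, truth, method = "spearman"), 0.9)
})
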