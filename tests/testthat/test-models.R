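test_that("an injected male-line effect is detected only where injected", {
  # strong male courtship propensity variation, everything else flat
  eff <- line_effects(4, 4, courtship_propensity_sd = 1.2,
                      courtship_attract_sd = 0, responsiveness_sd = 0,
                      y_sd = 0, seed = 31)
  tr <- simulate_trials(eff, min_matings = 15, max_trials = 15,
                        courtship_noise_sd = 0.5, seed = 32)
  et <- tidy(fit_courtship_model(tr))
  expect_lt(et$p.value[et$term == "male_line"], 0.01)
  expect_gt(et$p.value[et$term == "male_line:female_line"], 0.01)
})

test_that("injected female hazard effects surface in the Cox model", {
  # female responsiveness variation drives copulation latency; the male
  # side is flat, so its LR test sits near its null
  eff <- line_effects(4, 4, traits = rep(8, 4), y_sd = 0,
                      responsiveness_sd = 1, choosiness_sd = 0,
                      stimulus_scale = 0, seed = 33)
  tr <- simulate_trials(eff, min_matings = 15, max_trials = 15, seed = 34)
  et <- tidy(fit_copulation_model(tr))
  expect_lt(et$p.value[et$term == "female_line"], 1e-4)
  expect_gt(et$p.value[et$term == "male_line"], 0.01)
  expect_true(all(et$statistic >= 0))
  expect_equal(et$df[et$term == "male_line:female_line"], 9L)
})

test_that("duplicating a dataset approximately doubles the Cox LR statistics", {
  eff <- line_effects(3, 3, responsiveness_sd = 0.6, seed = 35)
  tr <- simulate_trials(eff, min_matings = 12, max_trials = 12, seed = 36)
  lr1 <- tidy(fit_copulation_model(tr, effects = "female_line"))$statistic
  tr2 <- dplyr::bind_rows(tr, tr)
  lr2 <- tidy(fit_copulation_model(tr2, effects = "female_line"))$statistic
  expect_gt(lr2 / lr1, 1.6)
  expect_lt(lr2 / lr1, 2.4)
})

test_that("LR statistics are invariant to relabeling line identifiers", {
  eff <- line_effects(3, 3, seed = 37)
  tr <- simulate_trials(eff, seed = 38)
  et1 <- tidy(fit_copulation_model(tr, effects = c("male_line", "female_line")))
  relab <- tr
  map <- c(L01 = "Z3", L02 = "Z1", L03 = "Z2")
  relab$male_line <- unname(map[relab$male_line])
  relab$female_line <- unname(map[relab$female_line])
  et2 <- tidy(fit_copulation_model(relab, effects = c("male_line", "female_line")))
  expect_equal(et1$statistic, et2$statistic, tolerance = 1e-8)
})

test_that("degenerate or incomplete designs are rejected with named cells", {
  eff <- line_effects(3, 3, seed = 39)
  tr <- simulate_trials(eff, seed = 40)
  single <- tr[tr$male_line == "L01" & tr$female_line == "L01", ]
  expect_error(fit_courtship_model(single), "degenerate")
  expect_error(fit_copulation_model(single), "degenerate")
  cut <- tr[!(tr$male_line == "L02" & tr$female_line == "L03"), ]
  expect_error(fit_courtship_model(cut), "L02/L03")
  expect_error(fit_copulation_model(cut), "L02/L03")
})

test_that("the duration model controls for earlier stages and finds male effects", {
  eff <- line_effects(4, 4, duration_propensity_sd = 0.8,
                      duration_attract_sd = 0, courtship_propensity_sd = 0,
                      courtship_attract_sd = 0, responsiveness_sd = 0,
                      y_sd = 0, seed = 41)
  tr <- simulate_trials(eff, min_matings = 15, max_trials = 15,
                        duration_noise_sd = 0.3, seed = 42)
  et <- tidy(fit_duration_model(tr))
  expect_lt(et$p.value[et$term == "male_line"], 0.01)
  expect_gt(et$p.value[et$term == "male_line:female_line"], 0.01)
  expect_true(all(c("log(courtship_latency)", "log(copulation_latency)") %in%
                    et$term))
})

test_that("effect tables carry tidy/glance metadata", {
  eff <- line_effects(3, 3, seed = 43)
  tr <- simulate_trials(eff, seed = 44)
  fit <- fit_courtship_model(tr)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit), c("channel", "n", "formula"))
  expect_equal(glance(fit)$channel, "courtship_latency")
})

test_that("Levene's test matches hand-computed absolute-deviation ANOVA", {
  # groups {0,4} and {1,5,9}: |dev| = {2,2} and {4,0,4};
  # SSB = 8/15, SSW = 32/3 -> F = (8/15) / ((32/3)/3) = 0.15 on df (1, 3)
  lt <- levene_test(c(0, 4, 1, 5, 9), c("a", "a", "b", "b", "b"))
  expect_equal(lt$statistic, 0.15, tolerance = 1e-12)
  expect_equal(c(lt$df, lt$df_residual), c(1L, 3L))

  # identical value-multisets -> F = 0
  lt0 <- levene_test(c(1, 5, 2, 1, 5, 2), rep(c("a", "b"), each = 3))
  expect_equal(lt0$statistic, 0)

  # brute-force oracle on random fixtures (classic mean-centered Levene)
  for (seed in 1:10) {
    set.seed(seed)
    g <- rep(letters[1:4], times = sample(3:8, 4, replace = TRUE))
    x <- rnorm(length(g), 0, rep(runif(4, 0.5, 2), table(g)[letters[1:4]]))
    z <- abs(x - ave(x, g))
    a <- anova(lm(z ~ g))
    lt <- levene_test(x, g)
    expect_equal(lt$statistic, a$`F value`[1], tolerance = 1e-10)
    expect_equal(lt$p.value, a$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_error(levene_test(1:4, rep("a", 4)), "two groups")
})

test_that("levene_choosiness uses capped latencies by default and flags genetic variation", {
  eff <- line_effects(5, 5, choosiness_sd = 0.35, stimulus_scale = 0.6, seed = 45)
  tr <- simulate_trials(eff, seed = 46)
  lt <- levene_choosiness(tr)
  expect_equal(lt$n, sum(tr$courted))
  expect_equal(lt$df_residual, sum(tr$courted) - 5L)
  lt_mated <- levene_choosiness(tr, mated_only = TRUE)
  expect_equal(lt_mated$n, sum(tr$mated))
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  for (seed in 1:10) {
    set.seed(seed)
    p <- runif(15)
    adj <- fdr_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
    # step-up definition computed directly
    n <- length(p); o <- order(p)
    manual <- rev(cummin(rev(p[o] * n / seq_len(n))))[order(o)]
    expect_equal(adj, pmin(manual, 1))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust(c(0.5, NA)), "\\[0, 1\\]")
})
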