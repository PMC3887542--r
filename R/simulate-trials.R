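#' Simulate a factorial no-choice mating-trial table
#'
#' Generates one row per no-choice trial for every (male line, female line)
#' cell of the factorial design, with the statistical structure of the
#' empirical assay: log-normal latencies, right-censoring of copulation
#' latency at the recording limit, and trials added per cell until a
#' minimum number of successful matings is reached (or a per-cell trial cap
#' is hit).
#'
#' The generative model is log-scale additive. For a trial of female line
#' f with male line m:
#' \itemize{
#'   \item `ln courtship_latency = baseline_courtship +
#'     courtship_propensity[m] + courtship_attract[f] + noise`; the pair
#'     courts if this latency is within `censor_time`.
#'   \item `ln copulation_latency = baseline_copulation - gamma[f] * s[f, m]
#'     + responsiveness_offset[f] + noise`, where `s[f, m]` is the female
#'     line's z-scored log preference for the male line (see
#'     [line_effects()]); the pair mates if the pair courted and this
#'     latency is within `censor_time`, otherwise the latency is recorded
#'     censored at `censor_time`.
#'   \item `ln copulation_duration = baseline_duration +
#'     duration_propensity[m] + duration_attract[f] + noise`, defined only
#'     for mated pairs.
#' }
#' The male-controlled channels use Gaussian log-scale noise (log-normal
#' latencies), matching the log-transformed linear models that analyze
#' them. For the copulation channel the default noise is a standardized
#' Gumbel (minimum) variate, which makes the latencies Weibull with a
#' proportional-hazards structure: under an additive linear predictor the
#' Cox genotype-interaction test is then correctly calibrated. Set
#' `copulation_noise = "normal"` for a log-normal copulation channel
#' instead (an additive-accelerated-failure-time world that a Cox model
#' only approximates). Either way the noise has mean 0 and SD `noise_sd`
#' on the log scale. Ages are sampled uniformly and independently of line;
#' array and chamber identifiers are pure labels (20 chambers per array).
#'
#' @param effects A [line_effects()] object.
#' @param min_matings Minimum successful matings per cell (default 10).
#' @param max_trials Cap on trials per cell (default 27).
#' @param censor_time Recording limit in seconds (default 3600).
#' @param ages Integer vector of possible fly ages in days (default 3:6).
#' @param baseline_copulation,baseline_courtship,baseline_duration
#'   Baseline log-latencies (log-seconds).
#' @param noise_sd,courtship_noise_sd,duration_noise_sd Residual SDs on the
#'   log scale.
#' @param copulation_noise Noise family for the copulation channel:
#'   `"gumbel"` (default; Weibull latencies, proportional hazards) or
#'   `"normal"` (log-normal latencies).
#' @param seed Optional integer seed; identical inputs and seed give an
#'   identical table.
#' @return A tibble with one row per trial: `male_line`, `female_line`,
#'   `male_age`, `female_age`, `array_id`, `chamber`, `courted`,
#'   `courtship_latency`, `mated`, `copulation_latency` (equal to
#'   `censor_time` with `mated = FALSE` when censored), and
#'   `copulation_duration` (`NA` unless mated). The `censor_time` used is
#'   attached as an attribute.
#' @examples
#' eff <- line_effects(4, 4, seed = 1)
#' trials <- simulate_trials(eff, seed = 2)
#' dplyr::count(trials, mated)
#' @export
simulate_trials <- function(effects,
                            min_matings = 10, max_trials = 27,
                            censor_time = 3600,
                            ages = 3:6,
                            baseline_copulation = log(600),
                            baseline_courtship = log(90),
                            baseline_duration = log(1200),
                            noise_sd = 0.9,
                            courtship_noise_sd = 0.9,
                            duration_noise_sd = 0.35,
                            copulation_noise = c("gumbel", "normal"),
                            seed = NULL) {
  copulation_noise <- match.arg(copulation_noise)
  stopifnot(inherits(effects, "line_effects"))
  min_matings <- check_scalar_int(min_matings, "min_matings", min = 1L)
  max_trials <- check_scalar_int(max_trials, "max_trials", min = 1L)
  if (max_trials < min_matings) {
    abort("infeasible design: `max_trials` must be >= `min_matings`.")
  }
  check_positive(censor_time, "censor_time")
  if (noise_sd < 0 || courtship_noise_sd < 0 || duration_noise_sd < 0) {
    abort("noise SDs must be >= 0.")
  }
  maybe_set_seed(seed)

  s <- stimulus_matrix(effects)
  males <- effects$males
  females <- effects$females
  cells <- tidyr::expand_grid(female_line = females$line, male_line = males$line)

  res <- purrr::pmap_dfr(cells, function(female_line, male_line) {
    f <- females[females$line == female_line, ]
    m <- males[males$line == male_line, ]
    n <- max_trials
    court_raw <- exp(baseline_courtship + m$courtship_propensity +
                       f$courtship_attract + rnorm(n, 0, courtship_noise_sd))
    courted <- court_raw <= censor_time
    cop_eps <- switch(copulation_noise,
      normal = rnorm(n, 0, noise_sd),
      gumbel = noise_sd * (log(stats::rexp(n)) + 0.5772156649) / (pi / sqrt(6))
    )
    cop_raw <- exp(baseline_copulation - f$gamma * s[female_line, male_line] +
                     f$responsiveness_offset + cop_eps)
    mated <- courted & cop_raw <= censor_time
    # stop at the trial that achieves the target number of matings
    k <- if (sum(mated) >= min_matings) which(cumsum(mated) == min_matings)[1L] else n
    idx <- seq_len(k)
    dur <- exp(baseline_duration + m$duration_propensity + f$duration_attract +
                 rnorm(n, 0, duration_noise_sd))
    tibble::tibble(
      male_line = male_line,
      female_line = female_line,
      male_age = sample(ages, k, replace = TRUE),
      female_age = sample(ages, k, replace = TRUE),
      courted = courted[idx],
      courtship_latency = ifelse(courted[idx], court_raw[idx], NA_real_),
      mated = mated[idx],
      copulation_latency = ifelse(courted[idx], pmin(cop_raw[idx], censor_time),
                                  NA_real_),
      copulation_duration = ifelse(mated[idx], dur[idx], NA_real_)
    )
  })

  n <- nrow(res)
  res$array_id <- sprintf("A%03d", (seq_len(n) - 1L) %/% 20L + 1L)
  res$chamber <- (seq_len(n) - 1L) %% 20L + 1L
  res <- res[, trial_columns()]
  attr(res, "censor_time") <- censor_time
  res
}

#' Analytic per-cell expected log latencies
#'
#' Noise-free expected values of the three log-scale latency channels for
#' every (male line, female line) cell, ignoring censoring. Serves as a
#' closed-form oracle for parameter-recovery checks against
#' [simulate_trials()]: empirical cell means of log latencies converge to
#' these values as the noise SDs shrink (censoring aside).
#'
#' @inheritParams simulate_trials
#' @return Tibble with `male_line`, `female_line`, `e_log_courtship`,
#'   `e_log_copulation`, `e_log_duration`.
#' @export
expected_cell_means <- function(effects,
                                baseline_copulation = log(600),
                                baseline_courtship = log(90),
                                baseline_duration = log(1200)) {
  stopifnot(inherits(effects, "line_effects"))
  s <- stimulus_matrix(effects)
  cells <- tidyr::expand_grid(female_line = effects$females$line,
                              male_line = effects$males$line)
  purrr::pmap_dfr(cells, function(female_line, male_line) {
    f <- effects$females[effects$females$line == female_line, ]
    m <- effects$males[effects$males$line == male_line, ]
    tibble::tibble(
      male_line = male_line,
      female_line = female_line,
      e_log_courtship = baseline_courtship + m$courtship_propensity +
        f$courtship_attract,
      e_log_copulation = baseline_copulation - f$gamma * s[female_line, male_line] +
        f$responsiveness_offset,
      e_log_duration = baseline_duration + m$duration_propensity +
        f$duration_attract
    )
  })
}

trial_columns <- function() {
  c("male_line", "female_line", "male_age", "female_age", "array_id",
    "chamber", "courted", "courtship_latency", "mated",
    "copulation_latency", "copulation_duration")
}
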