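# shared preparation for the base-model fits: factor coding with sum-to-zero
# contrasts (so type-III marginal tests match JMP-style effect tests),
# completeness check of the line x line design, and logged row filtering
prepare_model_data <- function(trials, require, channel) {
  stopifnot(is.data.frame(trials))
  dat <- trials[require(trials), , drop = FALSE]
  n0 <- nrow(dat)
  dat <- dat[!is.na(dat$male_age) & !is.na(dat$female_age), , drop = FALSE]
  if (nrow(dat) < n0) {
    inform(sprintf("%d row(s) dropped for missing ages.", n0 - nrow(dat)))
  }
  if (nrow(dat) == 0L) abort("no usable trials for this channel.")
  if (length(unique(dat$male_line)) < 2L || length(unique(dat$female_line)) < 2L) {
    abort("degenerate design: need at least two male and two female lines.")
  }
  present <- dplyr::distinct(dat, .data$male_line, .data$female_line)
  full <- tidyr::expand_grid(male_line = unique(dat$male_line),
                             female_line = unique(dat$female_line))
  missing <- dplyr::anti_join(full, present, by = c("male_line", "female_line"))
  if (nrow(missing) > 0L) {
    abort(sprintf(
      "rank-deficient design: no %s trials for cell(s) %s.", channel,
      paste(missing$male_line, missing$female_line, sep = "/", collapse = ", ")))
  }
  dat$male_line <- factor(dat$male_line)
  dat$female_line <- factor(dat$female_line)
  dat$male_age <- factor(dat$male_age)
  dat$female_age <- factor(dat$female_age)
  dat
}

sum_contrasts <- function(dat, vars) {
  vars <- vars[vapply(vars, function(v) is.factor(dat[[v]]) &&
                        nlevels(dat[[v]]) > 1L, logical(1))]
  stats::setNames(
    lapply(vars, function(v) stats::contr.sum(nlevels(dat[[v]]))), vars)
}

base_terms <- function() {
  c("male_line", "female_line", "male_age", "female_age",
    "male_line:female_line")
}

new_effect_fit <- function(effects, fit, channel, n, formula, subclass) {
  structure(
    list(effects = effects, fit = fit, channel = channel, n = n,
         formula = formula),
    class = c(subclass, "effect_fit"))
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("<%s> channel: %s, n = %d\n", class(x)[1L], x$channel, x$n))
  cat("formula:", paste(deparse(x$formula), collapse = " "), "\n")
  print(x$effects)
  invisible(x)
}

#' @rdname fit_courtship_model
#' @param x,object An `effect_fit` object.
#' @param ... Unused.
#' @export
tidy.effect_fit <- function(x, ...) x$effects

#' @rdname fit_courtship_model
#' @export
glance.effect_fit <- function(x, ...) {
  tibble::tibble(channel = x$channel, n = x$n,
                 formula = paste(deparse(x$formula), collapse = " "))
}

fit_lm_channel <- function(trials, channel, response_expr, extra_terms,
                           require, subclass) {
  dat <- prepare_model_data(trials, require, channel)
  rhs <- paste(c("male_line * female_line", "male_age", "female_age",
                 extra_terms), collapse = " + ")
  form <- as.formula(paste(response_expr, "~", rhs))
  fit <- lm(form, data = dat,
            contrasts = sum_contrasts(dat, c("male_line", "female_line",
                                             "male_age", "female_age")))
  an <- car::Anova(fit, type = 3)
  keep <- !rownames(an) %in% c("(Intercept)", "Residuals")
  effects <- tibble::tibble(
    term = rownames(an)[keep],
    df = an$Df[keep],
    sumsq = an$`Sum Sq`[keep],
    meansq = an$`Sum Sq`[keep] / an$Df[keep],
    statistic = an$`F value`[keep],
    p.value = an$`Pr(>F)`[keep]
  )
  new_effect_fit(effects, fit, channel, nrow(dat), form, subclass)
}

#' Linear model for courtship latency
#'
#' Fits the base model for the male-controlled courtship-latency channel:
#' a general linear model on natural-log courtship latency with male
#' genotype, female genotype, male age, female age, and the male x female
#' genotype interaction, using sum-to-zero contrasts and type-III
#' (marginal) F tests. A significant male-genotype effect indicates genetic
#' variation in male courtship propensity; a female-genotype effect,
#' genetic variation in female attractiveness to males; a genotype
#' interaction, that male genotypes rank female genotypes differently.
#'
#' @param trials Trial table; only courted trials enter.
#' @return An object of class `c("pref_lm", "effect_fit")`. `tidy()`
#'   returns the effect table (`term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`); `glance()` the model metadata.
#' @examples
#' trials <- simulate_trials(line_effects(4, 4, seed = 1), seed = 2)
#' tidy(fit_courtship_model(trials))
#' @export
fit_courtship_model <- function(trials) {
  fit_lm_channel(trials, "courtship_latency", "log(courtship_latency)",
                 character(),
                 function(d) d$courted & !is.na(d$courtship_latency),
                 "pref_lm")
}

#' Linear model for copulation duration
#'
#' As [fit_courtship_model()] but for the (male-controlled) copulation
#' duration of mated pairs, on the natural-log scale, with log courtship
#' latency and log copulation latency added as covariates to control for
#' the earlier stages of the trial.
#'
#' @inheritParams fit_courtship_model
#' @return An object of class `c("pref_lm", "effect_fit")`.
#' @export
fit_duration_model <- function(trials) {
  fit_lm_channel(trials, "copulation_duration", "log(copulation_duration)",
                 c("log(courtship_latency)", "log(copulation_latency)"),
                 function(d) d$mated & !is.na(d$copulation_duration) &
                   !is.na(d$courtship_latency) & !is.na(d$copulation_latency),
                 "pref_lm")
}

#' Cox proportional-hazards model for censored copulation latency
#'
#' Copulation latency is right-censored at the recording limit (pairs that
#' never mate), so the female-controlled channel is analyzed with a Cox
#' proportional-hazards model (Efron tie handling): event = mated,
#' time = copulation latency, covariates = the base model (male genotype,
#' female genotype, male age, female age, male x female genotype
#' interaction) plus log courtship latency. Each effect is tested with a
#' likelihood-ratio chi-square from a nested refit that removes the
#' effect's sum-to-zero model-matrix columns while keeping all other
#' effects (type-III-style marginal tests, so a main effect is testable in
#' the presence of the interaction). Cells without events contribute
#' through censoring only; cells that are all-censored or all-event are
#' flagged in the returned object.
#'
#' @inheritParams fit_courtship_model
#' @param effects Character vector of terms to test (default: all base
#'   terms plus the courtship-latency covariate). Restricting this (e.g. to
#'   `"male_line:female_line"`) skips the other nested refits.
#' @return An object of class `c("pref_coxph", "effect_fit")`; `tidy()`
#'   gives `term`, `df`, `statistic` (LR chi-square), `p.value`.
#' @examples
#' trials <- simulate_trials(line_effects(4, 4, seed = 1), seed = 2)
#' tidy(fit_copulation_model(trials, effects = "male_line:female_line"))
#' @export
fit_copulation_model <- function(trials, effects = NULL) {
  dat <- prepare_model_data(
    trials, function(d) d$courted & !is.na(d$copulation_latency) &
      !is.na(d$courtship_latency), "copulation_latency")
  terms_all <- c(base_terms(), "log(courtship_latency)")
  effects <- effects %||% terms_all
  if (!all(effects %in% terms_all)) {
    abort(sprintf("unknown effect(s): %s",
                  paste(setdiff(effects, terms_all), collapse = ", ")))
  }
  form <- as.formula(paste("~", paste(terms_all, collapse = " + ")))
  mm <- stats::model.matrix(
    form, dat,
    contrasts.arg = sum_contrasts(dat, c("male_line", "female_line",
                                         "male_age", "female_age")))
  assign <- attr(mm, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  X <- mm[, assign != 0L, drop = FALSE]
  col_term <- labels[assign[assign != 0L]]
  y <- survival::Surv(dat$copulation_latency, dat$mated)

  cox_ll <- function(Xsub) {
    fit <- survival::coxph(y ~ Xsub, ties = "efron",
                           control = survival::coxph.control(iter.max = 100))
    list(ll = fit$loglik[2L], df = sum(!is.na(coef(fit))), fit = fit)
  }
  full <- cox_ll(X)

  eff <- purrr::map_dfr(effects, function(term) {
    red <- cox_ll(X[, col_term != term, drop = FALSE])
    df <- full$df - red$df
    lr <- 2 * (full$ll - red$ll)
    tibble::tibble(term = term, df = df, statistic = lr,
                   p.value = pchisq(lr, df, lower.tail = FALSE))
  })

  flagged <- dat |>
    dplyr::group_by(.data$male_line, .data$female_line) |>
    dplyr::summarise(events = sum(.data$mated), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$events == 0L | .data$events == .data$n)
  out <- new_effect_fit(
    eff, full$fit, "copulation_latency", nrow(dat),
    as.formula(paste("survival::Surv(copulation_latency, mated)",
                     paste(deparse(form), collapse = ""))),
    "pref_coxph")
  out$all_censored_or_event_cells <- flagged
  out
}
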