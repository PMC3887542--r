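#' Levene's test for homogeneity of variance
#'
#' Classic Levene test: a one-way ANOVA on absolute deviations of each
#' observation from its group center. The default center is the group mean
#' (the classic form); `center = "median"` gives the Brown-Forsythe
#' variant.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector (coerced to factor) of the same length.
#' @param center `"mean"` (classic) or `"median"`.
#' @return Tibble with `statistic` (F), `df`, `df_residual`, `p.value`,
#'   `center`, `n`.
#' @examples
#' levene_test(c(1, 5, 3, 2, 4, 9), rep(c("a", "b"), each = 3))
#' @export
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  check_number(values, "values")
  if (length(values) != length(group)) {
    abort("`values` and `group` must have the same length.")
  }
  group <- factor(group)
  if (nlevels(group) < 2L) abort("Levene's test needs at least two groups.")
  if (any(table(group) < 2L)) {
    abort("Levene's test needs at least two observations per group.")
  }
  lt <- car::leveneTest(values, group,
                        center = if (center == "mean") mean else median)
  tibble::tibble(
    statistic = lt$`F value`[1L],
    df = lt$Df[1L],
    df_residual = lt$Df[2L],
    p.value = lt$`Pr(>F)`[1L],
    center = center,
    n = length(values)
  )
}

#' Levene's test for genetic variation in choosiness
#'
#' Choosiness is a SD among a line's per-partner cell means, so lines that
#' differ in choosiness differ in the variance of their trial-level
#' responses. This compares those variances among chooser lines with
#' Levene's test on per-trial responses grouped by chooser line. Because
#' the lines are isogenic, a significant result signals genetic variation
#' in choosiness.
#'
#' @inheritParams cell_means
#' @param center Passed to [levene_test()].
#' @param mated_only For copulation latency: `FALSE` (default) enters
#'   every courted trial with censored latencies capped at the recording
#'   limit, so all trials contribute; `TRUE` restricts to mated trials.
#' @return Tibble as [levene_test()], plus `channel`.
#' @examples
#' trials <- simulate_trials(line_effects(4, 4, seed = 1), seed = 2)
#' levene_choosiness(trials)
#' @export
levene_choosiness <- function(trials, channel = c("copulation_latency",
                                                  "courtship_latency",
                                                  "copulation_duration"),
                              center = c("mean", "median"),
                              mated_only = FALSE, log = FALSE) {
  channel <- match.arg(channel)
  center <- match.arg(center)
  stopifnot(is.data.frame(trials))
  roles <- channel_roles(channel)
  keep <- switch(channel,
    copulation_latency = if (mated_only) trials$mated else trials$courted,
    courtship_latency = trials$courted,
    copulation_duration = trials$mated
  )
  dat <- trials[keep & !is.na(trials[[channel]]), ]
  vals <- dat[[channel]]
  if (log) vals <- base::log(vals)
  out <- levene_test(vals, dat[[roles$chooser]], center = center)
  out$channel <- channel
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a family of p-values. Adjusted values are
#' monotone in the raw values, never smaller than them, and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted p-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be p-values in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}
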