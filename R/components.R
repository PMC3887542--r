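# chooser/partner roles per response channel: copulation latency is
# female-controlled, courtship latency and copulation duration male-controlled
channel_roles <- function(channel) {
  switch(channel,
    copulation_latency = list(chooser = "female_line", partner = "male_line"),
    courtship_latency = ,
    copulation_duration = list(chooser = "male_line", partner = "female_line"),
    abort(sprintf("unknown channel '%s'", channel))
  )
}

trial_channels <- function() {
  c("copulation_latency", "courtship_latency", "copulation_duration")
}

#' Per-cell summaries of a response channel
#'
#' Mean, sample SD and count of one response channel for every
#' (chooser line, partner line) cell of the factorial design. The chooser
#' sex depends on the channel: copulation latency is female-controlled
#' (chooser = female line), while courtship latency and copulation duration
#' are male-controlled (chooser = male line).
#'
#' @param trials Trial table (see [simulate_trials()] or [read_trials()]).
#' @param channel One of `"copulation_latency"`, `"courtship_latency"`,
#'   `"copulation_duration"`.
#' @param mated_only For copulation latency: if `TRUE` (default) use only
#'   mated trials (censored trials carry no observed latency); if `FALSE`
#'   include censored trials at their recorded value (`censor_time`).
#'   Copulation duration always uses mated trials; courtship latency uses
#'   courted trials.
#' @param log If `TRUE`, summarize natural-log values.
#' @return Tibble of class `"cell_summary"` with `chooser_line`,
#'   `partner_line`, `channel`, `n`, `mean`, `sd` (`NA` when `n < 2`).
#'   Empty cells are omitted with a warning.
#' @examples
#' trials <- simulate_trials(line_effects(4, 4, seed = 1), seed = 2)
#' cell_means(trials, "copulation_latency")
#' @export
cell_means <- function(trials, channel = c("copulation_latency",
                                           "courtship_latency",
                                           "copulation_duration"),
                       mated_only = TRUE, log = FALSE) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) abort("`trials` is empty.")
  roles <- channel_roles(channel)

  keep <- switch(channel,
    copulation_latency = if (mated_only) trials$mated else trials$courted,
    courtship_latency = trials$courted,
    copulation_duration = trials$mated
  )
  dat <- trials[keep & !is.na(trials[[channel]]), ]
  vals <- dat[[channel]]
  if (log) vals <- base::log(vals)

  all_cells <- tidyr::expand_grid(
    chooser_line = sort(unique(trials[[roles$chooser]])),
    partner_line = sort(unique(trials[[roles$partner]]))
  )
  out <- tibble::tibble(
    chooser_line = dat[[roles$chooser]],
    partner_line = dat[[roles$partner]],
    value = vals
  ) |>
    dplyr::group_by(.data$chooser_line, .data$partner_line) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop") |>
    dplyr::mutate(channel = channel, .after = "partner_line")

  n_missing <- nrow(all_cells) - nrow(out)
  if (n_missing > 0L) {
    missing <- dplyr::anti_join(all_cells, out,
                                by = c("chooser_line", "partner_line"))
    warn(sprintf("%d empty cell(s) omitted: %s", n_missing,
                 paste(missing$chooser_line, missing$partner_line,
                       sep = "/", collapse = ", ")))
  }
  class(out) <- c("cell_summary", class(out))
  out
}

#' Line-level responsiveness
#'
#' A chooser line's responsiveness is the unweighted mean of its per-partner
#' cell means: its average response across all partner genotypes, a measure
#' of motivation to mate.
#'
#' @param cells A [cell_means()] table.
#' @return Tibble with `chooser_line`, `channel`, `responsiveness`.
#' @export
responsiveness <- function(cells) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1L)
  cells |>
    dplyr::group_by(.data$chooser_line, .data$channel) |>
    dplyr::summarise(responsiveness = mean(.data$mean), .groups = "drop")
}

#' Line-level choosiness
#'
#' Variability of a chooser line's responses across partner genotypes.
#' The primary definition (`measure = "sd"`) is the sample SD among the
#' line's per-partner cell means; alternatives from the mate-choice
#' literature are the coefficient of variation (`"cv"` = sd/mean), its
#' square (`"cv2"`), and two preference-strength contrasts: the difference
#' between the maximum cell mean and the grand mean divided by the SD of
#' all of the line's trial values (`"strength_total_sd"`) or by the trial
#' SD within the maximum cell (`"strength_max_sd"`). The strength measures
#' need trial-level spread, so `trials` must be supplied for them.
#'
#' @inheritParams responsiveness
#' @param measure One of `"sd"`, `"cv"`, `"cv2"`, `"strength_total_sd"`,
#'   `"strength_max_sd"`.
#' @param trials Trial table; required for the strength measures.
#' @param mated_only,log Passed through to the trial-level values for the
#'   strength measures; must match how `cells` was computed.
#' @return Tibble with `chooser_line`, `channel`, `measure`, `choosiness`.
#' @examples
#' trials <- simulate_trials(line_effects(4, 4, seed = 1), seed = 2)
#' cells <- cell_means(trials, "copulation_latency")
#' choosiness(cells)
#' choosiness(cells, "cv")
#' @export
choosiness <- function(cells, measure = c("sd", "cv", "cv2",
                                          "strength_total_sd",
                                          "strength_max_sd"),
                       trials = NULL, mated_only = TRUE, log = FALSE) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(cells))
  counts <- table(cells$chooser_line)
  if (any(counts < 2L)) {
    abort(sprintf("choosiness needs >= 2 cells per chooser line (got %d for %s).",
                  min(counts), names(counts)[which.min(counts)]))
  }
  channel <- cells$channel[1L]

  base <- cells |>
    dplyr::group_by(.data$chooser_line, .data$channel) |>
    dplyr::summarise(sd_means = sd(.data$mean), grand = mean(.data$mean),
                     max_mean = max(.data$mean),
                     max_partner = .data$partner_line[which.max(.data$mean)],
                     .groups = "drop")

  if (measure %in% c("cv", "cv2") && any(base$grand == 0)) {
    abort("zero mean response: coefficient of variation undefined.")
  }

  if (measure %in% c("strength_total_sd", "strength_max_sd")) {
    if (is.null(trials)) {
      abort(sprintf("`trials` must be supplied for measure '%s'.", measure))
    }
    roles <- channel_roles(channel)
    keep <- switch(channel,
      copulation_latency = if (mated_only) trials$mated else trials$courted,
      courtship_latency = trials$courted,
      copulation_duration = trials$mated
    )
    dat <- trials[keep & !is.na(trials[[channel]]), ]
    vals <- dat[[channel]]
    if (log) vals <- base::log(vals)
    tl <- tibble::tibble(chooser_line = dat[[roles$chooser]],
                         partner_line = dat[[roles$partner]], value = vals)
    spread <- purrr::map_dbl(seq_len(nrow(base)), function(i) {
      line_vals <- tl[tl$chooser_line == base$chooser_line[i], ]
      if (measure == "strength_total_sd") {
        sd(line_vals$value)
      } else {
        sd(line_vals$value[line_vals$partner_line == base$max_partner[i]])
      }
    })
    if (any(is.na(spread) | spread == 0)) {
      abort("zero or undefined trial SD: preference-strength measure undefined.")
    }
    base$choosiness <- (base$max_mean - base$grand) / spread
  } else {
    base$choosiness <- switch(measure,
      sd = base$sd_means,
      cv = base$sd_means / base$grand,
      cv2 = (base$sd_means / base$grand)^2
    )
  }
  base |>
    dplyr::mutate(measure = measure) |>
    dplyr::select("chooser_line", "channel", "measure", "choosiness")
}

#' Line-level global attractiveness
#'
#' A partner line's global attractiveness is the unweighted mean of its
#' cell means across all chooser lines. For latency channels lower values
#' mean more attractive (less time to elicit a response), so the inverse
#' (1/mean, in 1/seconds) is also returned for display: larger inverse
#' values correspond to more attractive lines.
#'
#' @inheritParams responsiveness
#' @return Tibble with `partner_line`, `channel`, `attractiveness` (mean
#'   response, seconds), `inverse_attractiveness` (1/seconds).
#' @export
global_attractiveness <- function(cells) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1L)
  out <- cells |>
    dplyr::group_by(.data$partner_line, .data$channel) |>
    dplyr::summarise(attractiveness = mean(.data$mean), .groups = "drop")
  if (any(out$attractiveness == 0)) {
    abort("zero mean response: inverse attractiveness undefined.")
  }
  out$inverse_attractiveness <- 1 / out$attractiveness
  out
}

#' All line components for one channel
#'
#' Convenience wrapper computing responsiveness, every choosiness measure,
#' and global attractiveness from a trial table in one call.
#'
#' @inheritParams cell_means
#' @param measures Choosiness measures to include.
#' @return A list with tibbles `cells`, `chooser` (responsiveness joined
#'   with one column per choosiness measure) and `partner` (global
#'   attractiveness).
#' @export
line_components <- function(trials, channel = "copulation_latency",
                            measures = c("sd", "cv", "cv2"),
                            mated_only = TRUE, log = FALSE) {
  cells <- cell_means(trials, channel, mated_only = mated_only, log = log)
  chooser <- responsiveness(cells)
  for (m in measures) {
    ch <- choosiness(cells, m, trials = trials, mated_only = mated_only,
                     log = log)
    chooser[[paste0("choosiness_", m)]] <- ch$choosiness[
      match(chooser$chooser_line, ch$chooser_line)]
  }
  list(cells = cells, chooser = chooser,
       partner = global_attractiveness(cells))
}
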