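#' Write a trial table to CSV
#'
#' Long-format CSV, one row per no-choice trial, with a fixed column order
#' and empty fields for undefined values (courtship latency of non-courting
#' pairs, copulation duration of non-mating pairs).
#'
#' @param trials Trial table (see [simulate_trials()]).
#' @param path Output file path.
#' @return `trials`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`trials` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(trials[, trial_columns()], path, na = "")
  invisible(trials)
}

#' Read and validate a trial table from CSV
#'
#' Reads a long-format trial CSV (columns as written by [write_trials()])
#' and validates every row against the design invariants: latencies must be
#' positive, copulation latency cannot exceed the recording limit, a mated
#' pair must have courted and must carry a copulation duration, a censored
#' pair (courted but not mated) must carry copulation latency equal to
#' `censor_time`, and non-courting pairs carry no downstream fields.
#' Invalid files are rejected with an error naming each offending row;
#' nothing is silently coerced.
#'
#' @param path CSV file path.
#' @param censor_time Recording limit in seconds used to validate censored
#'   rows (default 3600).
#' @return A validated tibble of trials with the `censor_time` attribute
#'   set.
#' @export
read_trials <- function(path, censor_time = 3600) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  trials <- readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      male_line = readr::col_character(),
      female_line = readr::col_character(),
      male_age = readr::col_integer(),
      female_age = readr::col_integer(),
      array_id = readr::col_character(),
      chamber = readr::col_integer(),
      courted = readr::col_logical(),
      courtship_latency = readr::col_double(),
      mated = readr::col_logical(),
      copulation_latency = readr::col_double(),
      copulation_duration = readr::col_double()
    ))
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols) > 0L) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  problems <- readr::problems(trials)
  if (nrow(problems) > 0L) {
    abort(sprintf("unparseable value(s) at row(s): %s",
                  paste(unique(problems$row), collapse = ", ")))
  }
  issues <- validate_trials(trials, censor_time)
  if (length(issues) > 0L) {
    abort(paste(c("invalid trial table:", issues), collapse = "\n  "))
  }
  attr(trials, "censor_time") <- censor_time
  trials
}

# returns a character vector of row-level violations, empty when valid
validate_trials <- function(trials, censor_time) {
  issues <- character()
  flag <- function(bad, msg) {
    rows <- which(bad)
    if (length(rows) > 0L) {
      issues <<- c(issues, sprintf("row(s) %s: %s",
                                   paste(head(rows, 10L), collapse = ", "), msg))
    }
  }
  flag(is.na(trials$courted) | is.na(trials$mated),
       "courted/mated flags must be present")
  flag(trials$mated & !trials$courted, "mated implies courted")
  flag(trials$courted & (is.na(trials$courtship_latency) |
                           trials$courtship_latency <= 0),
       "courted pairs need a positive courtship_latency")
  flag(!trials$courted & !is.na(trials$courtship_latency),
       "non-courting pairs must have empty courtship_latency")
  flag(trials$courted & (is.na(trials$copulation_latency) |
                           trials$copulation_latency <= 0 |
                           trials$copulation_latency > censor_time),
       sprintf("courted pairs need copulation_latency in (0, %g]", censor_time))
  flag(trials$courted & !trials$mated & !is.na(trials$copulation_latency) &
         trials$copulation_latency != censor_time,
       sprintf("censored pairs must record copulation_latency = %g", censor_time))
  flag(trials$mated & (is.na(trials$copulation_duration) |
                         trials$copulation_duration <= 0),
       "mated pairs need a positive copulation_duration")
  flag(!trials$mated & !is.na(trials$copulation_duration),
       "copulation_duration is defined only for mated pairs")
  issues
}

#' Serialize line effects to and from JSON
#'
#' @param effects A [line_effects()] object.
#' @param path JSON file path.
#' @return `write_effects()` returns `effects` invisibly; `read_effects()`
#'   returns a `line_effects` object.
#' @export
write_effects <- function(effects, path) {
  stopifnot(inherits(effects, "line_effects"))
  jsonlite::write_json(
    list(model = effects$model, males = effects$males,
         females = effects$females),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(effects)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(males = tibble::as_tibble(x$males),
                 females = tibble::as_tibble(x$females),
                 model = x$model),
            class = "line_effects")
}
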