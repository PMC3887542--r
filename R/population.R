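#' Sample a population of female preference functions
#'
#' Draws per-female preference parameters from the population distributions
#' used in the preference-function simulations. For the open-ended model the
#' steepness `y` is Normal(`y_mean`, `y_sd`) (defaults 2 and 0.3); for the
#' unimodal model the peak `y` is Normal(`y_mean`, `y_sd`) (defaults 10.5
#' and 2) and the width `nu` is Normal(`nu_mean`, `nu_sd`) (defaults 15 and
#' 0; set `nu_sd = 7` for variable widths). Sampled widths must be positive:
#' non-positive draws are rejected and redrawn, and the number of rejections
#' is recorded in the `"nu_rejections"` attribute.
#'
#' @param n_females Number of females (>= 1).
#' @param model `"open_ended"` or `"unimodal"`.
#' @param y_mean,y_sd Mean and SD of the steepness (open-ended) or peak
#'   (unimodal) distribution. Defaults depend on `model`.
#' @param nu_mean,nu_sd Mean and SD of the width distribution (unimodal
#'   only). `nu_sd = 0` fixes the width at `nu_mean`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   population.
#' @return A tibble with one row per female: `female_id`, `model`, `y`,
#'   `nu` (`NA` for open-ended).
#' @examples
#' sample_females(10, model = "unimodal", seed = 1)
#' @export
sample_females <- function(n_females = 10,
                           model = c("unimodal", "open_ended"),
                           y_mean = NULL, y_sd = NULL,
                           nu_mean = 15, nu_sd = 0,
                           seed = NULL) {
  model <- match.arg(model)
  n_females <- check_scalar_int(n_females, "n_females", min = 1L)
  defaults <- switch(model,
    open_ended = c(y_mean = 2, y_sd = 0.3),
    unimodal = c(y_mean = 10.5, y_sd = 2)
  )
  y_mean <- y_mean %||% defaults[["y_mean"]]
  y_sd <- y_sd %||% defaults[["y_sd"]]
  check_number(y_mean, "y_mean"); check_number(y_sd, "y_sd")
  if (y_sd < 0) abort("`y_sd` must be >= 0.")
  if (model == "unimodal") {
    check_positive(nu_mean, "nu_mean")
    if (nu_sd < 0) abort("`nu_sd` must be >= 0.")
  }
  maybe_set_seed(seed)

  y <- rnorm(n_females, y_mean, y_sd)
  rejections <- 0L
  if (model == "unimodal") {
    nu <- rnorm(n_females, nu_mean, nu_sd)
    # widths must be positive; rejection-resample bad draws
    while (any(bad <- nu <= 0)) {
      rejections <- rejections + sum(bad)
      nu[bad] <- rnorm(sum(bad), nu_mean, nu_sd)
    }
  } else {
    nu <- NA_real_
  }

  out <- tibble::tibble(
    female_id = sprintf("F%03d", seq_len(n_females)),
    model = model,
    y = y,
    nu = nu
  )
  attr(out, "nu_rejections") <- rejections
  out
}

#' Per-female mating-response matrix over a male trait grid
#'
#' Evaluates every female's preference function on a grid of male trait
#' values and normalizes each female's responses so they are interpretable
#' as choice probabilities (`scale = "sum"`, rows sum to 1) or as relative
#' responses with maximum 1 (`scale = "max"`). Normalization does not change
#' any female's ranking of males.
#'
#' @param females Tibble from [sample_females()] (columns `female_id`,
#'   `model`, `y`, `nu`).
#' @param traits Numeric vector of at least two male trait values, e.g.
#'   [trait_grid()].
#' @param scale `"sum"` (each female's row sums to 1) or `"max"` (each
#'   female's maximum response is 1).
#' @return A tibble of class `"pref_response"` in long format:
#'   `female_id`, `male_id`, `trait`, `response`, and `log_response` (the
#'   female's log relative response shifted so her best male is at 0).
#'   Responses are exponentiated after subtracting each female's maximum
#'   log response, so narrow preference functions cannot underflow into
#'   spurious ties; `log_response` carries the exact ordering even when
#'   `response` underflows for far-off males.
#' @examples
#' pop <- sample_females(5, "open_ended", seed = 1)
#' response_matrix(pop, trait_grid(10))
#' @export
response_matrix <- function(females, traits, scale = c("sum", "max")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(females), nrow(females) >= 1L)
  if (!all(c("female_id", "model", "y") %in% names(females))) {
    abort("`females` must have columns female_id, model, y (see sample_females()).")
  }
  if (!is.numeric(traits) || length(traits) < 2L || anyNA(traits)) {
    abort("`traits` must be a numeric vector with at least two male trait values.")
  }
  male_id <- sprintf("M%03d", seq_along(traits))

  out <- purrr::pmap_dfr(
    list(females$female_id, females$model, females$y,
         females$nu %||% rep(NA_real_, nrow(females))),
    function(fid, model, y, nu) {
      lr <- log_response(model, y, nu, traits)
      lr <- lr - max(lr)
      resp <- exp(lr)
      resp <- switch(scale, sum = resp / sum(resp), max = resp)
      tibble::tibble(female_id = fid, male_id = male_id,
                     trait = traits, response = resp, log_response = lr)
    }
  )
  class(out) <- c("pref_response", class(out))
  attr(out, "scale") <- scale
  out
}

#' Population-level preference function
#'
#' Averages the per-female response matrix over females, giving the
#' population-level preference for each male.
#'
#' @param resp A `"pref_response"` tibble from [response_matrix()].
#' @return Tibble with `male_id`, `trait`, `preference` (mean response).
#' @export
population_preference <- function(resp) {
  stopifnot(is.data.frame(resp), nrow(resp) > 0L)
  resp |>
    dplyr::group_by(.data$male_id, .data$trait) |>
    dplyr::summarise(preference = mean(.data$response), .groups = "drop") |>
    dplyr::arrange(.data$male_id)
}

#' Attractiveness ranks of males
#'
#' Ranks males by their average attractiveness to the female population
#' (the population-level preference), with greater ranks more attractive
#' (rank 1 = least attractive). Ties receive average ranks.
#'
#' @inheritParams population_preference
#' @return Tibble with `male_id`, `trait`, `preference`, `attract_rank`.
#' @export
rank_males <- function(resp) {
  pop <- population_preference(resp)
  pop$attract_rank <- rank_avg(pop$preference)
  pop
}

#' Per-female preferences indexed by attractiveness rank
#'
#' Reorders each female's responses by the males' population attractiveness
#' ranks, i.e. each female's preference function for overall male
#' attractiveness rather than for the underlying trait. When peak
#' preferences vary among females, different females show different
#' rank-order preferences here even though the population-level function is
#' monotone by construction.
#'
#' @inheritParams population_preference
#' @return A tibble of class `"pref_ranked"`: `female_id`, `male_id`,
#'   `trait`, `attract_rank`, `response`, ordered by female then rank.
#' @export
preference_by_rank <- function(resp) {
  ranks <- rank_males(resp)[, c("male_id", "attract_rank")]
  out <- resp |>
    dplyr::inner_join(ranks, by = "male_id") |>
    dplyr::arrange(.data$female_id, .data$attract_rank) |>
    dplyr::select("female_id", "male_id", "trait", "attract_rank", "response")
  class(out) <- c("pref_ranked", class(out))
  out
}
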