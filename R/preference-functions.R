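#' Open-ended preference function
#'
#' Relative mating response of a chooser with an open-ended (monotone)
#' preference toward a prospective mate, proportional to `exp(y * ln t)`,
#' i.e. `t^y`, where `t` is the mate's trait value and `y` the chooser's
#' preference steepness. Positive `y` means larger trait values are always
#' preferred; all choosers with `y > 0` rank mates identically.
#'
#' @param trait Positive numeric vector of mate trait values (arbitrary
#'   trait units).
#' @param steepness Single finite number, the preference steepness `y`.
#' @return Numeric vector of unnormalized relative responses, `trait^steepness`.
#' @examples
#' pref_open_ended(c(1, 3), steepness = 2)
#' @seealso [pref_unimodal()], [response_matrix()]
#' @export
pref_open_ended <- function(trait, steepness) {
  check_positive(trait, "trait")
  check_number(steepness, "steepness")
  if (length(steepness) != 1L) abort("`steepness` must be a single value.")
  exp(steepness * log(trait))
}

#' Unimodal (Gaussian) preference function
#'
#' Relative mating response under a unimodal preference,
#' `exp(-(t - y)^2 / (2 * nu^2))`: maximal (1) when the mate's trait `t`
#' equals the chooser's peak preference `y`, falling off symmetrically with
#' width `nu`.
#'
#' @param trait Numeric vector of mate trait values.
#' @param peak Single finite number, the chooser's peak preference (trait
#'   units).
#' @param width Single positive number `nu`, the preference-function width
#'   (trait units).
#' @return Numeric vector of responses in `(0, 1]`.
#' @examples
#' pref_unimodal(10.5, peak = 10.5, width = 15)       # 1 at the peak
#' pref_unimodal(10.5 + 15, peak = 10.5, width = 15)  # exp(-1/2)
#' @export
pref_unimodal <- function(trait, peak, width) {
  check_number(trait, "trait")
  check_number(peak, "peak")
  if (length(peak) != 1L) abort("`peak` must be a single value.")
  if (length(width) != 1L || !is.numeric(width) || is.na(width) || width <= 0) {
    abort("`width` must be a single positive number.")
  }
  exp(-(trait - peak)^2 / (2 * width^2))
}

#' Evenly spaced male trait grid
#'
#' Default grid of male trait values used by the preference-function
#' simulations: `n` evenly spaced values spanning the unimodal peak
#' distribution's mean plus/minus three SDs (4.5 to 16.5 under the default
#' peak ~ Normal(10.5, 2)).
#'
#' @param n Number of males (>= 2).
#' @param lower,upper Grid endpoints (trait units).
#' @return Numeric vector of length `n`.
#' @export
trait_grid <- function(n = 10, lower = 4.5, upper = 16.5) {
  n <- check_scalar_int(n, "n", min = 2L)
  if (upper <= lower) abort("`upper` must exceed `lower`.")
  seq(lower, upper, length.out = n)
}

# log relative response of one chooser to a trait vector; the open-ended
# model consumes ln(trait), the unimodal model the raw trait
log_response <- function(model, y, nu, trait) {
  switch(model,
    open_ended = {
      check_positive(trait, "trait")
      y * log(trait)
    },
    unimodal = -(trait - y)^2 / (2 * nu^2),
    abort(sprintf("unknown preference model '%s'", model))
  )
}
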