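#' Line-level genetic effects for the trial generator
#'
#' Realizes the latent quantities the factorial no-choice design measures:
#' each isogenic line contributes a male side (a display trait value plus
#' log-scale propensity offsets for the male-controlled channels, courtship
#' latency and copulation duration) and a female side (a preference
#' function, a responsiveness offset, a discrimination scale, and
#' attractiveness-to-males offsets for the male-controlled channels).
#'
#' Male traits default to an evenly spaced grid over the trait range (see
#' [trait_grid()]); female preference parameters are drawn as in
#' [sample_females()]. The discrimination scale `gamma` (log-seconds per
#' stimulus SD) controls how strongly a female line's copulation latency
#' tracks its preference for a male, and is the generator's handle on true
#' choosiness. Setting `attract_choosiness_cor` to a nonzero value draws
#' each shared genotype's `gamma` correlated with its standardized male
#' trait, inducing a line-level genetic correlation between male
#' attractiveness and female choosiness (use with `model = "open_ended"`,
#' under which attractiveness is monotone in the trait).
#'
#' @param n_male_lines,n_female_lines Numbers of isogenic lines per sex
#'   (default 10 each). When equal, lines are treated as shared genotypes
#'   `L01..Lnn` on both sides.
#' @param model Preference-function class for the female lines.
#' @param traits Optional male trait values (length `n_male_lines`);
#'   default [trait_grid()].
#' @param y_mean,y_sd,nu_mean,nu_sd Preference-population parameters passed
#'   to [sample_females()].
#' @param responsiveness_sd SD (log-seconds) of female-line responsiveness
#'   offsets on copulation latency.
#' @param stimulus_scale Mean discrimination scale `gamma` (log-seconds per
#'   stimulus SD).
#' @param choosiness_sd SD of `gamma` across female lines.
#' @param attract_choosiness_cor Correlation in `[-1, 1]` between a shared
#'   genotype's standardized male trait and its `gamma`.
#' @param courtship_propensity_sd,duration_propensity_sd SDs (log-seconds)
#'   of male-line offsets on courtship latency and copulation duration.
#' @param courtship_attract_sd,duration_attract_sd SDs (log-seconds) of
#'   female-line attractiveness-to-males offsets on the same channels.
#' @param seed Optional integer seed.
#' @return A list of class `"line_effects"` with tibbles `males` (`line`,
#'   `trait`, `courtship_propensity`, `duration_propensity`) and `females`
#'   (`line`, `model`, `y`, `nu`, `responsiveness_offset`, `gamma`,
#'   `courtship_attract`, `duration_attract`).
#' @examples
#' line_effects(seed = 1)
#' @seealso [simulate_trials()], [expected_cell_means()]
#' @export
line_effects <- function(n_male_lines = 10, n_female_lines = 10,
                         model = c("unimodal", "open_ended"),
                         traits = NULL,
                         y_mean = NULL, y_sd = NULL,
                         nu_mean = 15, nu_sd = 0,
                         responsiveness_sd = 0.4,
                         stimulus_scale = 0.6,
                         choosiness_sd = 0,
                         attract_choosiness_cor = 0,
                         courtship_propensity_sd = 0.35,
                         courtship_attract_sd = 0.25,
                         duration_propensity_sd = 0.15,
                         duration_attract_sd = 0.1,
                         seed = NULL) {
  model <- match.arg(model)
  n_male_lines <- check_scalar_int(n_male_lines, "n_male_lines", min = 2L)
  n_female_lines <- check_scalar_int(n_female_lines, "n_female_lines", min = 2L)
  if (abs(attract_choosiness_cor) > 1) {
    abort("`attract_choosiness_cor` must be in [-1, 1].")
  }
  if (attract_choosiness_cor != 0 && n_male_lines != n_female_lines) {
    abort("`attract_choosiness_cor` requires shared genotypes (equal line counts).")
  }
  maybe_set_seed(seed)

  traits <- traits %||% trait_grid(n_male_lines)
  if (length(traits) != n_male_lines) {
    abort("`traits` must have one value per male line.")
  }
  check_positive(traits, "traits")

  males <- tibble::tibble(
    line = line_labels(n_male_lines),
    trait = traits,
    courtship_propensity = rnorm(n_male_lines, 0, courtship_propensity_sd),
    duration_propensity = rnorm(n_male_lines, 0, duration_propensity_sd)
  )

  fem <- sample_females(n_female_lines, model = model,
                        y_mean = y_mean, y_sd = y_sd,
                        nu_mean = nu_mean, nu_sd = nu_sd)

  if (attract_choosiness_cor != 0 && choosiness_sd > 0) {
    # gamma correlated with the shared genotype's standardized male trait
    z_t <- as.numeric(scale(males$trait))
    eps <- rnorm(n_female_lines)
    z_g <- attract_choosiness_cor * z_t +
      sqrt(1 - attract_choosiness_cor^2) * eps
    gamma <- stimulus_scale + choosiness_sd * z_g
  } else {
    gamma <- rnorm(n_female_lines, stimulus_scale, choosiness_sd)
  }

  females <- tibble::tibble(
    line = line_labels(n_female_lines),
    model = fem$model,
    y = fem$y,
    nu = fem$nu,
    responsiveness_offset = rnorm(n_female_lines, 0, responsiveness_sd),
    gamma = gamma,
    courtship_attract = rnorm(n_female_lines, 0, courtship_attract_sd),
    duration_attract = rnorm(n_female_lines, 0, duration_attract_sd)
  )

  structure(list(males = males, females = females, model = model),
            class = "line_effects")
}

#' @export
print.line_effects <- function(x, ...) {
  cat(sprintf("<line_effects> %d male x %d female lines (%s preferences)\n",
              nrow(x$males), nrow(x$females), x$model))
  cat("$males\n"); print(x$males, n = 5)
  cat("$females\n"); print(x$females, n = 5)
  invisible(x)
}

# stimulus matrix s[f, m]: each female line's log preference for each male
# line, z-scored across male lines (0 for a flat preference profile)
stimulus_matrix <- function(effects) {
  stopifnot(inherits(effects, "line_effects"))
  t_m <- effects$males$trait
  s <- t(vapply(seq_len(nrow(effects$females)), function(i) {
    f <- effects$females[i, ]
    lr <- log_response(f$model, f$y, f$nu, t_m)
    sdev <- sd(lr)
    if (length(lr) < 2L || sdev == 0) rep(0, length(lr)) else (lr - mean(lr)) / sdev
  }, numeric(length(t_m))))
  dimnames(s) <- list(effects$females$line, effects$males$line)
  s
}
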