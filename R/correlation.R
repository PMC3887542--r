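#' Line-level genetic correlation between attractiveness and choosiness
#'
#' With isogenic lines, each shared genotype contributes both a male-side
#' global attractiveness and a female-side choosiness, and the among-line
#' regression of one on the other estimates their genetic correlation.
#' Choosiness (the SD in female copulation latency across male genotypes)
#' is regressed on male global attractiveness by ordinary least squares.
#' Because lower latency means more attractive, the attractiveness axis is
#' inverse mean copulation latency by default (`transform = "inverse"`),
#' so a positive slope reads "genotypes with attractive males have choosy
#' females".
#'
#' @param choosiness Tibble with columns `line` and `choosiness` (e.g.
#'   from [choosiness()], renamed), one row per genotype.
#' @param attractiveness Tibble with columns `line` and `attractiveness`
#'   (mean copulation latency in seconds, e.g. from
#'   [global_attractiveness()]), same genotypes.
#' @param transform `"inverse"` (default; regress on 1/attractiveness) or
#'   `"identity"`.
#' @return An object of class `"genetic_correlation"`: a list with
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n_lines`, the joined
#'   `data`, and the underlying `lm` fit. `tidy()`/`glance()` return
#'   tibbles; `autoplot()` draws the regression.
#' @examples
#' ch <- tibble::tibble(line = letters[1:5], choosiness = c(1, 2, 3, 4, 5))
#' at <- tibble::tibble(line = letters[1:5], attractiveness = 1 / (1:5))
#' glance(genetic_correlation(ch, at))
#' @export
genetic_correlation <- function(choosiness, attractiveness,
                                transform = c("inverse", "identity")) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(choosiness), is.data.frame(attractiveness))
  if (!all(c("line", "choosiness") %in% names(choosiness))) {
    abort("`choosiness` must have columns `line` and `choosiness`.")
  }
  if (!all(c("line", "attractiveness") %in% names(attractiveness))) {
    abort("`attractiveness` must have columns `line` and `attractiveness`.")
  }
  if (!setequal(choosiness$line, attractiveness$line) ||
      anyDuplicated(choosiness$line) || anyDuplicated(attractiveness$line)) {
    abort("mismatched line sets: both tables must cover the same genotypes once.")
  }
  dat <- dplyr::inner_join(choosiness[, c("line", "choosiness")],
                           attractiveness[, c("line", "attractiveness")],
                           by = "line")
  if (nrow(dat) < 3L) abort("need at least 3 lines for the regression.")
  dat$x <- switch(transform,
    inverse = {
      if (any(dat$attractiveness == 0)) abort("zero attractiveness: inverse undefined.")
      1 / dat$attractiveness
    },
    identity = dat$attractiveness
  )
  fit <- lm(choosiness ~ x, data = dat)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2L, 4L],
    n_lines = nrow(dat),
    transform = transform,
    data = tibble::as_tibble(dat),
    fit = fit
  ), class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf(
    "Genetic correlation (n = %d lines): slope = %.4g, r^2 = %.3f, p = %.4g\n",
    x$n_lines, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' @rdname genetic_correlation
#' @param x,object A `genetic_correlation` object.
#' @param ... Unused.
#' @export
tidy.genetic_correlation <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 p.value = c(NA_real_, x$p_value))
}

#' @rdname genetic_correlation
#' @export
glance.genetic_correlation <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p.value = x$p_value,
                 n_lines = x$n_lines)
}
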