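# internal validation helpers

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", name))
  }
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite.", name))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name)
  if (any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

check_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# set the RNG state for one simulation call; NULL leaves the global stream alone
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    check_scalar_int(seed, "seed", min = 0L)
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

line_labels <- function(n, prefix = "L") sprintf("%s%02d", prefix, seq_len(n))

# ranks with average ties; larger value -> larger rank
rank_avg <- function(x) rank(x, ties.method = "average")
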