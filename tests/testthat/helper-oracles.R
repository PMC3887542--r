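# Independent brute-force oracles used to cross-check the package's
# statistics. Deliberately written from first principles (explicit loops,
# definitional formulas) rather than reusing package internals.

# Kendall's W via the average pairwise Spearman correlation:
# W = ((m - 1) * mean(rho) + 1) / m  (valid without ties)
bf_kendall_w_spearman <- function(scores) {
  m <- nrow(scores)
  rhos <- c()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      rhos <- c(rhos, suppressWarnings(
        cor(scores[i, ], scores[j, ], method = "spearman")))
    }
  }
  ((m - 1) * mean(rhos) + 1) / m
}

# Kendall's W from the definitional formula 12 S / (m^2 (n^3 - n)), no ties
bf_kendall_w_def <- function(ranks) {
  m <- nrow(ranks); n <- ncol(ranks)
  rank_sums <- colSums(ranks)
  s <- sum((rank_sums - mean(rank_sums))^2)
  12 * s / (m^2 * (n^3 - n))
}

bf_sample_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - sum(x) / n)^2) / (n - 1))
}

# per-line component statistics computed by explicit looping over a trial
# data frame (chooser, partner, value)
bf_components <- function(tl) {
  lines <- sort(unique(tl$chooser))
  out <- list()
  for (ln in lines) {
    sub <- tl[tl$chooser == ln, ]
    partners <- sort(unique(sub$partner))
    means <- sapply(partners, function(p) mean(sub$value[sub$partner == p]))
    grand <- sum(means) / length(means)
    sdm <- bf_sample_sd(means)
    max_idx <- which.max(means)
    max_cell_vals <- sub$value[sub$partner == partners[max_idx]]
    out[[ln]] <- list(
      responsiveness = grand,
      sd = sdm,
      cv = sdm / grand,
      cv2 = (sdm / grand)^2,
      strength_total_sd = (means[max_idx] - grand) / bf_sample_sd(sub$value),
      strength_max_sd = (means[max_idx] - grand) / bf_sample_sd(max_cell_vals)
    )
  }
  out
}

# random small factorial trial-level fixture: n_ch x n_pa cells, each with
# its own trial count; values positive and continuous (no ties)
random_trial_values <- function(seed, n_ch = 4, n_pa = 4, max_per_cell = 5) {
  set.seed(seed)
  grid <- expand.grid(chooser = paste0("C", seq_len(n_ch)),
                      partner = paste0("P", seq_len(n_pa)),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    k <- sample(2:max_per_cell, 1)
    data.frame(chooser = grid$chooser[i], partner = grid$partner[i],
               value = exp(rnorm(k, 5, 1)))
  }))
}

# wrap trial-level values as a minimal trial table on the female-chooser
# channel (all courted and mated, far from the censor limit)
as_copulation_trials <- function(tl) {
  tibble::tibble(
    male_line = tl$partner,
    female_line = tl$chooser,
    male_age = 4L, female_age = 4L,
    array_id = "A001", chamber = 1L,
    courted = TRUE,
    courtship_latency = 60,
    mated = TRUE,
    copulation_latency = tl$value,
    copulation_duration = 900
  )
}
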