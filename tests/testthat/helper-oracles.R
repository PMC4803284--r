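# Independent textbook oracles and fixture builders used across the suite.

# Tie-corrected Kruskal-Wallis H, straight from the rank-sum definition.
kw_oracle <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Friedman chi-square from within-block rank sums (tie-free designs).
friedman_oracle <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  r <- t(apply(y, 1, rank))
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

# Random on-grid parameters for any model (independent of sample_params).
random_params <- function(model, seed) {
  set.seed(seed)
  excl <- chordexpect::excluded_cells(model)
  grid <- seq(0, 1, by = 0.1)
  if (model %in% c("1P", "1M")) {
    T <- rep(NA_real_, 12)
  } else {
    T <- matrix(NA_real_, 12, 12)
  }
  T[!excl] <- sample(grid, sum(!excl), replace = TRUE)
  kappa <- if (model %in% c("BU", "BS")) sample(1:12, 1) / 12 else NA_real_
  theta <- if (model == "BS") sample(0:20, 1) * 0.05 else 0
  chordexpect::model_params(model, T, kappa = kappa, theta = theta)
}

# A small repetition-free sequence fixture covering all lengths.
fixture_sequences <- function() {
  list(c(0L, 7L), c(3L, 10L), c(11L, 0L),
       c(0L, 2L, 9L), c(5L, 4L, 11L),
       c(0L, 2L, 7L, 5L), c(8L, 3L, 1L, 6L))
}

# Balanced multi-participant 2-chord dataset with a chosen rating rule.
two_chord_dataset <- function(participants, rating_fn) {
  seqs <- chordexpect::stimulus_set(2L)
  out <- NULL
  for (p in seq_len(participants)) {
    r <- vapply(seqs, rating_fn, 1.0, p)
    d <- chordexpect::dor_dataset(rep(sprintf("p%d", p), length(seqs)),
                                  seqs, r)
    out <- if (is.null(out)) d else rbind(out, d)
  }
  class(out) <- c("dor_dataset", "data.frame")
  out
}
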