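test_that("participant averaging is a per-pattern arithmetic mean", {
  d <- dor_dataset(c("p1", "p2", "p1"),
                   list(c(0L, 7L), c(0L, 7L), c(2L, 5L)), c(8, 6, 4))
  tab <- average_dors(d, 2)
  expect_equal(tab$mean[tab$c1 == 0 & tab$c2 == 7], 7.0)
  expect_equal(tab$mean[tab$c1 == 2 & tab$c2 == 5], 4.0)

  full <- two_chord_dataset(1, function(s, p) 1 + (sum(s) %% 9))
  tab <- average_dors(full, 2)
  expect_identical(nrow(tab), 144L)
  expect_true(all(tab$mean >= 1 & tab$mean <= 9))
})

test_that("Kruskal-Wallis matches the textbook tie-corrected H", {
  for (seed in 1:20) {
    set.seed(seed)
    vals <- round(runif(144, 1, 9), 2)
    full <- two_chord_dataset(1, function(s, p) 5)
    tab <- average_dors(full, 2)
    tab$mean <- vals
    for (f in c("interval", "first_pitch", "second_pitch")) {
      g <- switch(f, interval = chord_interval(tab$c1, tab$c2),
                  first_pitch = tab$c1, second_pitch = tab$c2)
      expect_equal(kruskal_wallis_by_factor(tab, f)$statistic,
                   kw_oracle(vals, g), tolerance = 1e-9)
    }
    expect_identical(kruskal_wallis_by_factor(tab, "interval")$df, 11L)
  }
})

test_that("equal group mean-ranks give H = 0", {
  full <- two_chord_dataset(1, function(s, p) 5)
  tab <- average_dors(full, 2)
  g <- chord_interval(tab$c1, tab$c2)
  vals <- numeric(144)
  for (i in 0:11) {  # pair rank r with 25 - r so every group mean-rank ties
    vals[g == i] <- c(sapply(0:5, function(k) c(i + 1 + 24 * k, 24 - i + 24 * k)))
  }
  tab$mean <- vals
  expect_equal(kruskal_wallis_by_factor(tab, "interval")$statistic, 0)
})

test_that("Friedman tests match the rank-sum oracle on complete grids", {
  base <- dor_dataset("p", stimulus_set(3, seed = 2), rep(5, 144))
  for (seed in 1:20) {
    set.seed(seed)
    tab <- average_dors(base, 3)
    tab$mean <- runif(144, 1, 9)
    m <- matrix(NA_real_, 12, 12)
    m[cbind(tab$i1 + 1, tab$i2 + 1)] <- tab$mean
    r <- friedman_by_interval(tab, "interval_from_second")
    expect_equal(r$statistic, friedman_oracle(m), tolerance = 1e-9)
    expect_identical(r$df, 11L)
    y <- matrix(NA_real_, 12, 12)
    for (a in 0:11) for (b in 0:11) y[b + 1, (a + b) %% 12 + 1] <- m[a + 1, b + 1]
    expect_equal(friedman_by_interval(tab, "interval_from_first")$statistic,
                 friedman_oracle(y), tolerance = 1e-9)
  }
  tab <- average_dors(base, 3)  # constant: tie-degenerate
  expect_error(friedman_by_interval(tab, "interval_from_second"),
               "tie-degenerate")
})

test_that("interval profiles average the shared intervals per position", {
  params <- random_params("1M", seed = 4)
  seqs <- c(stimulus_set(2), stimulus_set(3, seed = 1), stimulus_set(4, seed = 2))
  d <- dor_dataset(rep("p", length(seqs)), seqs, rep(5, length(seqs)))
  prof <- interval_profile_vectors(d)
  expect_identical(rownames(prof),
                   c("C1-C2", "C1-C3", "C2-C3", "C1-C4", "C2-C4", "C3-C4"))
  expect_true(all(prof == 5))

  # deterministic rating rule checked by direct group-by
  rate <- function(s) 1 + (chord_interval(s[length(s) - 1], s[length(s)]) %% 8)
  d$rating <- vapply(seqs, rate, 1.0)
  prof <- interval_profile_vectors(d)
  shared <- c(2, 5, 7, 10)
  d3 <- d[d$condition == 3, ]
  for (k in seq_along(shared)) {
    sel <- chord_interval(d3$c1, d3$c3) == shared[k]
    expect_equal(prof["C1-C3", k], mean(d3$rating[sel]))
  }
  expect_equal(unname(prof["C2-C3", ]), 1 + shared %% 8)
})

test_that("non-metric MDS recovers embeddable configurations", {
  D3 <- matrix(1, 3, 3) - diag(3)
  fit <- nonmetric_mds(D3, dims = 2, nstarts = 10)
  expect_lt(fit$stress, 1e-6)

  set.seed(8)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  fit2 <- nonmetric_mds(D, dims = 2, nstarts = 10)
  expect_lt(fit2$stress, 1e-6)
  fit1 <- nonmetric_mds(D, dims = 1, nstarts = 10)
  expect_lte(fit2$stress, fit1$stress)  # stress non-increasing in dims

  expect_error(nonmetric_mds(matrix(1:9, 3)), "symmetric")
})

test_that("complete-link clustering merges pairs first and is monotone", {
  # two tight pairs far apart
  x <- c(0, 0.1, 10, 10.2)
  D <- as.matrix(dist(x))
  h <- complete_link_clustering(D)
  expect_equal(sort(h$height[1:2]), c(0.1, 0.2))
  expect_gt(h$height[3], 9)
  expect_true(all(diff(h$height) >= 0))

  set.seed(1)
  p <- matrix(rnorm(20), 10, 2)
  h2 <- complete_link_clustering(as.matrix(dist(p)))
  expect_true(all(diff(h2$height) >= -1e-12))

  D2 <- matrix(c(0, 3, 3, 0), 2)
  h3 <- complete_link_clustering(D2)
  expect_equal(h3$height, 3)
  expect_error(complete_link_clustering(matrix(0, 1, 1)), "at least 2")
})

test_that("context gain vanishes when 3-chord ratings copy matched 2-chord means", {
  f <- function(j) 1 + (j %% 8)
  two <- dor_dataset("p", stimulus_set(2),
                     vapply(stimulus_set(2),
                            function(s) f(chord_interval(s[1], s[2])), 1.0))
  s3 <- stimulus_set(3, seed = 3)
  three <- dor_dataset("p", s3,
                       vapply(s3, function(s) f(chord_interval(s[2], s[3])), 1.0))
  d <- rbind(two, three)
  class(d) <- c("dor_dataset", "data.frame")
  cg <- context_gain_analysis(d)
  expect_true(all(abs(cg$gain) < 1e-12))
  # an identically zero grid is all ties: flagged, statistic 0
  expect_match(cg$test$test_name, "all ties")
  expect_equal(cg$test$statistic, 0)
})

test_that("context gain flags planted interval contrasts", {
  g13 <- function(a) if (a %in% c(0, 7)) 3 else if (a %in% c(1, 8)) -3 else 0
  s3 <- stimulus_set(3, seed = 3)
  three <- dor_dataset("p", s3, vapply(s3, function(s) {
    5 + g13(chord_interval(s[1], s[3]))
  }, 1.0))
  two <- dor_dataset("p", stimulus_set(2), rep(5, 144))
  d <- rbind(two, three)
  class(d) <- c("dor_dataset", "data.frame")
  cg <- context_gain_analysis(d)
  expect_equal(cg$bonferroni_threshold, 0.05 / 66)
  expect_identical(nrow(cg$posthoc), 66L)
  expect_identical(cg$test$df, 11L)
  flagged <- cg$posthoc[cg$posthoc$significant, c("interval_a", "interval_b")]
  key <- paste(flagged$interval_a, flagged$interval_b)
  for (pair in c("0 1", "0 8", "1 7", "7 8")) expect_true(pair %in% key)
  # gain grid itself carries the planted pattern
  expect_true(all(cg$gain["0", ] == 3))
  expect_true(all(cg$gain["1", ] == -3))
})
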