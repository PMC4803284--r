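test_that("the condition split partitions a complete design into 288 + 64", {
  p <- random_params("BU", seed = 3)
  d <- simulate_experiment(p, participants = 1, noise_sd = 0, seed = 5)
  sp <- split_individual(d)
  expect_identical(nrow(sp$train), 288L)
  expect_identical(nrow(sp$test), 64L)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(d))
  expect_true(all(sp$train$condition %in% 2:3))
  expect_true(all(sp$test$condition == 4L))
  d23 <- d[d$condition != 4, ]
  expect_error(split_individual(d23), "conditions")
})

test_that("k-fold partitions are disjoint, exhaustive and reproducible", {
  seqs <- simulation_sequences()[1:100]
  d <- dor_dataset(rep("a", 100), seqs, rep(5, 100))
  folds <- kfold_split(d, k = 10, seed = 42)
  expect_length(folds, 10)
  sizes <- vapply(folds, function(f) nrow(f$test), 1L)
  expect_true(all(sizes == 10L))
  test_rows <- sort(unlist(lapply(folds, function(f) rownames(f$test))))
  expect_identical(test_rows, sort(rownames(d)))
  for (f in folds) {
    expect_identical(nrow(f$train) + nrow(f$test), 100L)
    expect_length(intersect(rownames(f$train), rownames(f$test)), 0)
  }
  folds2 <- kfold_split(d, k = 10, seed = 42)
  expect_identical(lapply(folds, function(f) rownames(f$test)),
                   lapply(folds2, function(f) rownames(f$test)))
  expect_error(kfold_split(d, k = 1), "k must be")
})

test_that("held-out evaluation reuses the training cost formula", {
  seqs <- simulation_sequences()
  truth <- random_params("1M", seed = 6)
  d <- simulate_ratings(truth, seqs, mode = "continuous", seed = 2)
  fit <- fit_model(d, "1M", restarts = 2, seed = 3)
  expect_equal(evaluate_model(fit$params, d), fit$cost, tolerance = 1e-12)
  # single-trial evaluation equals that trial's term; fold test costs add up
  folds <- kfold_split(d, k = 5, seed = 1)
  total <- sum(vapply(folds, function(f) evaluate_model(fit$params, f$test), 1.0))
  expect_equal(total, evaluate_model(fit$params, d), tolerance = 1e-9)
  one <- d[3, ]
  expect_equal(evaluate_model(fit$params, one), cross_entropy(one, fit$params))
})

test_that("the exact sign test reproduces the published pairwise p-values", {
  printed <- list(c(3, 12, 0.035), c(2, 13, 0.007), c(5, 2, 0.453),
                  c(11, 4, 0.119), c(12, 3, 0.035), c(6, 9, 0.607),
                  c(9, 6, 0.607), c(6, 4, 0.754), c(1, 9, 0.022),
                  c(0, 10, 0.002), c(2, 8, 0.109), c(3, 7, 0.344))
  for (row in printed) {
    st <- sign_test(c(rep(1, row[1]), rep(-1, row[2]), 0))
    expect_identical(st$N, as.integer(row[1] + row[2]))  # ties excluded
    expect_lt(abs(st$p - row[3]), 1e-3)
    # independent check: symmetric-null exact binomial test
    expect_equal(st$p,
                 binom.test(row[1], row[1] + row[2], 0.5)$p.value,
                 tolerance = 1e-12)
  }
  expect_equal(sign_test(c(1, 1, 1))$p, 0.25)
  expect_error(sign_test(c(0, 0)), "ties")
})

test_that("the paired t-test matches its closed form", {
  expect_equal(paired_t_test(c(2, 1), c(1, 2))$T, 0)
  expect_equal(paired_t_test(c(2, 1), c(1, 2))$p, 1)
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(12)
    y <- rnorm(12)
    r <- paired_t_test(x, y)
    d <- x - y
    tstat <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(r$T, tstat, tolerance = 1e-9)
    expect_equal(r$df, 11)
    expect_equal(r$p, 2 * pt(-abs(tstat), 11), tolerance = 1e-9)
  }
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "variance")
})

test_that("model comparison tabulates every pair over the fitted units", {
  truth <- random_params("1M", seed = 8)
  seqs <- simulation_sequences()
  d <- simulate_ratings(truth, seqs, mode = "discrete", participants = 2,
                        noise_sd = 1, seed = 5)
  cmp <- model_comparison(d, models = c("1P", "1M", "2P"), scheme = "kfold",
                          restarts = 2, seed = 11, k = 4)
  expect_identical(nrow(cmp$table), 3L)  # C(3, 2)
  expect_identical(dim(cmp$test_H), c(4L, 3L))
  expect_true(all(is.finite(cmp$test_H)))
  expect_true(all(cmp$table$N <= 4))
  expect_true(all(c("t_statistic", "t_p") %in% names(cmp$table)))
  # data planted from 1M: the true model wins the cross-validated comparison
  m <- colMeans(cmp$test_H)
  expect_lt(m["1M"], m["1P"])
})
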