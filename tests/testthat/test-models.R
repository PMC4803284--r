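test_that("the initial reference belief follows the kappa parameterisation", {
  expect_equal(initial_belief(3L, 1), c(0, 0, 0, 1, rep(0, 8)))
  expect_equal(initial_belief(5L, 1 / 12), rep(1 / 12, 12))
  b <- initial_belief(0L, 0.5)
  expect_equal(b[1], 0.5)
  expect_equal(unique(b[-1]), 0.5 / 11)
  expect_equal(sum(b), 1)
  expect_error(initial_belief(0L, 0), "kappa")
  expect_error(initial_belief(0L, 1.1), "kappa")
})

test_that("Bayesian belief updates multiply likelihood into the prior", {
  Tm <- matrix(0.1, 12, 12)
  diag(Tm) <- NA
  # constant likelihood: any prior is preserved
  prior <- initial_belief(2L, 0.5)
  expect_equal(bu_step(prior, 0L, 7L, Tm), prior)
  # point mass is preserved
  pm <- initial_belief(4L, 1)
  expect_equal(bu_step(pm, 0L, 7L, Tm), pm)
  # single high cell: posterior checked against a direct 12-term product
  Tm2 <- Tm
  Tm2[3, 10] <- 0.9  # labels (2, 9): reference X with (0 - X) %% 12 == 2
  post <- bu_step(rep(1 / 12, 12), 0L, 7L, Tm2)
  direct <- vapply(0:11, function(x) {
    max(Tm2[(0 - x) %% 12 + 1, (7 - x) %% 12 + 1], 1e-12) / 12
  }, 1.0)
  expect_equal(post, direct / sum(direct))
  expect_equal(sum(post), 1)
  expect_error(bu_step(prior, 3L, 3L, Tm), "excluded")
})

test_that("the switching update resets when belief confidence is low", {
  Tm <- matrix(0.5, 12, 12)
  diag(Tm) <- NA
  p <- model_params("BS", Tm, kappa = 0.3, theta = 0.4)
  state <- list(belief = initial_belief(0L, 0.3), w = 1L)
  s2 <- bs_step(state, 2L, 0L, 7L, p)
  expect_identical(s2$w, 1L)          # t = 2 is the anchored case, no switch
  expect_equal(s2$belief, state$belief)  # constant T preserves the prior
  # constant T keeps max posterior at kappa = 0.3 < theta = 0.4: reset at t = 3
  s3 <- bs_step(s2, 3L, 7L, 2L, p)
  expect_identical(s3$w, 3L)
  expect_equal(s3$belief, initial_belief(7L, 0.3))  # re-anchored on c2
  # theta = 0 never resets and matches the plain Bayesian trajectory
  p0 <- model_params("BS", Tm, kappa = 0.3, theta = 0)
  s3b <- bs_step(s2, 3L, 7L, 2L, p0)
  expect_identical(s3b$w, 1L)
  expect_equal(s3b$belief, bu_step(s2$belief, 7L, 2L, Tm))
})

test_that("BU with kappa = 1 reads the expectancy matrix directly", {
  p <- random_params("BU", seed = 11)
  p$kappa <- 1
  for (j in 1:11) {
    expect_equal(expectancy(p, c(0L, j)), p$T[1, j + 1])
    expect_equal(expectancy(p, c(4L, (4L + j) %% 12L)), p$T[1, j + 1])
  }
})

test_that("2M averages its column over defined rows for two-chord input", {
  p <- random_params("2M", seed = 12)
  for (j in 1:11) {
    expect_equal(expectancy(p, c(3L, (3L + j) %% 12L)),
                 mean(p$T[-(j + 1), j + 1]))
  }
  # three-chord input reads the (interval two back, final interval) cell
  e <- expectancy(p, c(0L, 4L, 9L))
  expect_equal(e, p$T[9 + 1, 5 + 1])
})

test_that("interval-indexed models are transposition-invariant, pitch models not", {
  seqs <- fixture_sequences()
  for (m in c("1M", "2M", "BU", "BS")) {
    p <- random_params(m, seed = 21)
    for (s in seqs) {
      e0 <- expectancy(p, s)
      for (k in 1:11) {
        expect_equal(expectancy(p, transpose_sequence(s, k)), e0,
                     tolerance = 1e-12)
      }
    }
  }
  for (m in c("1P", "2P")) {
    p <- random_params(m, seed = 22)
    variant <- FALSE
    for (s in seqs) {
      e0 <- expectancy(p, s)
      for (k in 1:11) {
        if (expectancy(p, transpose_sequence(s, k)) != e0) variant <- TRUE
      }
    }
    expect_true(variant)
  }
})

test_that("BS with theta 0 equals BU on all 253 sequences, and differs when resets fire", {
  seqs <- simulation_sequences()
  d <- dor_dataset(rep("s", 253), seqs, rep(5, 253))
  for (i in 1:25) {
    pb <- random_params("BU", seed = 300 + i)
    ps <- model_params("BS", pb$T, kappa = pb$kappa, theta = 0)
    expect_identical(expectancy_batch(ps, d), expectancy_batch(pb, d))
  }
  # resets only matter from the third update on, i.e. for 4-chord trials
  s4 <- stimulus_set(4, seed = 9)
  d4 <- dor_dataset(rep("s", 64), s4, rep(5, 64))
  pb <- random_params("BU", seed = 333)
  ps <- model_params("BS", pb$T, kappa = pb$kappa, theta = 1)
  eb <- expectancy_batch(pb, d4)
  es <- expectancy_batch(ps, d4)
  expect_gt(max(abs(eb - es)), 0)
})

test_that("expectancies stay in [0, 1] and beliefs stay normalised", {
  seqs <- simulation_sequences()
  d <- dor_dataset(rep("s", 253), seqs, rep(5, 253))
  for (m in c("1P", "2P", "1M", "2M", "BU", "BS")) {
    for (i in 1:10) {
      p <- random_params(m, seed = 500 + i)
      e <- expectancy_batch(p, d)
      expect_true(all(e >= 0 & e <= 1))
    }
  }
  p <- random_params("BU", seed = 77)
  belief <- initial_belief(0L, p$kappa)
  walk <- c(0L, 7L, 2L, 9L, 4L, 11L, 6L)
  for (t in 2:length(walk)) {
    belief <- bu_step(belief, walk[t - 1], walk[t], p$T)
    expect_lt(abs(sum(belief) - 1), 1e-9)
    expect_true(all(belief >= 0))
  }
})

test_that("the R and compiled expectancy paths agree to machine precision", {
  seqs <- c(simulation_sequences(), stimulus_set(4, seed = 2))
  d <- dor_dataset(rep("s", length(seqs)), seqs, rep(5, length(seqs)))
  for (m in c("1P", "2P", "1M", "2M", "BU", "BS")) {
    p <- random_params(m, seed = 600 + nchar(m))
    er <- vapply(dataset_sequences(d), function(s) expectancy(p, s), 1.0)
    expect_equal(expectancy_batch(p, d), er, tolerance = 1e-14)
  }
})

test_that("the key-profile is the column mean over defined cells", {
  Tm <- matrix(0.5, 12, 12)
  diag(Tm) <- NA
  expect_equal(unname(key_profile(Tm)), rep(0.5, 12))
  Tm2 <- Tm
  Tm2[, 4] <- 0.9
  Tm2[4, 4] <- NA
  expect_equal(unname(key_profile(Tm2)[4]), 0.9)
  p <- random_params("BU", seed = 41)
  kp <- key_profile(p$T)
  brute <- vapply(1:12, function(j) {
    acc <- 0
    for (i in setdiff(1:12, j)) acc <- acc + p$T[i, j]
    acc / 11
  }, 1.0)
  expect_equal(unname(kp), brute)
  expect_equal(unname(key_profile(p$T, reduce = "sum")), brute * 11)
  expect_equal(unname(key_profile(p$T, dor_scale = TRUE)), brute * 10)
})

test_that("parameter JSON serialisation round-trips bit-exactly", {
  for (m in c("1P", "1M", "2M", "BU", "BS")) {
    p <- random_params(m, seed = 900 + nchar(m))
    path <- tempfile(fileext = ".json")
    write_params_json(p, path)
    q <- read_params_json(path)
    expect_identical(q$model, p$model)
    expect_identical(unname(q$T), unname(p$T))
    expect_identical(q$kappa, p$kappa)
    expect_identical(q$theta, p$theta)
  }
})
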