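# Held-out evaluation schemes and statistical model comparison.

#' Train/test split by condition
#'
#' The individual analysis trains on the 2- and 3-chord conditions and tests
#' generalisation on the 4-chord condition.
#'
#' @param dataset a `dor_dataset` covering conditions 2, 3 and 4.
#' @return a list with `train` and `test` datasets.
#' @export
split_individual <- function(dataset) {
  if (!all(2:4 %in% dataset$condition)) {
    stop("dataset must cover conditions 2, 3 and 4", call. = FALSE)
  }
  keep_attrs <- function(d) {
    attr(d, "provenance") <- attr(dataset, "provenance")
    class(d) <- class(dataset)
    d
  }
  list(train = keep_attrs(dataset[dataset$condition %in% 2:3, , drop = FALSE]),
       test = keep_attrs(dataset[dataset$condition == 4L, , drop = FALSE]))
}

#' Random k-fold partition of the trials
#'
#' Pools all participants and conditions and divides the trials into `k`
#' near-equal random subsets; each subset serves once as the test set.
#'
#' @param dataset a `dor_dataset`.
#' @param k number of folds.
#' @param seed integer seed; the same seed reproduces identical folds.
#' @return a list of `k` lists, each with `train` and `test` datasets.
#' @export
kfold_split <- function(dataset, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  n <- nrow(dataset)
  if (n < k) stop("need at least k trials", call. = FALSE)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  lapply(seq_len(k), function(f) {
    sub <- function(idx) {
      d <- dataset[idx, , drop = FALSE]
      attr(d, "provenance") <- attr(dataset, "provenance")
      class(d) <- class(dataset)
      d
    }
    list(train = sub(fold != f), test = sub(fold == f))
  })
}

#' Cross-entropy of fitted parameters on a held-out set
#'
#' Evaluates [cross_entropy()] with no parameter updates; repetition trials
#' are dropped first.
#'
#' @param params a `model_params` (typically `fit$params`).
#' @param dataset the evaluation `dor_dataset`.
#' @return the scalar held-out cost.
#' @export
evaluate_model <- function(params, dataset) {
  dataset <- drop_repetition_trials(dataset)
  cross_entropy(dataset, params)
}

#' Exact two-sided sign test
#'
#' Zero differences (ties) are excluded; with `n_pos` positive among `N`
#' remaining signs, the p-value is the exact two-sided binomial tail
#' probability under Binomial(N, 1/2):
#' `p = min(1, 2 * min(P(X <= min(n_pos, n_neg)), P(X >= max(n_pos, n_neg))))`.
#'
#' @param differences numeric vector of paired differences.
#' @return a list with `n_pos`, `n_neg`, `N` and `p`.
#' @export
sign_test <- function(differences) {
  n_pos <- sum(differences > 0)
  n_neg <- sum(differences < 0)
  N <- n_pos + n_neg
  if (N == 0) stop("all differences are ties", call. = FALSE)
  lo <- min(n_pos, n_neg)
  hi <- max(n_pos, n_neg)
  p <- min(1, 2 * min(pbinom(lo, N, 0.5), 1 - pbinom(hi - 1L, N, 0.5)))
  list(n_pos = n_pos, n_neg = n_neg, N = N, p = p)
}

#' Paired t-test on two matched samples
#'
#' Classical paired t statistic with `N - 1` degrees of freedom and a
#' two-sided p-value.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return a list with `T`, `df` and `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must be matched samples of length >= 2", call. = FALSE)
  }
  if (sd(x - y) == 0) stop("zero-variance differences", call. = FALSE)
  tt <- t.test(x, y, paired = TRUE)
  list(T = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Fit and compare expectancy models under a split scheme
#'
#' Fits every model on each training unit, evaluates the test cross-entropy,
#' and tabulates all pairwise comparisons:
#' * `scheme = "individual"`: one fit per participant per model, trained on
#'   that participant's 2- and 3-chord trials and tested on their 4-chord
#'   trials; paired units are participants, compared by exact sign tests.
#' * `scheme = "kfold"`: the pooled trials are split into `k` random folds;
#'   paired units are folds, compared by sign tests and paired t-tests.
#'
#' Repetition trials are dropped before splitting.
#'
#' @param dataset a `dor_dataset`.
#' @param models character vector of at least two model names.
#' @param scheme `"individual"` or `"kfold"`.
#' @param restarts restarts per fit.
#' @param seed integer seed governing folds and fits.
#' @param k number of folds for the kfold scheme.
#' @return a list of class `model_comparison`: `scheme`, `units` (unit
#'   labels), `train_H` and `test_H` (units x models matrices), `table`
#'   (one row per model pair with sign-test counts and p, plus paired-t
#'   columns for kfold), `fits` (per unit, per model `fit_result`s).
#' @export
model_comparison <- function(dataset, models = MODEL_NAMES,
                             scheme = c("individual", "kfold"),
                             restarts = 10L, seed = 1L, k = 10L) {
  scheme <- match.arg(scheme)
  models <- vapply(models, function(m) match.arg(m, MODEL_NAMES), "")
  if (length(models) < 2) stop("need at least 2 models", call. = FALSE)
  dataset <- drop_repetition_trials(dataset)

  if (scheme == "individual") {
    units <- sort(unique(dataset$participant))
    splits <- lapply(units, function(p) {
      split_individual(dataset[dataset$participant == p, , drop = FALSE])
    })
  } else {
    splits <- kfold_split(dataset, k = k, seed = seed)
    units <- paste0("fold", seq_along(splits))
  }

  train_H <- matrix(NA_real_, length(units), length(models),
                    dimnames = list(units, models))
  test_H <- train_H
  fits <- vector("list", length(units))
  names(fits) <- units
  for (u in seq_along(units)) {
    fits[[u]] <- vector("list", length(models))
    names(fits[[u]]) <- models
    for (m in seq_along(models)) {
      fit_seed <- as.integer((as.double(seed) * 131 + u * 17 + m) %% 2147483646 + 1)
      fit <- fit_model(splits[[u]]$train, models[m], restarts = restarts,
                       seed = fit_seed)
      fits[[u]][[m]] <- fit
      train_H[u, m] <- fit$cost
      test_H[u, m] <- evaluate_model(fit$params, splits[[u]]$test)
    }
  }

  pairs <- utils::combn(length(models), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    m1 <- models[pairs[1, i]]
    m2 <- models[pairs[2, i]]
    d <- test_H[, m1] - test_H[, m2]
    st <- tryCatch(sign_test(d), error = function(e) {
      list(n_pos = 0L, n_neg = 0L, N = 0L, p = NA_real_)
    })
    row <- data.frame(model1 = m1, model2 = m2,
                      positive = st$n_pos, negative = st$n_neg,
                      N = st$N, sign_p = st$p)
    if (scheme == "kfold") {
      tt <- tryCatch(paired_t_test(test_H[, m1], test_H[, m2]),
                     error = function(e) list(T = NA_real_, df = NA_integer_,
                                              p = NA_real_))
      row$t_statistic <- tt$T
      row$t_df <- tt$df
      row$t_p <- tt$p
    }
    row
  })
  structure(list(scheme = scheme, units = units, models = models,
                 train_H = train_H, test_H = test_H,
                 table = do.call(rbind, rows), fits = fits,
                 seed = as.integer(seed)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s scheme, %d units\n", x$scheme,
              length(x$units)))
  cat("mean test cross-entropies:\n")
  print(round(colMeans(x$test_H), 4))
  print(x$table, digits = 4)
  invisible(x)
}
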