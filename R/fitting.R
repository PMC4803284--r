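# Parameter estimation: rating -> probability map, cross-entropy cost, and
# discrete coordinate descent with random restarts.

#' Map a 9-point rating to the probability scale
#'
#' Ratings are calibrated linearly to expectancies through `A = 10 * E`, so
#' the neutral rating 5 corresponds to `E = 0.5`.
#'
#' @param A numeric rating(s) in `[1, 9]` (continuous synthetic ratings in
#'   `[0, 10]` are accepted with `continuous = TRUE`).
#' @param continuous widen the admissible range to `[0, 10]`.
#' @return `A / 10`.
#' @export
rating_to_prob <- function(A, continuous = FALSE) {
  lo <- if (continuous) 0 else 1
  hi <- if (continuous) 10 else 9
  if (any(A < lo | A > hi)) stop("rating out of range", call. = FALSE)
  A / 10
}

#' Cross-entropy cost of a model on a dataset
#'
#' The fitting cost treats each trial's normalised rating `A' = A/10` as a
#' target expectancy and charges the binary cross-entropy between `A'` and
#' the model's `E` for the presented final chord:
#' \deqn{H = \sum_n -\left[A'_n \log E_n + (1 - A'_n) \log(1 - E_n)\right].}
#' Each term is minimised exactly at `E = A'`, which is what makes the
#' `A = 10 E` calibration identifiable and noiseless parameter recovery
#' exact for the models without reference updating. `E` is clamped to
#' `[1e-12, 1 - 1e-12]`, so grid values of exactly 0 or 1 remain admissible.
#' `H` is non-negative and additive over disjoint trial subsets.
#'
#' @param dataset a `dor_dataset` free of immediate-repetition trials (see
#'   [drop_repetition_trials()]).
#' @param params a `model_params`.
#' @return the scalar cost H.
#' @export
cross_entropy <- function(dataset, params) {
  if (nrow(dataset) == 0) stop("empty dataset", call. = FALSE)
  if (any(vapply(dataset_sequences(dataset), has_repetition, TRUE))) {
    stop("dataset contains immediate-repetition trials; drop them first",
         call. = FALSE)
  }
  enc <- .encode_dataset(dataset)
  ap <- rating_to_prob(dataset$rating, continuous = TRUE)
  cpp_cost(enc$seqs, enc$lens, ap, .model_code(params$model),
           .flat_grid(params), .scalar_or(params$kappa, 1), params$theta)
}

# Free-parameter descriptors for the compiled coordinate-descent backend.
# kind: 0 = grid entry (step 0.1), 1 = kappa (step 1/12), 2 = theta (0.05).
.free_params <- function(model) {
  excl <- excluded_cells(model)
  tidx <- which(!excl) - 1L  # 0-based flat index, column-major
  kind <- rep(0L, length(tidx))
  if (model %in% c("BU", "BS")) {
    kind <- c(kind, 1L)
    tidx <- c(tidx, -1L)
  }
  if (model == "BS") {
    kind <- c(kind, 2L)
    tidx <- c(tidx, -1L)
  }
  list(kind = as.integer(kind), tidx = as.integer(tidx))
}

#' Parameter grids of the estimator
#'
#' The estimator is a lattice search: grid entries move in steps of 0.1 on
#' `[0, 1]`, `kappa` in steps of 1/12 on `(0, 1]`, and `theta` in steps of
#' 0.05 on `[0, 1]`.
#'
#' @param which one of `"T"`, `"kappa"`, `"theta"`.
#' @return the numeric vector of admissible values.
#' @export
parameter_grid <- function(which = c("T", "kappa", "theta")) {
  switch(match.arg(which),
         T = seq(0, 1, by = 0.1),
         kappa = (1:12) / 12,
         theta = seq(0, 1, by = 0.05))
}

#' Fit an expectancy model by discrete coordinate descent
#'
#' Trials containing an immediate chord repetition are dropped, ratings are
#' mapped to the probability scale, and the cross-entropy is minimised over
#' the parameter lattice ([parameter_grid()]): each restart draws every free
#' parameter uniformly at random on its grid, then repeatedly sweeps the
#' parameters in a freshly shuffled order, moving each to the better of its
#' two grid neighbours when that strictly lowers the cost, until a complete
#' sweep makes no move. The restart attaining the lowest terminal cost wins.
#'
#' @param dataset a `dor_dataset`.
#' @param model model name (`"1P"`, `"2P"`, `"1M"`, `"2M"`, `"BU"`, `"BS"`).
#' @param restarts number of random restarts (the reference analysis uses
#'   100; small values suffice for the separable models).
#' @param seed integer seed; the whole fit is a deterministic function of
#'   (dataset, model, restarts, seed).
#' @param shuffle_each_sweep reshuffle the parameter visiting order every
#'   sweep (default) or only once per restart.
#' @return a `fit_result` list: `params` (fitted `model_params`), `cost`,
#'   `restarts`, `best_restart`, `restart_costs`, `traces` (per-restart
#'   sweep-end cost sequences), `seed`, `n_trials`.
#' @export
fit_model <- function(dataset, model, restarts = 100L, seed = 1L,
                      shuffle_each_sweep = TRUE) {
  model <- match.arg(model, MODEL_NAMES)
  if (restarts < 1) stop("restarts must be >= 1", call. = FALSE)
  dataset <- drop_repetition_trials(dataset)
  if (nrow(dataset) == 0) stop("no trials left after exclusion", call. = FALSE)
  enc <- .encode_dataset(dataset)
  ap <- rating_to_prob(dataset$rating, continuous = TRUE)
  fp <- .free_params(model)
  set.seed(as.integer(seed))
  res <- cpp_fit(enc$seqs, enc$lens, ap, .model_code(model),
                 fp$kind, fp$tidx, as.integer(restarts), shuffle_each_sweep)
  params <- .values_to_params(model, res$values, fp)
  structure(list(params = params,
                 cost = res$cost,
                 restarts = as.integer(restarts),
                 best_restart = res$best_restart,
                 restart_costs = res$restart_costs,
                 traces = res$traces,
                 seed = as.integer(seed),
                 n_trials = nrow(dataset)),
            class = "fit_result")
}

.values_to_params <- function(model, values, fp) {
  excl <- excluded_cells(model)
  kappa <- NA_real_
  theta <- 0
  tvals <- values[fp$kind == 0L]
  if (model %in% c("BU", "BS")) kappa <- values[fp$kind == 1L]
  if (model == "BS") theta <- values[fp$kind == 2L]
  if (model %in% c("1P", "1M")) {
    T <- rep(NA_real_, 12)
    T[!excl] <- tvals
  } else {
    T <- matrix(NA_real_, 12, 12)
    T[!excl] <- tvals
  }
  model_params(model, T, kappa = kappa, theta = theta)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s model: H = %.4f over %d trials (best of %d restarts, #%d)\n",
    x$params$model, x$cost, x$n_trials, x$restarts, x$best_restart))
  invisible(x)
}
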