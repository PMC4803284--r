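# Expectancy models
#
# All six models map a chord sequence to the internal fitness E of its final
# chord, a free value in [0, 1] (NOT a normalised probability over the 12
# candidates: E is calibrated to ratings through A = 10 * E, so a strongly
# related progression must be able to reach E ~ 0.9).
#
# Indexing conventions (0-based pitch classes, A = 0):
#  * BU/BS: T(i, j) is the fitness of moving from a chord labelled i to a
#    chord labelled j, labels being intervals from the hidden reference X
#    (label = (root - X) mod 12, stored 1-based in the matrix). The diagonal
#    (immediate repetition under every X) is excluded.
#  * 2M: T(i, j) with i = interval from c_{t-2} to c_t, j = interval from
#    c_{t-1} to c_t. Column j = 0 (repetition of the penultimate chord) and
#    the diagonal i = j (repetition two back) are excluded.
#  * 2P: T(i, j) over raw root pairs (penultimate, final); diagonal excluded.
#  * 1M: 12-vector over the final interval; interval 0 excluded.
#  * 1P: 12-vector over the final root.

LIK_FLOOR <- 1e-12

#' Excluded-cell mask of a model's expectancy grid
#'
#' Cells representing an immediate chord repetition are excluded from
#' estimation and stored as `NA`.
#'
#' @param model one of `"1P"`, `"2P"`, `"1M"`, `"2M"`, `"BU"`, `"BS"`.
#' @return a logical matrix (12 x 12) or vector (length 12), `TRUE` where
#'   the cell is excluded.
#' @export
excluded_cells <- function(model) {
  model <- match.arg(model, MODEL_NAMES)
  switch(model,
    "1P" = rep(FALSE, 12),
    "1M" = c(TRUE, rep(FALSE, 11)),
    "2P" = ,
    "BU" = ,
    "BS" = diag(12) == 1,
    "2M" = {
      m <- diag(12) == 1
      m[, 1] <- TRUE
      m
    })
}

#' Bundle model parameters
#'
#' @param model model name.
#' @param T expectancy grid: a 12 x 12 matrix (2P, 2M, BU, BS) or a
#'   12-vector (1P, 1M), with `NA` at excluded cells. Defined entries lie in
#'   `[0, 1]`.
#' @param kappa initial reference weight on the first chord, in `(0, 1]`
#'   (BU and BS only).
#' @param theta reset threshold on the reference belief, in `[0, 1]`
#'   (BS only; fixed to 0 for BU).
#' @return an object of class `model_params`.
#' @export
model_params <- function(model, T, kappa = NA_real_, theta = 0) {
  model <- match.arg(model, MODEL_NAMES)
  excl <- excluded_cells(model)
  T <- .check_grid(model, T, excl)
  if (model %in% c("BU", "BS")) {
    if (is.na(kappa) || kappa <= 0 || kappa > 1) {
      stop("kappa must lie in (0, 1] for BU/BS", call. = FALSE)
    }
  } else {
    kappa <- NA_real_
  }
  if (model != "BS") theta <- 0
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]", call. = FALSE)
  structure(list(model = model, T = T, kappa = kappa, theta = theta),
            class = "model_params")
}

.check_grid <- function(model, T, excl) {
  if (model %in% c("1P", "1M")) {
    if (length(T) != 12L) stop(model, " uses a 12-vector grid", call. = FALSE)
    T <- as.numeric(T)
  } else {
    if (!is.matrix(T) || !all(dim(T) == c(12L, 12L))) {
      stop(model, " uses a 12 x 12 grid", call. = FALSE)
    }
    storage.mode(T) <- "double"
  }
  if (anyNA(T[!excl]) || any(T[!excl] < 0 | T[!excl] > 1)) {
    stop("defined grid entries must lie in [0, 1]", call. = FALSE)
  }
  T[excl] <- NA_real_
  T
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %s model, %d free grid entries", x$model,
              sum(!excluded_cells(x$model))))
  if (x$model %in% c("BU", "BS")) cat(sprintf(", kappa = %.4f", x$kappa))
  if (x$model == "BS") cat(sprintf(", theta = %.2f", x$theta))
  cat("\n")
  invisible(x)
}

#' Initial belief over the hidden reference
#'
#' When the first chord is heard, the reference distribution places weight
#' `kappa` on that chord and spreads the rest uniformly over the other 11
#' candidates. `kappa = 1/12` is the uninformative limit; `kappa = 1` pins
#' the reference to the first chord.
#'
#' @param c1 first chord root (0..11).
#' @param kappa weight in `(0, 1]`.
#' @return a 12-vector of probabilities over candidate references (index
#'   `x + 1` holds reference root `x`).
#' @export
initial_belief <- function(c1, kappa) {
  .check_root(c1)
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]", call. = FALSE)
  b <- rep((1 - kappa) / 11, 12)
  b[c1 + 1L] <- kappa
  b
}

# likelihood of the observed pair under each candidate reference
.pair_likelihoods <- function(c_prev, c_cur, T) {
  x <- 0:11
  lik <- T[cbind((c_prev - x) %% 12L + 1L, (c_cur - x) %% 12L + 1L)]
  pmax(lik, LIK_FLOOR)
}

#' One Bayesian update of the reference belief
#'
#' Multiplies the prior belief by the likelihood of the observed chord pair
#' under each candidate reference (the reference-relative expectancy-matrix
#' entry, floored at `1e-12`) and renormalises.
#'
#' @param belief prior 12-vector over references.
#' @param c_prev,c_cur the observed chord pair (roots 0..11, distinct).
#' @param T a BU/BS-indexed 12 x 12 expectancy matrix.
#' @return the posterior 12-vector.
#' @export
bu_step <- function(belief, c_prev, c_cur, T) {
  if (abs(sum(belief) - 1) > 1e-9) stop("belief must be normalised", call. = FALSE)
  if ((c_cur - c_prev) %% 12L == 0L) {
    stop("immediate repetitions map to excluded cells", call. = FALSE)
  }
  post <- .pair_likelihoods(c_prev, c_cur, T) * belief
  z <- sum(post)
  if (z <= 0) stop("degenerate evidence: all-zero posterior", call. = FALSE)
  post / z
}

#' One update of the switching model's belief state
#'
#' As [bu_step()], except that at `t = 2`, or whenever the provisional
#' posterior's maximum falls below the threshold `theta`, the prior is
#' replaced by the initial-state distribution re-anchored on the preceding
#' chord (weight `kappa`) before updating, and the switch time `w` is set to
#' `t`. With `theta = 0` the reset never fires and the trajectory equals the
#' plain Bayesian-updating one.
#'
#' @param state list with elements `belief` (12-vector) and `w` (time step
#'   of the most recent switch; 1 when none occurred).
#' @param t current 1-based time step (>= 2).
#' @param c_prev,c_cur observed chord pair.
#' @param params a BS `model_params`.
#' @return the updated state list.
#' @export
bs_step <- function(state, t, c_prev, c_cur, params) {
  stopifnot(params$model == "BS", t >= 2)
  lik <- .pair_likelihoods(c_prev, c_cur, params$T)
  if (t == 2) {
    post <- lik * state$belief  # prior is already anchored on c1
    return(list(belief = post / sum(post), w = state$w))
  }
  post <- lik * state$belief
  post <- post / sum(post)
  if (max(post) < params$theta) {
    prior <- initial_belief(c_prev, params$kappa)
    post <- lik * prior
    post <- post / sum(post)
    return(list(belief = post, w = t))
  }
  list(belief = post, w = state$w)
}

#' Internal fitness of the final chord of a sequence
#'
#' Evaluates the model's expectancy E in `[0, 1]` for the last chord given
#' its context:
#' * `1P`: the final root's profile value, context-free;
#' * `2P`: the (penultimate root, final root) grid entry;
#' * `1M`: the final interval's profile value;
#' * `2M`: the (interval two back, final interval) entry; two-chord
#'   sequences average the column over its 11 defined rows (flat prior on
#'   the missing two-back chord);
#' * `BU`/`BS`: the reference belief is propagated over chords `1..t-1`
#'   and E is the belief-weighted reference-relative grid entry for the
#'   final pair.
#'
#' @param params a `model_params`.
#' @param seq integer root vector (length 2..4; 1P also accepts length 1).
#' @return E, a real in `[0, 1]`.
#' @export
expectancy <- function(params, seq) {
  if (params$model == "1P") {
    if (length(seq) == 1L) .check_root(seq) else .check_sequence(seq)
    return(params$T[seq[length(seq)] + 1L])
  }
  .check_sequence(seq)
  if (has_repetition(seq)) {
    stop("sequence touches an excluded repetition cell", call. = FALSE)
  }
  tau <- length(seq)
  cp <- seq[tau - 1L]
  cf <- seq[tau]
  switch(params$model,
    "2P" = params$T[cp + 1L, cf + 1L],
    "1M" = params$T[chord_interval(cp, cf) + 1L],
    "2M" = {
      j <- chord_interval(cp, cf) + 1L
      if (tau == 2L) {
        mean(params$T[-j, j])
      } else {
        i <- chord_interval(seq[tau - 2L], cf) + 1L
        params$T[i, j]
      }
    },
    {
      belief <- .propagate_belief(params, seq)
      x <- 0:11
      sum(params$T[cbind((cp - x) %% 12L + 1L, (cf - x) %% 12L + 1L)] * belief)
    })
}

.propagate_belief <- function(params, seq) {
  tau <- length(seq)
  if (params$model == "BU") {
    belief <- initial_belief(seq[1], params$kappa)
    t <- 2L
    while (t <= tau - 1L) {
      belief <- bu_step(belief, seq[t - 1L], seq[t], params$T)
      t <- t + 1L
    }
    belief
  } else {
    state <- list(belief = initial_belief(seq[1], params$kappa), w = 1L)
    t <- 2L
    while (t <= tau - 1L) {
      state <- bs_step(state, t, seq[t - 1L], seq[t], params)
      t <- t + 1L
    }
    state$belief
  }
}

#' Model expectancies for every trial of a dataset
#'
#' Fast batch version of [expectancy()] (compiled backend); used by the
#' fitting and evaluation code.
#'
#' @param params a `model_params`.
#' @param dataset a `dor_dataset`, free of immediate-repetition trials.
#' @return numeric vector of E values, one per trial.
#' @export
expectancy_batch <- function(params, dataset) {
  enc <- .encode_dataset(dataset)
  cpp_expectancies(enc$seqs, enc$lens, .model_code(params$model),
                   .flat_grid(params), .scalar_or(params$kappa, 1),
                   params$theta)
}

.encode_dataset <- function(dataset) {
  seqs <- as.matrix(dataset[, c("c1", "c2", "c3", "c4")])
  seqs[is.na(seqs)] <- -1L
  storage.mode(seqs) <- "integer"
  list(seqs = seqs, lens = as.integer(dataset$condition))
}

.flat_grid <- function(params) {
  v <- as.numeric(params$T)
  v[is.na(v)] <- 0  # excluded cells are never read
  if (length(v) == 12L) v <- c(v, numeric(132L))
  v
}

.scalar_or <- function(x, default) if (is.na(x)) default else x

#' Key-profile of a reference-relative expectancy matrix
#'
#' Marginalises the preceding chord out of a BU/BS expectancy matrix: for
#' each reference-relative label j, the profile is the mean of `T[i, j]`
#' over the 11 defined preceding labels i. The mean (rather than the raw
#' column sum) keeps the profile on the `[0, 1]` fitness scale so it can be
#' read as an ideal DOR via the `10 * E` calibration; the raw sum is
#' available via `reduce = "sum"`.
#'
#' @param T a BU/BS-indexed 12 x 12 matrix (`NA` diagonal).
#' @param reduce `"mean"` (default) or `"sum"`.
#' @param dor_scale multiply by 10 to report on the rating scale.
#' @return a named 12-vector, labels `I1`..`I12` (intervals 0..11 from the
#'   reference).
#' @export
key_profile <- function(T, reduce = c("mean", "sum"), dor_scale = FALSE) {
  reduce <- match.arg(reduce)
  stopifnot(is.matrix(T), all(dim(T) == c(12L, 12L)))
  prof <- vapply(1:12, function(j) {
    v <- T[-j, j]
    if (reduce == "mean") mean(v) else sum(v)
  }, 1.0)
  if (dor_scale) prof <- prof * 10
  setNames(prof, paste0("I", 1:12))
}

#' Serialise model parameters to JSON
#'
#' The document records the model name, the full 12 x 12 grid (`null` at
#' excluded cells; 1P/1M vectors are stored as their 12-vector), `kappa` and
#' `theta`. Numbers carry 17 significant digits so that
#' `read_params_json(write_params_json(p))` is bit-exact.
#'
#' @param params a `model_params`.
#' @param path output path.
#' @export
write_params_json <- function(params, path) {
  doc <- list(model = params$model,
              T = params$T,
              kappa = params$kappa,
              theta = params$theta)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  T <- doc$T
  if (is.matrix(T)) {
    # stored row-major; fromJSON rebuilds rows as rows, nothing to do
  } else {
    T <- as.numeric(T)
  }
  kappa <- if (is.null(doc$kappa)) NA_real_ else doc$kappa
  model_params(doc$model, T, kappa = kappa, theta = doc$theta %||% 0)
}
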