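# Synthetic rating generation and parameter-recovery studies.

#' Draw random model parameters on the estimation lattice
#'
#' Every free parameter is drawn uniformly from its grid
#' ([parameter_grid()]); excluded cells stay undefined. BU draws `kappa`
#' and keeps `theta = 0`; BS draws both.
#'
#' @param model model name.
#' @param seed integer seed.
#' @return a `model_params`.
#' @export
sample_params <- function(model, seed = 1L) {
  model <- match.arg(model, MODEL_NAMES)
  set.seed(as.integer(seed))
  excl <- excluded_cells(model)
  tg <- parameter_grid("T")
  if (model %in% c("1P", "1M")) {
    T <- rep(NA_real_, 12)
  } else {
    T <- matrix(NA_real_, 12, 12)
  }
  T[!excl] <- sample(tg, sum(!excl), replace = TRUE)
  kappa <- if (model %in% c("BU", "BS")) sample(parameter_grid("kappa"), 1L)
           else NA_real_
  theta <- if (model == "BS") sample(parameter_grid("theta"), 1L) else 0
  model_params(model, T, kappa = kappa, theta = theta)
}

#' Simulate DOR ratings from planted parameters
#'
#' Computes the model expectancy E for each sequence and emits ratings
#' through the `A = 10 * E` calibration:
#' * `mode = "continuous"`: the lossless channel `A = 10 * E` (real-valued,
#'   in `[0, 10]`), used by recovery studies;
#' * `mode = "discrete"`: `round(10 * E + N(0, noise_sd))` clipped to the
#'   9-point scale, emulating behavioral responses.
#'
#' @param params a `model_params`.
#' @param sequences list of integer root vectors (no immediate repetitions
#'   for the repetition-excluding models).
#' @param mode `"continuous"` or `"discrete"`.
#' @param participants number of simulated participants (replicates).
#' @param noise_sd rating-scale Gaussian noise SD (discrete mode).
#' @param seed integer seed.
#' @return a `dor_dataset`.
#' @export
simulate_ratings <- function(params, sequences,
                             mode = c("continuous", "discrete"),
                             participants = 1L, noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  E <- vapply(sequences, function(s) expectancy(params, s), 1.0)
  set.seed(as.integer(seed))
  n <- length(sequences)
  ratings <- numeric(0)
  for (p in seq_len(participants)) {
    if (mode == "continuous") {
      ratings <- c(ratings, 10 * E)
    } else {
      a <- round(10 * E + rnorm(n, 0, noise_sd))
      ratings <- c(ratings, pmin(pmax(a, 1), 9))
    }
  }
  dor_dataset(rep(sprintf("sim%02d", seq_len(participants)), each = n),
              rep(sequences, participants), ratings,
              provenance = sprintf("simulated:%s", params$model),
              continuous = (mode == "continuous"))
}

#' Simulate a full multi-participant experiment
#'
#' Generates the complete stimulus design (144 + 144 + 64 trials per
#' participant, conditions 2-4, fresh random initial roots per participant)
#' and rates it under the planted model, in discrete mode with additive
#' rating noise. Used to exercise the pre-modelling and evaluation stages
#' on data shaped like a behavioral session.
#'
#' Trials with an immediately repeated chord cannot be rated by the
#' repetition-excluding models; emulating the unstable behavioral responses
#' to such stimuli, they receive noisy neutral ratings (midpoint 5 plus the
#' same Gaussian noise) unless `drop_repetitions = TRUE` removes them. This
#' keeps the 2-chord design complete for the pre-modelling statistics while
#' the fitting stage drops those trials anyway.
#'
#' @param params a `model_params`.
#' @param participants number of participants.
#' @param noise_sd rating noise SD.
#' @param seed integer seed.
#' @param drop_repetitions remove immediate-repetition trials instead of
#'   giving them neutral ratings.
#' @return a `dor_dataset`.
#' @export
simulate_experiment <- function(params, participants = 15L, noise_sd = 1,
                                seed = 1L, drop_repetitions = FALSE) {
  set.seed(as.integer(seed))
  sub_seeds <- matrix(sample.int(2147483646L, participants * 4L),
                      participants, 4L)
  out <- NULL
  for (p in seq_len(participants)) {
    seqs <- c(stimulus_set(2L),
              stimulus_set(3L, seed = sub_seeds[p, 1L]),
              stimulus_set(4L, seed = sub_seeds[p, 2L]))
    is_rep <- if (params$model == "1P") rep(FALSE, length(seqs)) else
      vapply(seqs, has_repetition, TRUE)
    d <- simulate_ratings(params, seqs[!is_rep], mode = "discrete",
                          participants = 1L, noise_sd = noise_sd,
                          seed = sub_seeds[p, 3L])
    if (any(is_rep) && !drop_repetitions) {
      set.seed(sub_seeds[p, 4L])
      a <- round(5 + rnorm(sum(is_rep), 0, noise_sd))
      r <- dor_dataset(rep("tmp", sum(is_rep)), seqs[is_rep],
                       pmin(pmax(a, 1), 9))
      d <- rbind(d, r)
    }
    d$participant <- sprintf("p%02d", p)
    out <- if (is.null(out)) d else rbind(out, d)
  }
  attr(out, "provenance") <- sprintf("simulated-experiment:%s", params$model)
  class(out) <- c("dor_dataset", "data.frame")
  out
}

.param_vector <- function(params) {
  excl <- excluded_cells(params$model)
  v <- params$T[!excl]
  names(v) <- paste0("T", which(!excl))
  if (params$model %in% c("BU", "BS")) v <- c(v, kappa = params$kappa)
  if (params$model == "BS") v <- c(v, theta = params$theta)
  v
}

#' Parameter-recovery study
#'
#' Repeats the cycle plant -> simulate -> refit: parameters are drawn on
#' the lattice, noiseless continuous ratings are generated for the 253
#' repetition-free 2- and 3-chord patterns, the model is refit by
#' coordinate descent, and the signed estimation error (estimate - truth)
#' is recorded per parameter. For the models without reference updating
#' (1P, 2P, 1M, 2M) the lossless channel makes recovery exact; the updating
#' models (BU, BS) carry a finite bias that this study quantifies.
#'
#' @param model model name.
#' @param repetitions number of plant/refit cycles.
#' @param restarts restarts per refit.
#' @param seed integer seed.
#' @param randomize_roots randomise the 3-chord initial roots (default for
#'   the pitch-indexed 1P/2P models, which are not transposition-invariant).
#' @return a list of class `recovery_report`: `model`, `repetitions`,
#'   `errors` (repetitions x parameters matrix of signed errors), `bias`
#'   and `sd` (per-parameter mean and SD), and the summary scalars
#'   `max_abs_bias`, `max_sd`.
#' @export
recovery_study <- function(model, repetitions = 100L, restarts = 10L,
                           seed = 1L,
                           randomize_roots = model %in% c("1P", "2P")) {
  model <- match.arg(model, MODEL_NAMES)
  set.seed(as.integer(seed))
  rep_seeds <- matrix(sample.int(2147483646L, repetitions * 3L),
                      repetitions, 3L)
  errors <- NULL
  for (r in seq_len(repetitions)) {
    truth <- sample_params(model, seed = rep_seeds[r, 1L])
    seqs <- simulation_sequences(randomize_roots = randomize_roots,
                                 seed = rep_seeds[r, 2L])
    data <- simulate_ratings(truth, seqs, mode = "continuous",
                             seed = rep_seeds[r, 2L])
    fit <- fit_model(data, model, restarts = restarts,
                     seed = rep_seeds[r, 3L])
    err <- .param_vector(fit$params) - .param_vector(truth)
    errors <- rbind(errors, err)
  }
  rownames(errors) <- NULL
  bias <- colMeans(errors)
  sdev <- apply(errors, 2L, sd)
  if (repetitions == 1L) sdev[] <- 0
  structure(list(model = model, repetitions = repetitions,
                 errors = errors, bias = bias, sd = sdev,
                 max_abs_bias = max(abs(bias)), max_sd = max(sdev)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> %s model, %d repetitions: max |bias| = %.4g, max SD = %.4g\n",
    x$model, x$repetitions, x$max_abs_bias, x$max_sd))
  invisible(x)
}
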