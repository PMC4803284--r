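#' Directed interval between two chord roots
#'
#' The directed root distance from `a` to `b`, reduced modulo 12 (octave
#' equivalence). Roots use the internal 0..11 coding (0 = A ... 11 = G sharp).
#'
#' @param a,b integer chord roots in 0..11 (vectorised).
#' @return integer interval(s) in 0..11, `(b - a) mod 12`.
#' @examples
#' chord_interval(0, 7)  # A -> E, a fifth: 7
#' chord_interval(11, 0) # G# -> A wraps to 1
#' @export
chord_interval <- function(a, b) {
  .check_root(a)
  .check_root(b)
  (b - a) %% 12L
}

.check_root <- function(x) {
  if (length(x) == 0 || anyNA(x) || any(x != as.integer(x)) ||
      any(x < 0L) || any(x > 11L)) {
    stop("chord roots must be integers in 0..11", call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Transpose a chord sequence
#'
#' Shifts every root by `k` semitones modulo 12. All pairwise intervals are
#' preserved, which is the invariance the interval-indexed models (1M, 2M,
#' BU, BS) inherit.
#'
#' @param seq integer vector of roots (0..11), length 2..4.
#' @param k integer transposition in semitones (any integer).
#' @return transposed integer vector of roots.
#' @examples
#' transpose_sequence(c(0, 7), 2)
#' @export
transpose_sequence <- function(seq, k) {
  .check_sequence(seq)
  (seq + as.integer(k)) %% 12L
}

.check_sequence <- function(seq) {
  if (!length(seq) %in% 2:4) {
    stop("chord sequences have length 2, 3 or 4", call. = FALSE)
  }
  .check_root(seq)
}

#' Enumerate the stimulus set of one experimental condition
#'
#' The experimental design uses three sequence lengths:
#' * condition 2: all ordered pairs of the 12 major-triad roots (144
#'   sequences, repetitions included);
#' * condition 3: all 144 ordered pairs of directed root intervals, each
#'   realised from an initial root drawn uniformly at random;
#' * condition 4: all 64 triples of intervals over \{2, 5, 7, 10\} semitones
#'   (major 2nd, perfect 4th, perfect 5th, minor 7th), random initial root.
#'
#' @param condition 2, 3 or 4 (the sequence length).
#' @param seed integer seed for the random initial roots (conditions 3 and 4).
#' @return a list of integer root vectors, one per sequence.
#' @examples
#' length(stimulus_set(2))           # 144
#' length(stimulus_set(4, seed = 1)) # 64
#' @export
stimulus_set <- function(condition, seed = 1L) {
  if (!condition %in% 2:4) stop("condition must be 2, 3 or 4", call. = FALSE)
  if (condition == 2) {
    grid <- expand.grid(c2 = 0:11, c1 = 0:11)
    return(Map(function(a, b) c(a, b), grid$c1, grid$c2))
  }
  set.seed(as.integer(seed))
  if (condition == 3) {
    grid <- expand.grid(i2 = 0:11, i1 = 0:11)
    roots <- sample(0:11, nrow(grid), replace = TRUE)
    return(Map(function(r, i1, i2) c(r, (r + i1) %% 12L, (r + i1 + i2) %% 12L),
               roots, grid$i1, grid$i2))
  }
  iv <- c(2L, 5L, 7L, 10L)
  grid <- expand.grid(i3 = iv, i2 = iv, i1 = iv)
  roots <- sample(0:11, nrow(grid), replace = TRUE)
  Map(function(r, i1, i2, i3) {
    c(r, (r + i1) %% 12L, (r + i1 + i2) %% 12L, (r + i1 + i2 + i3) %% 12L)
  }, roots, grid$i1, grid$i2, grid$i3)
}

#' Repetition-free sequences for recovery simulations
#'
#' The 253 two- and three-chord patterns with no immediately repeated chord:
#' all 132 ordered pairs of distinct roots, plus all 121 three-chord interval
#' patterns whose two successive intervals are both nonzero, realised from
#' the canonical initial root 0 (the interval-indexed models are
#' transposition-invariant, so the anchor is immaterial for them).
#'
#' @param randomize_roots if `TRUE`, the 3-chord patterns get a uniformly
#'   random initial root instead of the canonical 0 (needed when studying the
#'   pitch-indexed 1P/2P models, which are not transposition-invariant).
#' @param seed seed used when `randomize_roots = TRUE`.
#' @return a list of 253 integer root vectors.
#' @export
simulation_sequences <- function(randomize_roots = FALSE, seed = 1L) {
  pairs <- expand.grid(c2 = 0:11, c1 = 0:11)
  pairs <- pairs[pairs$c1 != pairs$c2, ]
  two <- Map(function(a, b) c(a, b), pairs$c1, pairs$c2)
  grid <- expand.grid(i2 = 1:11, i1 = 1:11)
  if (randomize_roots) {
    set.seed(as.integer(seed))
    roots <- sample(0:11, nrow(grid), replace = TRUE)
  } else {
    roots <- rep(0L, nrow(grid))
  }
  three <- Map(function(r, i1, i2) c(r, (r + i1) %% 12L, (r + i1 + i2) %% 12L),
               roots, grid$i1, grid$i2)
  c(two, three)
}

#' Construct a rating dataset
#'
#' A `dor_dataset` is a data frame with one row per rated trial: columns
#' `participant` (character), `condition` (2, 3 or 4), `c1`..`c4` (roots in
#' 0..11, `NA` beyond the sequence length) and `rating`. Ratings are integers
#' on the 9-point scale for behavioral data; synthetic continuous-mode data
#' may carry real ratings in `[0, 10]` (the lossless `10 * E` channel).
#'
#' @param participant character vector of participant identifiers.
#' @param sequences list of integer root vectors (0..11 coding).
#' @param rating numeric vector of ratings.
#' @param provenance free-text source tag.
#' @param continuous allow real-valued ratings in `[0, 10]`.
#' @return a data frame of class `dor_dataset`.
#' @export
dor_dataset <- function(participant, sequences, rating, provenance = "",
                        continuous = FALSE) {
  participant <- rep_len(as.character(participant), length(sequences))
  stopifnot(length(rating) == length(sequences))
  if (length(sequences) == 0) stop("a rating dataset cannot be empty", call. = FALSE)
  lens <- vapply(sequences, length, 1L)
  lapply(sequences, .check_sequence)
  .check_rating(rating, continuous)
  mat <- matrix(NA_integer_, length(sequences), 4L)
  for (i in seq_along(sequences)) mat[i, seq_len(lens[i])] <- sequences[[i]]
  out <- data.frame(participant = as.character(participant),
                    condition = lens,
                    c1 = mat[, 1], c2 = mat[, 2], c3 = mat[, 3], c4 = mat[, 4],
                    rating = rating,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("dor_dataset", "data.frame")
  out
}

.check_rating <- function(rating, continuous = FALSE) {
  if (anyNA(rating)) stop("ratings must not be missing", call. = FALSE)
  if (continuous) {
    if (any(rating < 0 | rating > 10)) {
      stop("continuous ratings must lie in [0, 10]", call. = FALSE)
    }
  } else if (any(rating != round(rating) | rating < 1 | rating > 9)) {
    stop("ratings must be integers on the 9-point scale (1..9)", call. = FALSE)
  }
  invisible(rating)
}

#' @export
print.dor_dataset <- function(x, ...) {
  cat(sprintf("<dor_dataset> %d trials, %d participants, conditions {%s}\n",
              nrow(x), length(unique(x$participant)),
              paste(sort(unique(x$condition)), collapse = ", ")))
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("  provenance:", attr(x, "provenance"), "\n")
  }
  print(head(as.data.frame(x), 5L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract trial sequences from a dataset
#'
#' @param dataset a `dor_dataset`.
#' @return a list of integer root vectors.
#' @export
dataset_sequences <- function(dataset) {
  mat <- as.matrix(dataset[, c("c1", "c2", "c3", "c4")])
  lapply(seq_len(nrow(mat)), function(i) {
    as.integer(mat[i, seq_len(dataset$condition[i])])
  })
}

#' Does a sequence contain an immediate chord repetition?
#'
#' @param seq integer root vector.
#' @return logical.
#' @export
has_repetition <- function(seq) any(diff(seq) %% 12L == 0L)

#' Drop trials with immediately repeated chords
#'
#' Ratings of immediate self-transitions are unstable and the corresponding
#' expectancy-matrix cells are excluded from estimation, so such trials are
#' removed before fitting and evaluation.
#'
#' @param dataset a `dor_dataset`.
#' @return the filtered dataset (same class and attributes).
#' @export
drop_repetition_trials <- function(dataset) {
  keep <- !vapply(dataset_sequences(dataset), has_repetition, TRUE)
  out <- dataset[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(dataset, "provenance")
  class(out) <- class(dataset)
  out
}

#' Read a trial-level DOR rating CSV
#'
#' The dialect has one row per trial with columns `participant`,
#' `chord1`..`chord4` (roots coded 1..12; cells beyond the sequence length
#' empty) and `rating` (1..9). Roots are decoded to the internal 0..11
#' coding; the condition is inferred from the number of chord cells present.
#'
#' @param path file path.
#' @param continuous accept real-valued ratings in `[0, 10]` (synthetic
#'   continuous-mode files); default `FALSE` enforces the 9-point scale.
#' @return a `dor_dataset`.
#' @export
read_dor_csv <- function(path, continuous = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "chord1", "chord2", "chord3", "chord4", "rating")
  if (!all(need %in% names(raw))) {
    stop("missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) stop("a rating dataset cannot be empty", call. = FALSE)
  chords <- as.matrix(raw[, c("chord1", "chord2", "chord3", "chord4")])
  seqs <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    v <- suppressWarnings(as.numeric(chords[i, ]))
    v <- v[!is.na(v)]
    if (!length(v) %in% 2:4 || any(v != round(v)) || any(v < 1 | v > 12)) {
      stop(sprintf("row %d: chords must be 2-4 integer codes in 1..12", i),
           call. = FALSE)
    }
    seqs[[i]] <- as.integer(v) - 1L
  }
  rat <- suppressWarnings(as.numeric(raw$rating))
  if (anyNA(rat)) {
    stop(sprintf("row %d: unparseable rating", which(is.na(rat))[1]), call. = FALSE)
  }
  tryCatch(.check_rating(rat, continuous), error = function(e) {
    bad <- if (continuous) which(rat < 0 | rat > 10) else
      which(rat != round(rat) | rat < 1 | rat > 9)
    stop(sprintf("row %d: rating %s out of scale", bad[1], rat[bad[1]]),
         call. = FALSE)
  })
  dor_dataset(raw$participant, seqs, rat, provenance = path,
              continuous = continuous)
}

#' Write a rating dataset in the trial-level CSV dialect
#'
#' The inverse of [read_dor_csv()]: roots are encoded back to 1..12 and
#' chord cells beyond the sequence length are left empty. Reading the file
#' back yields an identical dataset.
#'
#' @param dataset a `dor_dataset`.
#' @param path output path.
#' @export
write_dor_csv <- function(dataset, path) {
  out <- data.frame(participant = dataset$participant,
                    chord1 = dataset$c1 + 1L, chord2 = dataset$c2 + 1L,
                    chord3 = dataset$c3 + 1L, chord4 = dataset$c4 + 1L,
                    rating = dataset$rating)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
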