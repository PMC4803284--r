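# Pre-modelling behavioral statistics on participant-averaged DORs.

.test_result <- function(statistic, df, p, test_name) {
  structure(list(statistic = unname(statistic), df = as.integer(unname(df)),
                 p = unname(p), test_name = test_name),
            class = "ce_test")
}

#' @export
print.ce_test <- function(x, ...) {
  cat(sprintf("%s: chi^2(%d) = %.4g, p = %.4g\n",
              x$test_name, x$df, x$statistic, x$p))
  invisible(x)
}

#' Participant-averaged DORs per stimulus pattern
#'
#' Averages ratings across participants for each distinct stimulus pattern
#' of one condition. Two-chord patterns are keyed by the ordered root pair;
#' three- and four-chord patterns by their sequential interval tuple (the
#' design randomises initial roots, so intervals are the stimulus identity).
#'
#' @param dataset a `dor_dataset`.
#' @param condition 2, 3 or 4.
#' @return a data frame of class `context_mean_table` with the key columns
#'   (`c1`,`c2` for condition 2; `i1`,`i2`(,`i3`) otherwise) and `mean`.
#' @export
average_dors <- function(dataset, condition) {
  stopifnot(condition %in% 2:4)
  d <- dataset[dataset$condition == condition, , drop = FALSE]
  if (nrow(d) == 0) stop("no trials for condition ", condition, call. = FALSE)
  if (condition == 2) {
    key <- data.frame(c1 = d$c1, c2 = d$c2)
  } else if (condition == 3) {
    key <- data.frame(i1 = chord_interval(d$c1, d$c2),
                      i2 = chord_interval(d$c2, d$c3))
  } else {
    key <- data.frame(i1 = chord_interval(d$c1, d$c2),
                      i2 = chord_interval(d$c2, d$c3),
                      i3 = chord_interval(d$c3, d$c4))
  }
  agg <- aggregate(d$rating, by = key, FUN = mean)
  names(agg)[ncol(agg)] <- "mean"
  agg <- agg[do.call(order, agg[, seq_len(ncol(agg) - 1L), drop = FALSE]), ]
  rownames(agg) <- NULL
  attr(agg, "condition") <- condition
  class(agg) <- c("context_mean_table", "data.frame")
  agg
}

.require_complete <- function(found, expected, what) {
  missing <- setdiff(expected, found)
  if (length(missing)) {
    stop("incomplete design; missing ", what, ": ",
         paste(head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "", call. = FALSE)
  }
}

#' Kruskal-Wallis test of a 2-chord design factor
#'
#' Tests the averaged 2-chord DORs for an effect of one of the three design
#' factors: the interval between the roots, the first chord's pitch, or the
#' second chord's pitch. Each factor partitions the complete 12 x 12 design
#' into 12 groups of 12 means; the tie-corrected H statistic is referred to
#' a chi-square distribution with 11 degrees of freedom.
#'
#' @param table a condition-2 `context_mean_table` (144 rows).
#' @param factor `"interval"`, `"first_pitch"` or `"second_pitch"`.
#' @return a `ce_test`.
#' @export
kruskal_wallis_by_factor <- function(table,
                                     factor = c("interval", "first_pitch",
                                                "second_pitch")) {
  factor <- match.arg(factor)
  if (is.null(attr(table, "condition")) || attr(table, "condition") != 2) {
    stop("a condition-2 table is required", call. = FALSE)
  }
  .require_complete(paste(table$c1, table$c2),
                    paste(rep(0:11, each = 12), rep(0:11, 12)), "root pairs")
  g <- switch(factor,
              interval = chord_interval(table$c1, table$c2),
              first_pitch = table$c1,
              second_pitch = table$c2)
  kt <- kruskal.test(table$mean, g = base::factor(g, levels = 0:11))
  .test_result(kt$statistic, kt$parameter, kt$p.value,
               paste0("Kruskal-Wallis (", factor, ")"))
}

.grid_3chord <- function(table) {
  if (is.null(attr(table, "condition")) || attr(table, "condition") != 3) {
    stop("a condition-3 table is required", call. = FALSE)
  }
  .require_complete(paste(table$i1, table$i2),
                    paste(rep(0:11, each = 12), rep(0:11, 12)),
                    "interval pairs")
  m <- matrix(NA_real_, 12, 12, dimnames = list(i1 = 0:11, i2 = 0:11))
  m[cbind(table$i1 + 1L, table$i2 + 1L)] <- table$mean
  m
}

#' Friedman test of a 3-chord interval effect
#'
#' Arranges the averaged 3-chord DORs as a complete 12 x 12 block design and
#' tests one interval factor with the other as blocks:
#' * `interval_from_second`: treatments are the final-interval levels
#'   (second to third chord), blocks the first-interval levels;
#' * `interval_from_first`: treatments are the levels of the interval from
#'   the first to the third chord, blocks the final-interval levels.
#'
#' @param table a condition-3 `context_mean_table` (144 rows).
#' @param treatment which interval effect to test.
#' @return a `ce_test` with 11 degrees of freedom.
#' @export
friedman_by_interval <- function(table,
                                 treatment = c("interval_from_second",
                                               "interval_from_first")) {
  treatment <- match.arg(treatment)
  m <- .grid_3chord(table)
  if (treatment == "interval_from_second") {
    y <- m  # rows (blocks) = i1, columns (treatments) = i2
  } else {
    # re-key cells by (interval c1 -> c3, interval c2 -> c3)
    y <- matrix(NA_real_, 12, 12, dimnames = list(i2 = 0:11, i13 = 0:11))
    for (a in 0:11) for (b in 0:11) {
      y[b + 1L, (a + b) %% 12L + 1L] <- m[a + 1L, b + 1L]
    }
  }
  ft <- friedman.test(y)
  if (!is.finite(ft$statistic)) {
    stop("tie-degenerate design: no variation across treatments within blocks",
         call. = FALSE)
  }
  .test_result(ft$statistic, ft$parameter, ft$p.value,
               paste0("Friedman (", treatment, ")"))
}

#' Interval-profile vectors of the shared intervals
#'
#' For each of the six preceding-chord positions (Cm-Cn: the m-th chord
#' against the final n-th chord), the mean DOR over all trials whose
#' interval from that chord to the final chord is a major 2nd, perfect 4th,
#' perfect 5th or minor 7th (2, 5, 7, 10 semitones) -- the four intervals
#' common to all three conditions.
#'
#' @param dataset a `dor_dataset` covering conditions 2, 3 and 4.
#' @return a 6 x 4 matrix, rows `C1-C2`, `C1-C3`, `C2-C3`, `C1-C4`,
#'   `C2-C4`, `C3-C4`, columns the four intervals.
#' @export
interval_profile_vectors <- function(dataset) {
  shared <- c(2L, 5L, 7L, 10L)
  specs <- list(`C1-C2` = c(2L, 1L), `C1-C3` = c(3L, 1L), `C2-C3` = c(3L, 2L),
                `C1-C4` = c(4L, 1L), `C2-C4` = c(4L, 2L), `C3-C4` = c(4L, 3L))
  out <- matrix(NA_real_, 6L, 4L,
                dimnames = list(names(specs), paste0(shared, "st")))
  colnames(out) <- c("M2", "P4", "P5", "m7")
  cols <- as.matrix(dataset[, c("c1", "c2", "c3", "c4")])
  final <- cols[cbind(seq_len(nrow(dataset)), dataset$condition)]
  for (s in seq_along(specs)) {
    cond <- specs[[s]][1]
    pos <- specs[[s]][2]
    in_cond <- dataset$condition == cond
    iv <- (final - cols[, pos]) %% 12L
    for (k in seq_along(shared)) {
      sel <- in_cond & iv == shared[k]
      if (!any(sel)) {
        stop(sprintf("no trials for cell %s at interval %d",
                     names(specs)[s], shared[k]), call. = FALSE)
      }
      out[s, k] <- mean(dataset$rating[sel])
    }
  }
  out
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal's non-metric MDS (stress-1, monotone regression), run from a
#' metric-scaling start plus `nstarts` random configurations, keeping the
#' lowest-stress solution.
#'
#' @param D symmetric distance matrix (or `dist`) with zero diagonal.
#' @param dims embedding dimension.
#' @param nstarts number of additional random starts.
#' @param seed seed for the random starts.
#' @return a list with `coordinates` (n x dims) and `stress` (in `[0, 1]`).
#' @export
nonmetric_mds <- function(D, dims = 2L, nstarts = 50L, seed = 1L) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D)) || any(abs(diag(D)) > 1e-12)) {
    stop("D must be symmetric with zero diagonal", call. = FALSE)
  }
  d <- as.dist(D)
  n <- nrow(D)
  set.seed(as.integer(seed))
  best <- vegan::monoMDS(d, k = dims)
  for (i in seq_len(nstarts)) {
    y0 <- matrix(rnorm(n * dims), n, dims)
    cand <- vegan::monoMDS(d, y = y0, k = dims)
    if (cand$stress < best$stress) best <- cand
  }
  pts <- best$points
  rownames(pts) <- rownames(D)
  list(coordinates = pts, stress = best$stress)
}

#' Complete-linkage hierarchical clustering
#'
#' Standard agglomerative clustering where the distance between clusters is
#' the maximum pairwise distance, so merge heights are monotone
#' non-decreasing.
#'
#' @param D symmetric distance matrix (or `dist`).
#' @return an `hclust` object (merge history, heights, labels).
#' @export
complete_link_clustering <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) < 2) stop("need at least 2 items", call. = FALSE)
  if (!isSymmetric(unname(D))) stop("D must be symmetric", call. = FALSE)
  hclust(as.dist(D), method = "complete")
}

#' Context gain of the three-chord condition
#'
#' Measures what the first chord adds beyond the final transition: from each
#' averaged 3-chord DOR (keyed by the interval from the first to the third
#' chord and the final interval), the averaged 2-chord DOR with the same
#' final interval is subtracted. The resulting 12 x 12 gain grid is tested
#' for an effect of the first-to-third interval by a Friedman test
#' (treatments = first-to-third interval levels, blocks = final-interval
#' levels), followed by Nemenyi-style pairwise mean-rank comparisons with
#' Bonferroni correction over the 66 pairs.
#'
#' @param dataset a `dor_dataset` with complete 2- and 3-chord designs.
#' @param alpha family-wise error level for the post-hoc flags.
#' @return a list: `gain` (12 x 12 matrix, rows = interval c1 to c3, columns
#'   = interval c2 to c3), `test` (`ce_test`), `posthoc` (data frame of the
#'   66 pairwise contrasts with z, p and a Bonferroni flag), and
#'   `bonferroni_threshold` (`alpha / 66`).
#' @export
context_gain_analysis <- function(dataset, alpha = 0.05) {
  two <- average_dors(dataset, 2L)
  .require_complete(paste(two$c1, two$c2),
                    paste(rep(0:11, each = 12), rep(0:11, 12)), "root pairs")
  iv2 <- chord_interval(two$c1, two$c2)
  two_by_interval <- vapply(0:11, function(k) mean(two$mean[iv2 == k]), 1.0)
  m3 <- .grid_3chord(average_dors(dataset, 3L))
  gain <- matrix(NA_real_, 12, 12, dimnames = list(i13 = 0:11, i23 = 0:11))
  for (a in 0:11) for (b in 0:11) {
    # cell (i1 = (a - b) mod 12, i2 = b) has first-to-third interval a
    gain[a + 1L, b + 1L] <- m3[(a - b) %% 12L + 1L, b + 1L] -
      two_by_interval[b + 1L]
  }
  y <- t(gain)  # blocks (rows) = final interval, treatments = i13
  ft <- friedman.test(y)
  test <- if (is.finite(ft$statistic)) {
    .test_result(ft$statistic, ft$parameter, ft$p.value,
                 "Friedman (context gain, interval c1->c3)")
  } else {  # all within-block ties (e.g. an identically zero gain grid)
    .test_result(0, 11L, 1, "Friedman (context gain, interval c1->c3) [all ties]")
  }
  # Nemenyi-style mean-rank contrasts after Friedman
  ranks <- t(apply(y, 1L, rank))
  rbar <- colMeans(ranks)
  k <- 12L
  n <- 12L
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2L)
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
  p <- 2 * pnorm(-abs(z))
  posthoc <- data.frame(interval_a = pairs[1, ] - 1L,
                        interval_b = pairs[2, ] - 1L,
                        mean_rank_a = rbar[pairs[1, ]],
                        mean_rank_b = rbar[pairs[2, ]],
                        z = z, p = p,
                        significant = p < alpha / ncol(pairs))
  rownames(posthoc) <- NULL
  list(gain = gain, test = test, posthoc = posthoc,
       bonferroni_threshold = alpha / ncol(pairs))
}
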