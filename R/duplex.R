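#' Duplex train/test partitioning
#'
#' Deterministic pairwise max-distance selection of an external test set.
#' Rounds alternate between the two sets, training set first: each round
#' assigns the pair of still-unassigned samples with the largest Euclidean
#' distance (in the provided, untreated spectral space) to the round's set,
#' until the test set holds `n_test` samples. When `n_test` is odd, the final
#' test round contributes a single sample: the member of the winning pair
#' that lies farther (larger mean distance) from the remaining unassigned
#' samples. After the test set is complete, every unassigned sample joins
#' the training set. Exact distance ties are broken towards the
#' lexicographically smallest sample-id pair, so the partition is a
#' deterministic function of the data and `n_test`.
#'
#' @param x a `spectra_set` (or numeric matrix with rownames as ids), usually
#'   the fingerprint-region spectra without pre-treatment.
#' @param n_test requested test-set size (>= 2); default `round(0.2 * n)`.
#' @return a `split_result` with `train_ids`, `test_ids`.
#' @export
duplex_split <- function(x, n_test = round(0.2 * nrow(as_abs_matrix(x)))) {
  m <- as_abs_matrix(x)
  ids <- if (inherits(x, "spectra_set")) x$sample_ids else rownames(m)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(m)))
  n <- nrow(m)
  n_test <- as.integer(n_test)
  if (n < 4L) stop("Duplex needs at least 4 samples")
  if (n_test < 2L) stop("n_test must be >= 2")
  if (n < n_test + 2L) stop("need n_samples >= n_test + 2")

  D <- as.matrix(stats::dist(m))
  remaining <- seq_len(n)
  train <- integer(0); test <- integer(0)
  turn_train <- TRUE

  # pair among `rem` with max distance; ties -> smallest sorted id pair
  best_pair <- function(rem) {
    sub <- D[rem, rem, drop = FALSE]
    mx <- max(sub[upper.tri(sub)])
    hits <- which(sub >= mx - 0 & upper.tri(sub), arr.ind = TRUE)
    hits <- hits[sub[hits] == mx, , drop = FALSE]
    cand <- cbind(rem[hits[, 1L]], rem[hits[, 2L]])
    key <- apply(cand, 1L, function(p) {
      s <- sort(ids[p]); paste(s[1L], s[2L], sep = "\r")
    })
    cand[order(key)[1L], ]
  }

  while (length(test) < n_test) {
    need <- n_test - length(test)
    if (!turn_train && length(remaining) <= need) {
      test <- c(test, remaining); remaining <- integer(0); break
    }
    if (length(remaining) < 2L) { train <- c(train, remaining); remaining <- integer(0); break }
    pr <- best_pair(remaining)
    if (turn_train) {
      train <- c(train, pr)
      remaining <- setdiff(remaining, pr)
    } else if (need >= 2L) {
      test <- c(test, pr)
      remaining <- setdiff(remaining, pr)
    } else {
      # odd n_test: keep the member farther from the rest of the data
      others <- setdiff(remaining, pr)
      score <- if (length(others))
        c(mean(D[pr[1L], others]), mean(D[pr[2L], others]))
      else c(D[pr[1L], pr[2L]], D[pr[1L], pr[2L]])
      pick <- if (score[2L] > score[1L]) pr[2L] else
        if (score[1L] > score[2L]) pr[1L] else pr[order(ids[pr])[1L]]
      test <- c(test, pick)
      remaining <- setdiff(remaining, pick)
    }
    turn_train <- !turn_train
  }
  train <- c(train, remaining)
  structure(list(train_ids = ids[sort(train)], test_ids = ids[sort(test)],
                 n_test = n_test),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("split_result: ", length(x$train_ids), " train / ",
      length(x$test_ids), " test samples\n", sep = "")
  invisible(x)
}

#' Verify class-ratio and purity coverage of a split
#'
#' For each compound, compares the positive fraction in the test set with the
#' full set and flags absolute differences above `tolerance`; also reports
#' whether the test set covers the purity range of the full set (relevant for
#' the purity regression).
#'
#' @param split a `split_result`.
#' @param labels a `sample_table` covering every id in the split.
#' @param tolerance absolute positive-fraction difference above which a
#'   compound is flagged (default 0.15).
#' @return a `ratio_report` data.frame (one row per compound, columns
#'   `n_test_pos`, `n_test_neg`, `frac_test`, `frac_full`, `difference`,
#'   `flagged`) with a `purity_coverage` attribute
#'   (`min/max` purity in test vs full set).
#' @export
verify_split <- function(split, labels, tolerance = 0.15) {
  stopifnot(inherits(split, "split_result"), inherits(labels, "sample_table"))
  all_ids <- c(split$train_ids, split$test_ids)
  missing <- setdiff(all_ids, labels$sample_id)
  if (length(missing))
    stop("labels do not cover id(s): ", paste(missing, collapse = ", "))
  lab_test <- labels[match(split$test_ids, labels$sample_id), ]
  lab_full <- labels[match(all_ids, labels$sample_id), ]
  rows <- lapply(compound_names(), function(nm) {
    ft <- mean(lab_test[[nm]]); ff <- mean(lab_full[[nm]])
    data.frame(compound = nm,
               n_test_pos = sum(lab_test[[nm]]),
               n_test_neg = sum(!lab_test[[nm]]),
               frac_test = ft, frac_full = ff,
               difference = ft - ff,
               flagged = abs(ft - ff) > tolerance)
  })
  out <- do.call(rbind, rows)
  attr(out, "purity_coverage") <- list(
    test = range(lab_test$purity), full = range(lab_full$purity))
  attr(out, "tolerance") <- tolerance
  class(out) <- c("ratio_report", "data.frame")
  out
}
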