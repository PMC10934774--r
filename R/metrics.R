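#' Confusion-matrix metrics for a binary classifier
#'
#' Computes exact integer confusion counts and the derived rates as
#' percentages: correct classification rate `ccr = 100 (TP + TN) / n`,
#' `sensitivity = 100 TP / (TP + FN)`, `specificity = 100 TN / (TN + FP)`,
#' `precision = 100 TP / (TP + FP)`. A rate with a zero denominator is
#' undefined and reported as `NA`, never as 0 or 100.
#'
#' @param truth,predicted equal-length binary vectors (logical, 0/1 or a
#'   shared two-level factor; the second level / `TRUE` / `1` is positive).
#' @return a `class_metrics` list: `tp`, `tn`, `fp`, `fn`, `n`, `ccr`,
#'   `sensitivity`, `specificity`, `precision` (full precision; round to two
#'   decimals for reporting).
#' @export
classification_metrics <- function(truth, predicted) {
  as_bin <- function(v, what) {
    if (is.logical(v)) return(v)
    if (is.factor(v)) {
      if (nlevels(v) != 2L) stop(what, " must be binary")
      return(v == levels(v)[2L])
    }
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1))) stop(what, " must be binary (0/1)")
      return(v == 1)
    }
    stop(what, " must be logical, 0/1 or a two-level factor")
  }
  truth <- as_bin(truth, "truth"); predicted <- as_bin(predicted, "predicted")
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  tp <- sum(truth & predicted); tn <- sum(!truth & !predicted)
  fp <- sum(!truth & predicted); fn <- sum(truth & !predicted)
  n <- length(truth)
  rate <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
                 ccr = rate(tp + tn, n),
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 precision = rate(tp, tp + fp)),
            class = "class_metrics")
}

#' Metrics from stated confusion counts
#'
#' Same arithmetic as [classification_metrics()] but starting from the
#' class sizes and error counts directly (as published reports state them).
#'
#' @param n_pos,n_neg true positive/negative class sizes.
#' @param fp,fn false positive/negative counts.
#' @return a `class_metrics` object.
#' @export
metrics_from_counts <- function(n_pos, n_neg, fp, fn) {
  if (fn > n_pos || fp > n_neg) stop("error counts exceed class sizes")
  truth <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  pred <- c(rep(TRUE, n_pos - fn), rep(FALSE, fn),
            rep(TRUE, fp), rep(FALSE, n_neg - fp))
  classification_metrics(truth, pred)
}

#' @export
print.class_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  cat("n = ", x$n, "  TP ", x$tp, " TN ", x$tn, " FP ", x$fp, " FN ", x$fn,
      "\nccr ", fmt(x$ccr), "  sensitivity ", fmt(x$sensitivity),
      "  specificity ", fmt(x$specificity),
      "  precision ", fmt(x$precision), "\n", sep = "")
  invisible(x)
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Calibration / cross-validation / prediction report for a regression model
#'
#' Root mean squared errors (RMSEC on the training fit, RMSECV from the
#' supplied cross-validation, RMSEP on the external test set) and the
#' corresponding determination coefficients, all on the response scale
#' (purity fraction), plus true-vs-predicted pairs for correlation plots.
#'
#' @param model a fitted regression `pls_model`.
#' @param x_train,y_train the training spectra and response.
#' @param x_test,y_test the external test set (optional; `NULL` omits the
#'   prediction leg).
#' @param cv a `cv_result` for the training set (optional), evaluated at the
#'   model's factor count.
#' @return a `model_report` list: `rmsec`, `rmsecv`, `rmsep`, `r2_cal`,
#'   `r2_cv`, `r2_test`, `n_factors`, `correlation_data` (data.frame with
#'   columns `set`, `observed`, `predicted`).
#' @export
regression_report <- function(model, x_train, y_train,
                              x_test = NULL, y_test = NULL, cv = NULL) {
  stopifnot(inherits(model, "pls_model"))
  y_train <- as.numeric(y_train)
  fit <- predict(model, x_train)
  out <- list(n_factors = model$n_factors,
              rmsec = sqrt(mean((fit - y_train)^2)),
              r2_cal = r_squared(y_train, fit),
              rmsecv = NA_real_, r2_cv = NA_real_,
              rmsep = NA_real_, r2_test = NA_real_)
  cd <- data.frame(set = "calibration", observed = y_train, predicted = fit)
  if (!is.null(cv)) {
    a <- min(model$n_factors, ncol(cv$cv_predictions))
    pcv <- cv$cv_predictions[, max(a, 1L)]
    out$rmsecv <- sqrt(mean((pcv - y_train)^2))
    out$r2_cv <- r_squared(y_train, pcv)
    cd <- rbind(cd, data.frame(set = "cv", observed = y_train,
                               predicted = pcv))
  }
  if (!is.null(x_test) && !is.null(y_test) && length(y_test)) {
    y_test <- as.numeric(y_test)
    pte <- predict(model, x_test)
    out$rmsep <- sqrt(mean((pte - y_test)^2))
    out$r2_test <- r_squared(y_test, pte)
    cd <- rbind(cd, data.frame(set = "test", observed = y_test,
                               predicted = pte))
  }
  out$correlation_data <- cd
  class(out) <- "model_report"
  out
}

#' @export
print.model_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.4f", v)
  cat("model_report (", x$n_factors, " factors)\n",
      "RMSEC ", fmt(x$rmsec), "  RMSECV ", fmt(x$rmsecv),
      "  RMSEP ", fmt(x$rmsep), "\n",
      "r2 cal ", fmt(x$r2_cal), "  cv ", fmt(x$r2_cv),
      "  test ", fmt(x$r2_test), "\n", sep = "")
  invisible(x)
}
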