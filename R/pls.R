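#' Partial least squares by NIPALS
#'
#' PLS1 with X- and y-deflation. Latent factors are linear combinations of
#' the wavenumber variables chosen to maximise covariance with the response;
#' the first factor captures the largest covariance, later factors the
#' remaining covariance after deflation. Used in two modes: `regression`
#' (response = heroin mass fraction in `[0, 1]`) and `discriminant`
#' (response = class coded 0/1, hard class by thresholding the continuous
#' prediction, default cut 0.5).
#'
#' @name pls
NULL

# Core NIPALS PLS1 on a centered matrix/centered response.
# Returns weights W (unit norm), x-loadings P, y-loadings q, scores T and
# the cumulative coefficient matrix B (column a = regression vector using
# the first a factors). Stops early if X'y vanishes (rank exhausted).
nipals_pls1 <- function(X, y, a_max) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, a_max); P <- matrix(0, p, a_max)
  Tm <- matrix(0, n, a_max); q <- numeric(a_max)
  a_eff <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(X, y)                       # p x 1
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(X, t) / tt
    qa <- sum(y * t) / tt
    X <- X - tcrossprod(t, pv)
    y <- y - t * qa
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    a_eff <- a
  }
  B <- matrix(0, p, a_max)
  if (a_eff > 0L) {
    for (a in seq_len(a_eff)) {
      Wa <- W[, seq_len(a), drop = FALSE]
      Pa <- P[, seq_len(a), drop = FALSE]
      # P'W is unit upper triangular in NIPALS; small a, direct solve
      B[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
    }
    if (a_eff < a_max)                         # rank exhausted: coefs plateau
      for (a in (a_eff + 1L):a_max) B[, a] <- B[, a_eff]
  }
  list(W = W[, seq_len(max(a_eff, 1L)), drop = FALSE],
       P = P[, seq_len(max(a_eff, 1L)), drop = FALSE],
       T = Tm[, seq_len(max(a_eff, 1L)), drop = FALSE],
       q = q[seq_len(max(a_eff, 1L))], B = B, a_eff = a_eff)
}

coerce_response <- function(y, mode) {
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("discriminant response must be binary")
    y <- as.numeric(y) - 1
  }
  y <- as.numeric(y)
  if (anyNA(y)) stop("response contains missing values")
  if (mode == "discriminant") {
    if (!all(y %in% c(0, 1))) stop("discriminant response must be coded 0/1")
    if (length(unique(y)) < 2L)
      stop("discriminant response contains a single class")
  }
  if (stats::sd(y) == 0) stop("response has zero variance")
  y
}

#' Fit a PLS or PLS-DA model
#'
#' The pre-treatment (if any) is fitted on the training spectra; the
#' pre-treated matrix is column mean-centered (`center_x`, default on — PLS
#' on uncentered data is unusual) and the response mean-centered using the
#' training mean, which predictions add back.
#'
#' @param x training spectra (`spectra_set` or matrix).
#' @param y response: numeric purity fraction (regression) or 0/1, logical
#'   or two-level factor (discriminant).
#' @param n_factors number of latent factors (>= 0; 0 gives the
#'   constant-mean model).
#' @param preprocess method name, fitted `pretreat_state`, or `NULL`.
#' @param mode `"regression"` or `"discriminant"`.
#' @param class_threshold decision cut on the continuous score
#'   (discriminant mode), default 0.5.
#' @param center_x center the pre-treated matrix (default `TRUE`).
#' @return a `pls_model` with weights `W`, x-loadings `P`, y-loadings `q`,
#'   scores `T`, coefficient matrix `coefs` (column `a` = regression vector
#'   at `a` factors), regression vector `b = coefs[, n_factors]`, centers
#'   and pre-treatment state.
#' @export
fit_pls <- function(x, y, n_factors,
                    preprocess = NULL,
                    mode = c("regression", "discriminant"),
                    class_threshold = 0.5, center_x = TRUE) {
  mode <- match.arg(mode)
  y <- coerce_response(y, mode)
  m_raw <- as_abs_matrix(x)
  if (length(y) != nrow(m_raw)) stop("length(y) must equal nrow(x)")
  n_factors <- as.integer(n_factors)
  if (n_factors < 0L) stop("n_factors must be >= 0")
  state <- if (is.null(preprocess)) NULL
    else if (inherits(preprocess, "pretreat_state")) preprocess
    else preprocess_fit(preprocess, x)
  m <- if (is.null(state)) m_raw else as_abs_matrix(preprocess_apply(state, x))
  rank_bound <- min(nrow(m) - as.integer(center_x), ncol(m))
  if (n_factors > rank_bound)
    stop("n_factors (", n_factors, ") exceeds the rank bound (", rank_bound, ")")
  x_center <- if (center_x) colMeans(m) else rep(0, ncol(m))
  y_center <- mean(y)
  Xc <- sweep(m, 2L, x_center)
  fit <- nipals_pls1(Xc, y - y_center, max(n_factors, 1L))
  b <- if (n_factors == 0L) rep(0, ncol(m)) else fit$B[, n_factors]
  structure(list(mode = mode, n_factors = n_factors,
                 W = fit$W, P = fit$P, q = fit$q, T = fit$T,
                 coefs = fit$B, b = b, a_eff = fit$a_eff,
                 x_center = x_center, y_center = y_center,
                 preprocess = state, class_threshold = class_threshold,
                 wavenumbers = if (inherits(x, "spectra_set")) x$wavenumbers,
                 fitted = drop(Xc %*% b) + y_center),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model (", x$mode, "): ", x$n_factors, " factors, ",
      length(x$b), " variables",
      if (!is.null(x$preprocess)) paste0(", pre-treatment ",
                                         x$preprocess$method), "\n", sep = "")
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata spectra on the training axis.
#' @param n_factors override the factor count (<= fitted `a_eff`).
#' @param type `"response"` (continuous) or `"class"` (discriminant mode:
#'   logical, prediction above the class threshold).
#' @param clip clip regression predictions into `[0, 1]` (off by default).
#' @param ... unused.
#' @return numeric vector (or logical for `type = "class"`).
#' @export
predict.pls_model <- function(object, newdata, n_factors = object$n_factors,
                              type = c("response", "class"), clip = FALSE,
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "spectra_set") && !is.null(object$wavenumbers)) {
    if (length(newdata$wavenumbers) != length(object$wavenumbers) ||
        max(abs(newdata$wavenumbers - object$wavenumbers)) > 1e-8)
      stop("wavenumber axis does not match the training axis")
  }
  m <- if (is.null(object$preprocess)) as_abs_matrix(newdata)
    else as_abs_matrix(preprocess_apply(object$preprocess, newdata))
  b <- if (n_factors == object$n_factors) object$b
    else if (n_factors == 0L) rep(0, ncol(m))
    else object$coefs[, n_factors]
  pred <- drop(sweep(m, 2L, object$x_center) %*% b) + object$y_center
  if (clip && object$mode == "regression") pred <- pmin(pmax(pred, 0), 1)
  if (type == "class") {
    if (object$mode != "discriminant")
      stop("type = 'class' requires a discriminant model")
    pred > object$class_threshold
  } else pred
}

make_folds <- function(y, folds, stratify, seed = NULL) {
  n <- length(y)
  if (!is.null(seed)) set.seed(seed)
  assign <- integer(n)
  if (stratify) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    assign[sample.int(n)] <- rep_len(seq_len(folds), n)
  }
  assign
}

#' 10-fold cross-validation of a PLS model over factor counts
#'
#' Per held-out fold, the pre-treatment and the PLS model are re-fitted on
#' the remaining folds only (no leakage) and the held-out samples predicted
#' at every factor count `1..a_max`. RMSECV(A) is the root mean squared
#' held-out error pooled over all samples. Factor selection: regression —
#' the smallest A whose RMSECV is within 2% (relative) of the minimum;
#' discriminant — the A with the highest cross-validated correct
#' classification rate, ties broken by smaller RMSECV then smaller A.
#'
#' @inheritParams fit_pls
#' @param a_max largest factor count to evaluate (default 15).
#' @param folds number of folds (default 10). Fold assignment is random
#'   (stratified by class in discriminant mode so every training part keeps
#'   both classes) and recorded in the result.
#' @param seed RNG seed for the fold assignment (recorded).
#' @param selection `"auto"` (mode-dependent rule above), `"rmsecv"` or
#'   `"ccr"`.
#' @return a `cv_result`: `rmsecv_by_factor`, `ccr_by_factor` (discriminant),
#'   `chosen_factors`, `fold_assignment`, `cv_predictions` (matrix sample x
#'   factor), `seed`.
#' @export
cross_validate <- function(x, y, a_max = 15L,
                           preprocess = NULL,
                           mode = c("regression", "discriminant"),
                           folds = 10L, seed = NULL,
                           class_threshold = 0.5,
                           selection = c("auto", "rmsecv", "ccr")) {
  mode <- match.arg(mode)
  selection <- match.arg(selection)
  y <- coerce_response(y, mode)
  m_raw <- as_abs_matrix(x)
  n <- nrow(m_raw)
  if (n < folds) stop("need at least as many samples as folds")
  a_max <- as.integer(a_max)
  if (a_max < 1L) stop("a_max must be >= 1")

  method <- if (is.null(preprocess)) NULL
    else if (inherits(preprocess, "pretreat_state")) preprocess$method
    else preprocess
  # snv / savgol are per-spectrum with no fitted state: transforming the
  # full matrix once equals per-fold refitting and is much cheaper
  stateless <- !is.null(method) &&
    method %in% c("snv", "savgol_2nd_derivative", "derivative")
  m_pre <- if (stateless)
    as_abs_matrix(preprocess_apply(preprocess_fit(method, x), x))
  else m_raw

  assign <- make_folds(y, folds, stratify = mode == "discriminant", seed)
  preds <- matrix(NA_real_, n, a_max)
  for (f in seq_len(folds)) {
    hold <- which(assign == f)
    keep <- which(assign != f)
    if (!length(hold)) next
    if (mode == "discriminant" && length(unique(y[keep])) < 2L)
      stop("a cross-validation training part lost a class; reduce folds")
    if (stateless || is.null(method)) {
      Xtr <- m_pre[keep, , drop = FALSE]; Xte <- m_pre[hold, , drop = FALSE]
    } else {
      st <- preprocess_fit(method, m_raw[keep, , drop = FALSE])
      Xtr <- preprocess_apply(st, m_raw[keep, , drop = FALSE])
      Xte <- preprocess_apply(st, m_raw[hold, , drop = FALSE])
    }
    xc <- colMeans(Xtr); yc <- mean(y[keep])
    a_fold <- min(a_max, length(keep) - 1L, ncol(Xtr))
    fit <- nipals_pls1(sweep(Xtr, 2L, xc), y[keep] - yc, a_fold)
    Pm <- sweep(Xte, 2L, xc) %*% fit$B + yc
    if (a_fold < a_max)
      Pm <- cbind(Pm, Pm[, rep(a_fold, a_max - a_fold), drop = FALSE])
    preds[hold, ] <- Pm
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  ccr <- if (mode == "discriminant")
    colMeans((preds > class_threshold) == (y > 0.5)) * 100 else NULL

  rule <- if (selection == "auto")
    if (mode == "discriminant") "ccr" else "rmsecv" else selection
  chosen <- if (rule == "rmsecv") {
    min(which(rmsecv <= min(rmsecv) * 1.02))
  } else {
    best <- which(ccr == max(ccr))
    best[order(rmsecv[best], best)][1L]
  }
  structure(list(rmsecv_by_factor = rmsecv, ccr_by_factor = ccr,
                 chosen_factors = as.integer(chosen),
                 fold_assignment = assign, cv_predictions = preds,
                 folds = folds, seed = seed, mode = mode),
            class = "cv_result")
}

#' Grid search over pre-treatments and factor counts
#'
#' Exhaustive cross-validated evaluation of every (pre-treatment, factor
#' count) pair. Best configuration: lowest RMSECV (regression) or highest
#' cross-validated ccr with RMSECV tie-break (discriminant).
#'
#' @inheritParams cross_validate
#' @param pretreatments subset of [pretreatment_methods()] (default all
#'   four).
#' @return a `grid_result`: `table` (data.frame method x factors with
#'   `rmsecv` and, for discriminant, `ccr_cv`), `best_method`,
#'   `best_factors`, `cv` (the winning `cv_result`).
#' @export
pls_grid_search <- function(x, y, pretreatments = pretreatment_methods(),
                            a_max = 15L,
                            mode = c("regression", "discriminant"),
                            folds = 10L, seed = NULL,
                            class_threshold = 0.5) {
  mode <- match.arg(mode)
  bad <- setdiff(pretreatments, pretreatment_methods())
  if (length(bad)) stop("unknown pre-treatment(s): ", paste(bad, collapse = ", "))
  rows <- list(); cvs <- list()
  for (pm in pretreatments) {
    cv <- cross_validate(x, y, a_max = a_max, preprocess = pm, mode = mode,
                         folds = folds, seed = seed,
                         class_threshold = class_threshold)
    cvs[[pm]] <- cv
    rows[[pm]] <- data.frame(
      method = pm, n_factors = seq_len(a_max),
      rmsecv = cv$rmsecv_by_factor,
      ccr_cv = if (is.null(cv$ccr_by_factor)) NA_real_ else cv$ccr_by_factor)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (mode == "regression") {
    best_row <- tab[order(tab$rmsecv, tab$n_factors), ][1L, ]
  } else {
    best_row <- tab[order(-tab$ccr_cv, tab$rmsecv, tab$n_factors), ][1L, ]
  }
  structure(list(table = tab,
                 best_method = best_row$method,
                 best_factors = as.integer(best_row$n_factors),
                 cv = cvs[[best_row$method]]),
            class = "grid_result")
}
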