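#' Permutation test against model overfitting
#'
#' Tests whether a selected PLS(-DA) configuration genuinely relates the
#' spectra to the response or merely overfits: the response is randomly
#' shuffled `n_permutations` times, the full model configuration
#' (pre-treatment + factor count) is re-fitted per shuffle, and the
#' unpermuted model's absolute residuals are compared with each permuted
#' model's, paired by sample — both on self-prediction residuals and on
#' 10-fold cross-validated residuals. Each model's residuals are measured
#' against the response it was trained on, so under the null hypothesis the
#' unpermuted model is exchangeable with the shuffled ones. Three paired statistics are used per
#' comparison: the Wilcoxon signed-rank statistic, the sign statistic and
#' the paired t statistic (used only through its permutation-derived null,
#' never the parametric t distribution).
#'
#' Two aggregations are available. The default (`"per_permutation"`) counts,
#' for each statistic, the permutations whose paired comparison fails to
#' show the original residuals are smaller and reports
#' `(1 + #not beaten) / (n_permutations + 1)` — exactly valid under
#' exchangeability of the original with the shuffles, at the price of a
#' discrete p-value grid (the smallest attainable p is
#' `1 / (n_permutations + 1)`). The alternative (`"pooled"`) averages each
#' sample's residual over all permuted models and runs one paired test of
#' the original against that average (Wilcoxon signed-rank, sign test, and a
#' sign-flip randomization t-test); it is more powerful but only
#' approximately calibrated, because the pooled differences share the
#' original model's fit. Small p-values (< 0.05) mean the real model
#' outperforms essentially all shuffled ones — a low risk of overfitting.
#'
#' @param x spectra (`spectra_set` or matrix).
#' @param y response (coding as in [fit_pls()]).
#' @param n_factors,preprocess,mode the model configuration under test.
#' @param n_permutations number of response shuffles (>= 20; default 50).
#' @param folds cross-validation folds (default 10). Folds are re-drawn per
#'   permutation from a seed derived as `seed + permutation index`.
#' @param seed RNG seed for shuffles and fold draws.
#' @param aggregate `"per_permutation"` (default, exact) or `"pooled"` (more
#'   powerful, approximate); see Details.
#' @return a `permutation_report`: p-values `p_wilcoxon_self`, `p_sign_self`,
#'   `p_randt_self`, `p_wilcoxon_cv`, `p_sign_cv`, `p_randt_cv`;
#'   `ssqy_points` data.frame (`y_block_correlation`, `ssqy_self`,
#'   `ssqy_cv`; first row = unpermuted reference with correlation 1);
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(x, y, n_factors, preprocess = NULL,
                             mode = c("regression", "discriminant"),
                             n_permutations = 50L, folds = 10L,
                             seed = NULL,
                             aggregate = c("per_permutation", "pooled")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  y <- coerce_response(y, mode)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 20L) stop("n_permutations must be >= 20")
  if (!is.null(seed)) set.seed(seed)
  base_seed <- if (is.null(seed)) sample.int(2^30, 1L) else as.integer(seed)

  m_raw <- as_abs_matrix(x)
  method <- if (is.null(preprocess)) NULL
    else if (inherits(preprocess, "pretreat_state")) preprocess$method
    else preprocess
  stateless <- !is.null(method) &&
    method %in% c("snv", "savgol_2nd_derivative", "derivative")
  m_pre <- if (stateless)
    as_abs_matrix(preprocess_apply(preprocess_fit(method, x), x))
  else m_raw
  eff_method <- if (stateless) NULL else method

  # Fit the configured model to a (possibly shuffled) training response and
  # return its self-prediction and 10-fold-CV absolute residuals, measured
  # against the response it was trained on. Under the null the original is
  # just another shuffle, so original-vs-permutation comparisons are
  # exchangeable and the reported p-values exactly valid; under the
  # alternative only responses correlated with the truth can be fitted from
  # the spectra, which is what makes the SSQY-vs-correlation diagnostic
  # fall towards the unpermuted point.
  self_cv_residuals <- function(yy, fold_seed) {
    # self-prediction
    st <- if (is.null(eff_method)) NULL else preprocess_fit(eff_method, m_pre)
    Xp <- if (is.null(st)) m_pre else as_abs_matrix(preprocess_apply(st, m_pre))
    xc <- colMeans(Xp); yc <- mean(yy)
    a <- min(n_factors, nrow(Xp) - 1L, ncol(Xp))
    fit <- nipals_pls1(sweep(Xp, 2L, xc), yy - yc, max(a, 1L))
    b <- if (a == 0L) rep(0, ncol(Xp)) else fit$B[, a]
    self_pred <- drop(sweep(Xp, 2L, xc) %*% b) + yc
    # 10-fold CV
    assign <- make_folds(yy, folds,
                         stratify = mode == "discriminant" &&
                           length(unique(yy)) == 2L,
                         seed = fold_seed)
    cv_pred <- numeric(length(yy))
    for (f in seq_len(folds)) {
      hold <- which(assign == f); keep <- which(assign != f)
      if (!length(hold)) next
      if (is.null(eff_method)) {
        Xtr <- m_pre[keep, , drop = FALSE]; Xte <- m_pre[hold, , drop = FALSE]
      } else {
        stf <- preprocess_fit(eff_method, m_pre[keep, , drop = FALSE])
        Xtr <- preprocess_apply(stf, m_pre[keep, , drop = FALSE])
        Xte <- preprocess_apply(stf, m_pre[hold, , drop = FALSE])
      }
      xcf <- colMeans(Xtr); ycf <- mean(yy[keep])
      af <- min(n_factors, length(keep) - 1L, ncol(Xtr))
      ff <- nipals_pls1(sweep(Xtr, 2L, xcf), yy[keep] - ycf, max(af, 1L))
      bf <- if (af == 0L) rep(0, ncol(Xtr)) else ff$B[, af]
      cv_pred[hold] <- drop(sweep(Xte, 2L, xcf) %*% bf) + ycf
    }
    list(self = abs(yy - self_pred), cv = abs(yy - cv_pred))
  }

  ref <- self_cv_residuals(y, fold_seed = base_seed)

  # direction of each paired statistic: does it favour the original
  # (original residuals smaller than the permuted model's)?
  favours <- function(r_orig, r_perm) {
    d <- r_perm - r_orig
    nz <- d[d != 0]
    wil <- if (!length(nz)) FALSE else {
      rk <- rank(abs(nz))
      sum(rk[nz > 0]) > sum(rk[nz < 0])
    }
    sgn <- sum(d > 0) > sum(d < 0)
    tst <- if (length(nz) < 2L || stats::sd(d) == 0) FALSE else mean(d) > 0
    c(wilcoxon = wil, sign = sgn, randt = tst)
  }

  not_beaten <- matrix(0L, 2L, 3L,
                       dimnames = list(c("self", "cv"),
                                       c("wilcoxon", "sign", "randt")))
  sum_self <- numeric(length(y)); sum_cv <- numeric(length(y))
  pts <- data.frame(y_block_correlation = 1,
                    ssqy_self = sum(ref$self^2), ssqy_cv = sum(ref$cv^2))
  for (k in seq_len(n_permutations)) {
    y_perm <- sample(y)
    res <- self_cv_residuals(y_perm, fold_seed = base_seed + k)
    fs <- favours(ref$self, res$self)
    fc <- favours(ref$cv, res$cv)
    not_beaten["self", ] <- not_beaten["self", ] + !fs
    not_beaten["cv", ] <- not_beaten["cv", ] + !fc
    sum_self <- sum_self + res$self; sum_cv <- sum_cv + res$cv
    pts <- rbind(pts, data.frame(
      y_block_correlation = abs(stats::cor(y_perm, y)),
      ssqy_self = sum(res$self^2), ssqy_cv = sum(res$cv^2)))
  }
  pv <- if (aggregate == "per_permutation")
    (1 + not_beaten) / (n_permutations + 1)
  else rbind(self = pooled_p_values(sum_self / n_permutations - ref$self),
             cv = pooled_p_values(sum_cv / n_permutations - ref$cv))
  structure(list(n_permutations = n_permutations,
                 p_wilcoxon_self = pv["self", "wilcoxon"],
                 p_sign_self = pv["self", "sign"],
                 p_randt_self = pv["self", "randt"],
                 p_wilcoxon_cv = pv["cv", "wilcoxon"],
                 p_sign_cv = pv["cv", "sign"],
                 p_randt_cv = pv["cv", "randt"],
                 ssqy_points = pts, seed = seed, aggregate = aggregate),
            class = "permutation_report")
}

# One paired test of the original residuals against the permutation-average
# residuals; d > 0 favours the original. The randomization t uses a
# sign-flip null for the mean difference, not the parametric t distribution.
pooled_p_values <- function(d) {
  nz <- d[d != 0]
  wil <- if (!length(nz)) 1 else
    stats::wilcox.test(nz, alternative = "greater", exact = FALSE)$p.value
  sgn <- if (!length(nz)) 1 else
    stats::binom.test(sum(nz > 0), length(nz),
                      alternative = "greater")$p.value
  tst <- if (length(nz) < 2L) 1 else {
    t0 <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    flips <- vapply(seq_len(999L), function(i) {
      df <- d * sample(c(-1, 1), length(d), replace = TRUE)
      mean(df) / (stats::sd(df) / sqrt(length(df)))
    }, numeric(1L))
    (1 + sum(flips >= t0)) / 1000
  }
  c(wilcoxon = wil, sign = sgn, randt = tst)
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("permutation_report (", x$n_permutations, " permutations)\n",
      sprintf("self-prediction: wilcoxon %.3f  sign %.3f  rand-t %.3f\n",
              x$p_wilcoxon_self, x$p_sign_self, x$p_randt_self),
      sprintf("cross-validated: wilcoxon %.3f  sign %.3f  rand-t %.3f\n",
              x$p_wilcoxon_cv, x$p_sign_cv, x$p_randt_cv), sep = "")
  invisible(x)
}

#' All six permutation p-values as a named vector
#'
#' @param report a `permutation_report`.
#' @return named numeric vector of the six p-values.
#' @export
permutation_p_values <- function(report) {
  stopifnot(inherits(report, "permutation_report"))
  unlist(report[c("p_wilcoxon_self", "p_sign_self", "p_randt_self",
                  "p_wilcoxon_cv", "p_sign_cv", "p_randt_cv")])
}
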