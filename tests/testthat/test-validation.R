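test_that("metrics agree with exhaustive enumeration of small confusion tables", {
  for (tp in 0:3) for (tn in 0:3) for (fp in 0:3) for (fn in 0:3) {
    n <- tp + tn + fp + fn
    if (n == 0 || n > 6) next
    truth <- c(rep(TRUE, tp), rep(FALSE, tn), rep(FALSE, fp), rep(TRUE, fn))
    pred <- c(rep(TRUE, tp), rep(FALSE, tn), rep(TRUE, fp), rep(FALSE, fn))
    m <- classification_metrics(truth, pred)
    expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(tp, tn, fp, fn))
    expect_equal(m$ccr, 100 * (tp + tn) / n)
    expect_equal(m$sensitivity,
                 if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn))
    expect_equal(m$specificity,
                 if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp))
    expect_equal(m$precision,
                 if (tp + fp == 0) NA_real_ else 100 * tp / (tp + fp))
  }
})

test_that("degenerate denominators are undefined, never 0 or 100", {
  m <- classification_metrics(rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(m$precision, 0)
  expect_true(is.na(m$sensitivity))
  perfect <- classification_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(c(perfect$ccr, perfect$sensitivity, perfect$specificity,
                 perfect$precision), rep(100, 4))
  expect_error(classification_metrics(c(0, 1, 2), c(0, 1, 1)), "binary")
})

test_that("sensitivity and specificity swap under class relabelling", {
  set.seed(50)
  truth <- runif(40) < 0.6
  pred <- xor(truth, runif(40) < 0.2)
  a <- classification_metrics(truth, pred)
  b <- classification_metrics(!truth, !pred)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$ccr, b$ccr)
})

test_that("regression report reproduces the direct error formulas", {
  set.seed(51)
  g <- generate_spectra(40, noise = low_noise(), seed = 52)
  y <- g$samples$purity
  m <- fit_pls(g$spectra, y, n_factors = 4, preprocess = "snv")
  te <- generate_spectra(15, noise = low_noise(), seed = 53)
  rep_ <- regression_report(m, g$spectra, y, te$spectra, te$samples$purity)
  pred_te <- predict(m, te$spectra)
  expect_equal(rep_$rmsep,
               sqrt(mean((pred_te - te$samples$purity)^2)), tolerance = 1e-12)
  expect_equal(rep_$r2_test,
               1 - sum((te$samples$purity - pred_te)^2) /
                 sum((te$samples$purity - mean(te$samples$purity))^2),
               tolerance = 1e-12)
  expect_true(all(c("calibration", "test") %in% rep_$correlation_data$set))

  # a perfect model: fit on noiseless single-component data
  x0 <- matrix(seq(0.1, 1, length.out = 10), 10, 1) %*%
    t(rep(1, 5)) * matrix(rep(c(1, 2, 3, 2, 1), each = 10), 10, 5)
  y0 <- seq(0.1, 1, length.out = 10)
  m0 <- fit_pls(x0, y0, 1)
  r0 <- regression_report(m0, x0, y0, x0, y0)
  expect_lt(r0$rmsec, 1e-10)
  expect_equal(r0$r2_cal, 1, tolerance = 1e-10)

  # constant mean prediction scores r2 = 0 under the 1 - SSres/SStot rule
  set.seed(54)
  Xn <- matrix(rnorm(20), 10, 2)
  yn <- rnorm(10)
  mc <- fit_pls(Xn, yn, 0)
  rc <- regression_report(mc, Xn, yn)
  expect_equal(rc$r2_cal, 0, tolerance = 1e-12)
})

test_that("permutation report is self-consistent on informative data", {
  g <- generate_spectra(60, composition = informative_composition(),
                        noise = low_noise(), seed = 60)
  y <- as.numeric(g$samples$diacetylmorphine)
  pr <- permutation_test(g$spectra, y, n_factors = 5, preprocess = "snv",
                         mode = "discriminant", n_permutations = 20,
                         seed = 61)
  pv <- permutation_p_values(pr)
  expect_true(all(pv >= 0 & pv <= 1))
  expect_equal(pr$ssqy_points$y_block_correlation[1], 1)
  expect_equal(which.min(pr$ssqy_points$ssqy_self), 1L)
  expect_equal(nrow(pr$ssqy_points), 21L)
  # reproducible under a fixed seed
  pr2 <- permutation_test(g$spectra, y, n_factors = 5, preprocess = "snv",
                          mode = "discriminant", n_permutations = 20,
                          seed = 61)
  expect_identical(permutation_p_values(pr2), pv)
  expect_identical(pr2$ssqy_points, pr$ssqy_points)
  expect_error(permutation_test(g$spectra, rep(1, 60), 2), "zero variance")
  expect_error(permutation_test(g$spectra, y, 2, n_permutations = 5),
               ">= 20")
})

test_that("permutation p-values have a seed-invariant distribution", {
  set.seed(62)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30)
  ps <- vapply(1:16, function(s)
    permutation_test(X, y, n_factors = 1, mode = "regression",
                     n_permutations = 200, seed = s)$p_randt_cv,
    numeric(1))
  ks <- suppressWarnings(
    stats::ks.test(ps[1:8], ps[9:16]))
  expect_gt(ks$p.value, 0.01)
})

test_that("pooled aggregation is more powerful on informative data", {
  g <- generate_spectra(60, composition = informative_composition(),
                        noise = low_noise(), seed = 63)
  y <- as.numeric(g$samples$diacetylmorphine)
  pr <- permutation_test(g$spectra, y, n_factors = 5, preprocess = "snv",
                         mode = "discriminant", n_permutations = 20,
                         seed = 64, aggregate = "pooled")
  expect_true(all(permutation_p_values(pr) < 0.05))
})
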