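test_that("an exact linear relation is fitted perfectly with one factor", {
  x <- matrix(c(1, 2, 3), 3, 1)
  m <- fit_pls(x, c(2, 4, 6), n_factors = 1)
  expect_equal(m$fitted, c(2, 4, 6), tolerance = 1e-12)
  expect_equal(sqrt(mean((m$fitted - c(2, 4, 6))^2)), 0, tolerance = 1e-12)
})

test_that("full-factor PLS equals the least-squares oracle on full-rank data", {
  set.seed(30)
  n <- 14L; p <- 4L
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  m <- fit_pls(X, y, n_factors = p)
  # normal-equations oracle on centered data
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  beta <- solve(crossprod(Xc), crossprod(Xc, yc))
  expect_lt(max(abs(m$fitted - (drop(Xc %*% beta) + mean(y)))), 1e-8)
  expect_lt(max(abs(predict(m, X) - m$fitted)), 1e-12)
})

test_that("zero factors predict the training mean", {
  set.seed(31)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- fit_pls(X, y, n_factors = 0)
  expect_equal(predict(m, X), rep(mean(y), 10), tolerance = 1e-12)
})

test_that("NIPALS scores are orthogonal and weights unit-norm", {
  set.seed(32)
  X <- matrix(rnorm(20 * 15), 20, 15)
  y <- rnorm(20)
  m <- fit_pls(X, y, n_factors = 5)
  g <- crossprod(m$T)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  expect_equal(unname(colSums(m$W^2)), rep(1, 5), tolerance = 1e-10)
})

test_that("the stored regression vector equals the re-projection path", {
  set.seed(33)
  X <- matrix(rnorm(18 * 12), 18, 12)
  y <- rnorm(18)
  m <- fit_pls(X, y, n_factors = 4)
  Xc <- sweep(X, 2, m$x_center)
  T_re <- Xc %*% m$W %*% solve(crossprod(m$P, m$W))
  pred_re <- drop(T_re %*% m$q) + m$y_center
  expect_lt(max(abs(pred_re - predict(m, X))), 1e-8)
})

test_that("degenerate responses and excess factors are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rep(1, 10), 1), "zero variance")
  expect_error(fit_pls(X, rnorm(10), 5), "rank bound")
  expect_error(fit_pls(X, rep(1, 10), 1, mode = "discriminant"),
               "single class")
  expect_error(fit_pls(X, c(rep(0, 5), rep(2, 5)), 1, mode = "discriminant"),
               "0/1")
})

test_that("cross-validation is leakage-free, reproducible and finds the rank", {
  set.seed(34)
  n <- 40L; p <- 5L
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta)             # noiseless, rank-p relation
  cv <- cross_validate(X, y, a_max = 8, folds = 10, seed = 99)
  expect_lt(cv$rmsecv_by_factor[p], 1e-8)
  expect_lte(cv$chosen_factors, p)
  cv2 <- cross_validate(X, y, a_max = 8, folds = 10, seed = 99)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$rmsecv_by_factor, cv2$rmsecv_by_factor)
})

test_that("pure-noise responses keep the chosen factor count small", {
  set.seed(35)
  res <- replicate(50, {
    X <- matrix(rnorm(30 * 20), 30, 20)
    y <- rnorm(30)
    cv <- cross_validate(X, y, a_max = 8, folds = 5,
                         seed = sample.int(1e6, 1))
    c(chosen = cv$chosen_factors,
      early = cv$rmsecv_by_factor[1], late = cv$rmsecv_by_factor[8])
  })
  # overfitting inflates RMSECV beyond small factor counts, on average
  expect_gt(mean(res["late", ]), mean(res["early", ]))
  expect_lte(median(res["chosen", ]), 3)
})

test_that("grid search covers every configuration and returns the requested one", {
  set.seed(36)
  g <- generate_spectra(40, noise = low_noise(), seed = 40)
  y <- g$samples$purity
  gs <- pls_grid_search(g$spectra, y, a_max = 4, folds = 5, seed = 1)
  expect_equal(nrow(gs$table), 4L * 4L)
  gs1 <- pls_grid_search(g$spectra, y, pretreatments = "snv", a_max = 1,
                         folds = 5, seed = 1)
  expect_equal(nrow(gs1$table), 1L)
  expect_equal(gs1$best_method, "snv")
  expect_equal(gs1$best_factors, 1L)
  expect_error(pls_grid_search(g$spectra, y, pretreatments = "msc"),
               "unknown pre-treatment")
})

test_that("NIPALS agrees with an independent PLS implementation", {
  set.seed(37)
  X <- matrix(rnorm(25 * 10), 25, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  y <- drop(X %*% rnorm(10)) + rnorm(25, sd = 0.2)
  ours <- fit_pls(X, y, n_factors = 3)
  theirs <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                          scale = FALSE)
  pred <- predict(theirs, X)$predict[, 1, 3]
  expect_lt(max(abs(ours$fitted - pred)), 1e-6)
})

test_that("discriminant models classify a clearly present compound reliably", {
  # compound at >= 5% mass fraction (heroin), fixed workflow-selected config
  set.seed(38)
  ccrs <- replicate(50, {
    g <- generate_spectra(100, composition = informative_composition(),
                          seed = sample.int(1e6, 1))
    y <- as.numeric(g$samples$diacetylmorphine)
    if (sum(y == 0) < 2 || sum(y == 1) < 2) return(NA_real_)
    sp <- duplex_split(g$spectra, 20)
    tr <- match(sp$train_ids, g$spectra$sample_ids)
    te <- match(sp$test_ids, g$spectra$sample_ids)
    m <- fit_pls(subset_samples(g$spectra, sp$train_ids), y[tr],
                 n_factors = 5, preprocess = "snv", mode = "discriminant")
    pred <- predict(m, subset_samples(g$spectra, sp$test_ids),
                    type = "class")
    mean(pred == (y[te] == 1))
  })
  expect_gte(median(ccrs, na.rm = TRUE), 0.9)
})
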