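test_that("column scaling states hold training statistics", {
  x <- spectra_set(matrix(c(1, 3), 2, 1), 1000)
  st <- preprocess_fit("mean_center", x)
  expect_equal(unname(st$column_means), 2)

  const <- spectra_set(cbind(rnorm(4), rep(5, 4)), c(1000, 996))
  expect_error(preprocess_fit("autoscale", const), "996")

  y <- toy_spectra(10L, 6L, seed = 3)
  st2 <- preprocess_fit("autoscale", y)
  # brute-force per-column oracle
  for (j in 1:6) {
    expect_equal(unname(st2$column_means[j]), mean(y$absorbance[, j]))
    expect_equal(unname(st2$column_sds[j]), sd(y$absorbance[, j]))
  }
})

test_that("snv standardises each spectrum and ignores affine scatter", {
  x <- spectra_set(matrix(c(1, 2, 3), 1, 3), c(1008, 1004, 1000), "A")
  out <- preprocess_apply(preprocess_fit("snv", x), x)
  expect_equal(unname(out$absorbance[1, ]), c(-1, 0, 1))

  y <- toy_spectra(8L, 30L, seed = 4)
  sn <- preprocess_apply(preprocess_fit("snv", y), y)
  expect_lt(max(abs(rowMeans(sn$absorbance))), 1e-10)
  expect_lt(max(abs(apply(sn$absorbance, 1, sd) - 1)), 1e-10)
  # invariance to per-spectrum a*x + b with a > 0
  a <- runif(8, 0.5, 3); b <- rnorm(8)
  y2 <- spectra_set(y$absorbance * a + b, y$wavenumbers, y$sample_ids)
  sn2 <- preprocess_apply(preprocess_fit("snv", y2), y2)
  expect_lt(max(abs(sn$absorbance - sn2$absorbance)), 1e-9)

  flat <- spectra_set(rbind(rnorm(5), rep(2, 5)), seq(1016, 1000, by = -4),
                      c("ok", "flat"))
  expect_error(preprocess_apply(preprocess_fit("snv", flat), flat), "flat")
})

test_that("mean centering is invariant to adding a column constant", {
  y <- toy_spectra(6L, 10L, seed = 5)
  shift <- rnorm(10)
  y2 <- spectra_set(sweep(y$absorbance, 2, shift, "+"), y$wavenumbers,
                    y$sample_ids)
  c1 <- preprocess_apply(preprocess_fit("mean_center", y), y)
  c2 <- preprocess_apply(preprocess_fit("mean_center", y2), y2)
  expect_lt(max(abs(c1$absorbance - c2$absorbance)), 1e-12)
})

test_that("savgol second derivative annihilates lines and recovers quadratics", {
  n <- 40L
  expect_lt(max(abs(savgol_filter(seq_len(n)))), 1e-10)
  q <- savgol_filter((seq_len(n))^2)
  expect_lt(max(abs(q - 2)), 1e-9)   # exact everywhere incl. edges
})

test_that("savgol matches a per-window polynomial regression oracle", {
  set.seed(6)
  X <- matrix(rnorm(3 * 50), 3, 50)
  out <- savgol_filter(X, window = 17, poly_order = 2, deriv = 2)
  # independent oracle: local quadratic lm over the (possibly truncated)
  # window, second derivative = 2 * quadratic coefficient
  oracle <- function(v, j, h = 8L) {
    idx <- max(1L, j - h):min(length(v), j + h)
    z <- idx - j
    fit <- stats::lm(v[idx] ~ z + I(z^2))
    2 * unname(coef(fit)[3])
  }
  for (r in 1:3)
    for (j in c(1:3, 8:10, 25, 42:44, 48:50))
      expect_lt(abs(out[r, j] - oracle(X[r, ], j)), 1e-8)
})

test_that("savgol rejects invalid windows and scales to per-wavenumber units", {
  expect_error(savgol_filter(rnorm(30), window = 16), "odd")
  expect_error(savgol_filter(rnorm(10), window = 17), "shorter")
  v <- rnorm(40)
  expect_equal(savgol_filter(v, scale_delta = 4), savgol_filter(v) / 16)
})

test_that("train/test application fits state on the training set only", {
  tr <- toy_spectra(12L, 8L, seed = 7)
  te <- spectra_set(matrix(rnorm(4 * 8, mean = 3), 4, 8), tr$wavenumbers,
                    paste0("U", 1:4))
  res <- preprocess_train_test("mean_center", tr, te)
  expect_lt(max(abs(colMeans(res$train$absorbance))), 1e-12)
  expect_gt(max(abs(colMeans(res$test$absorbance))), 0.5)

  # snv has no fitted state: identical with or without a test set
  r1 <- preprocess_train_test("snv", tr, te)
  expect_equal(r1$test$absorbance,
               preprocess_apply(preprocess_fit("snv", te), te)$absorbance)

  # autoscale round trip via the algebraic inverse
  r2 <- preprocess_train_test("autoscale", tr, te)
  back <- preprocess_invert(r2$state, r2$train)
  expect_lt(max(abs(back$absorbance - tr$absorbance)), 1e-10)

  expect_error(preprocess_apply(
    r2$state, spectra_set(matrix(1:8, 1), seq(4000, 3972, by = -4))),
    "axis")
})
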