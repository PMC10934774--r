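test_that("duplex assigns the extreme pair to training, the next to test", {
  x <- spectra_set(matrix(c(0, 1, 9, 10), 4, 1), 1000,
                   c("a", "b", "c", "d"))
  sp <- duplex_split(x, 2)
  expect_setequal(sp$train_ids, c("a", "d"))   # pair (0, 10)
  expect_setequal(sp$test_ids, c("b", "c"))    # pair (1, 9)
})

test_that("duplex partitions are disjoint, exhaustive and deterministic", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:60, 1)
    m <- matrix(rnorm(n * 6), n, 6)
    rownames(m) <- sprintf("S%02d", seq_len(n))
    n_test <- sample(5:12, 1)
    sp <- duplex_split(m, n_test)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$test_ids), rownames(m))
    expect_length(sp$test_ids, n_test)
    # first selected pair realises the global max pairwise distance
    D <- as.matrix(dist(m))
    far <- which(D == max(D), arr.ind = TRUE)[1L, ]
    expect_true(all(rownames(m)[far] %in% sp$train_ids))
    # second round's winning pair (max distance among the rest) is in test
    rest <- setdiff(seq_len(n), far)
    D2 <- D[rest, rest]
    far2 <- which(D2 == max(D2), arr.ind = TRUE)[1L, ]
    expect_true(all(rownames(m)[rest][far2] %in% sp$test_ids))
    # deterministic
    expect_identical(duplex_split(m, n_test), sp)
    # row order is irrelevant without exact ties
    perm <- sample.int(n)
    sp2 <- duplex_split(m[perm, , drop = FALSE], n_test)
    expect_setequal(sp2$test_ids, sp$test_ids)
  }
})

test_that("odd test sizes are honoured and tiny inputs rejected", {
  m <- matrix(rnorm(30 * 3), 30, 3)
  sp <- duplex_split(m, 7)
  expect_length(sp$test_ids, 7)
  expect_length(sp$train_ids, 23)
  expect_error(duplex_split(matrix(rnorm(6), 3, 2), 2), "4 samples")
  expect_error(duplex_split(m, 29), "n_test")
})

test_that("ratio verification equals direct counting", {
  set.seed(8)
  n <- 60
  flags <- as.data.frame(matrix(runif(n * 11) < 0.7, n, 11,
                                dimnames = list(NULL, compound_names())))
  labels <- sample_table(sprintf("S%02d", 1:n),
                         ifelse(flags$diacetylmorphine, runif(n, 0.01, 0.5), 0),
                         flags, check_consistency = FALSE)
  m <- matrix(rnorm(n * 4), n, 4, dimnames = list(labels$sample_id, NULL))
  sp <- duplex_split(m, 12)
  rep <- verify_split(sp, labels, tolerance = 0.15)
  for (nm in compound_names()) {
    row <- rep[rep$compound == nm, ]
    in_test <- labels[[nm]][labels$sample_id %in% sp$test_ids]
    expect_equal(row$n_test_pos, sum(in_test))
    expect_equal(row$frac_test, mean(in_test))
    expect_equal(row$frac_full, mean(labels[[nm]]))
    expect_equal(row$flagged, abs(row$frac_test - row$frac_full) > 0.15)
  }
  cov <- attr(rep, "purity_coverage")
  expect_true(cov$test[1] >= cov$full[1] && cov$test[2] <= cov$full[2])
})

test_that("an all-positive compound is never flagged", {
  n <- 20
  flags <- as.data.frame(matrix(TRUE, n, 11,
                                dimnames = list(NULL, compound_names())))
  labels <- sample_table(sprintf("S%02d", 1:n), runif(n, 0.1, 0.5), flags)
  m <- matrix(rnorm(n * 3), n, 3, dimnames = list(labels$sample_id, NULL))
  rep <- verify_split(duplex_split(m, 5), labels)
  expect_true(all(rep$difference == 0))
  expect_false(any(rep$flagged))
})
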