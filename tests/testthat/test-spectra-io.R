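test_that("wide CSV round trip preserves ids, axis and values", {
  x <- toy_spectra(3L, 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(x, path)
  y <- read_spectra(path, "wide_csv")
  expect_identical(y$sample_ids, x$sample_ids)
  expect_equal(y$wavenumbers, x$wavenumbers)
  expect_lt(max(abs(y$absorbance - x$absorbance)), 1e-12)
  expect_equal(dim(y), c(3L, 5L))
})

test_that("ascending input is normalised to a descending axis", {
  m <- matrix(1:8, 2, 4)
  x <- spectra_set(m, c(650, 654, 658, 662))
  expect_true(all(diff(x$wavenumbers) < 0))
  expect_true(attr(x, "resorted"))
  # values follow their wavenumbers through the reordering
  expect_equal(unname(x$absorbance[, x$wavenumbers == 650]), m[, 1])
})

test_that("malformed spectral input fails loudly", {
  expect_error(spectra_set(matrix(1:4, 2), c(1000, 900), c("S1", "S1")),
               "S1")
  expect_error(spectra_set(matrix(c(1, NA, 3, 4), 2), c(1000, 900)),
               "non-finite")
  expect_error(spectra_set(matrix(1:6, 2), c(1000, 900, 950)),
               "monotone")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,1000,900", "S1,0.1,0.2", "S2,x,0.3"), bad)
  expect_error(read_spectra(bad, "wide_csv"), "S2")
})

test_that("select_region keeps the closed-interval fingerprint columns", {
  full_axis <- seq(4000, 400, by = -4)
  x <- spectra_set(matrix(rnorm(2 * length(full_axis)), 2), full_axis)
  fp <- select_region(x, region_spec(650, 2000))
  # brute-force count over the generated axis
  expect_equal(length(fp$wavenumbers),
               sum(full_axis >= 650 & full_axis <= 2000))
  expect_equal(length(fp$wavenumbers), 338L)
  expect_true(all(fp$wavenumbers >= 650 & fp$wavenumbers <= 2000))
  # idempotent, and the full-axis region is the identity
  expect_equal(select_region(fp, region_spec(650, 2000)), fp)
  expect_equal(select_region(x, region_spec(400, 4000))$absorbance,
               x$absorbance)
  expect_error(select_region(x, region_spec(10000, 11000)), "no wavenumbers")
})

test_that("minimal JCAMP-DX reader assembles a directory into one set", {
  dir <- withr::local_tempdir()
  wn <- seq(2000, 1980, by = -4)
  for (s in c("a", "b")) {
    y <- if (s == "a") 1:6 else 7:12
    writeLines(c("##TITLE=synthetic", "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
                 "##FIRSTX=2000", "##LASTX=1980", "##NPOINTS=6",
                 "##XFACTOR=1", "##YFACTOR=0.5",
                 "##XYDATA=(X++(Y..Y))",
                 paste(c(2000, y[1:3]), collapse = " "),
                 paste(c(1988, y[4:6]), collapse = " "),
                 "##END="),
               file.path(dir, paste0(s, ".jdx")))
  }
  x <- read_spectra(dir, "jcamp_dx")
  expect_equal(x$sample_ids, c("a", "b"))
  expect_equal(x$wavenumbers, wn)
  expect_equal(unname(x$absorbance["a", ]), (1:6) * 0.5)
  expect_equal(unname(x$absorbance["b", ]), (7:12) * 0.5)
})

test_that("sample table parsing handles percent purity and +/- flags", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("sample_id", "purity_percent", compound_names()),
               collapse = ",")
  writeLines(c(hdr,
               paste0("S33,56.53%,+,", paste(rep("-", 10), collapse = ",")),
               paste0("S1,0.00%,", paste(rep("−", 11), collapse = ","))),
             path)
  tab <- read_sample_table(path)
  expect_equal(tab$purity[tab$sample_id == "S33"], 0.5653)
  expect_true(tab$diacetylmorphine[tab$sample_id == "S33"])
  expect_false(tab$acetaminophen[tab$sample_id == "S33"])
  # all-negative zero-purity row passes the consistency check silently
  expect_false(tab$diacetylmorphine[tab$sample_id == "S1"])

  writeLines(c(hdr, paste0("S2,1.0%,?,", paste(rep("-", 10), collapse = ","))),
             path)
  expect_error(read_sample_table(path), "\\?")
  writeLines(paste(c("sample_id", "purity_percent", compound_names()[-3]),
                   collapse = ","), path)
  expect_error(read_sample_table(path), "diacetamate")
})

test_that("purity/presence inconsistency warns but does not abort", {
  flags <- as.data.frame(matrix(TRUE, 1, 11,
                                dimnames = list(NULL, compound_names())))
  expect_warning(sample_table("S1", 0, flags), "inconsistency")
  expect_silent(sample_table("S1", 0, flags, check_consistency = FALSE))
})

test_that("sample tables round-trip through CSV", {
  set.seed(9)
  flags <- as.data.frame(matrix(runif(5 * 11) < 0.6, 5, 11,
                                dimnames = list(NULL, compound_names())))
  tab <- sample_table(paste0("S", 1:5),
                      ifelse(flags$diacetylmorphine, runif(5, 0.01, 0.6), 0),
                      flags, check_consistency = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_table(tab, path)
  back <- read_sample_table(path, check_consistency = FALSE)
  expect_equal(back$purity, tab$purity, tolerance = 1e-6)
  for (nm in compound_names()) expect_identical(back[[nm]], tab[[nm]])
})

test_that("bundled assay panel reproduces the printed summary counts", {
  panel <- assay_panel()
  expect_equal(nrow(panel), 124L)
  counts <- count_positives(panel)
  expect_equal(unname(counts[c("diacetylmorphine", "acetaminophen",
                               "diacetamate", "caffeine", "codeine",
                               "morphine", "acetylcodeine",
                               "monoacetylmorphine", "papaverine",
                               "noscapine", "methacetin")]),
               c(117L, 117L, 115L, 118L, 29L, 111L, 116L, 117L, 112L,
                 116L, 10L))
  expect_equal(sum(!panel$diacetylmorphine), 7L)
  pos <- panel$purity[panel$diacetylmorphine]
  expect_equal(max(pos) * 100, 56.53)
  expect_equal(min(pos) * 100, 0.21)
  expect_equal(panel$sample_id[which.max(panel$purity)], "S33")
})
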