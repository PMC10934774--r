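#' Published per-compound model summary
#'
#' The packaged record of the published PLS-DA models this package's
#' workflow mirrors: per compound, the train/test class ratios (shared
#' 100/25 Duplex split), the selected pre-treatment and factor count, the
#' printed validation percentages, and the misclassification counts stated
#' in the accompanying per-compound discussion (`cv_fp`, `cv_fn`,
#' `test_fp`, `test_fn`; `NA` where no model was found — methacetin).
#'
#' @return data.frame, one row per compound.
#' @export
reported_models <- function() {
  path <- system.file("extdata", "reported_models.csv",
                      package = "ftirpls", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Arithmetic consistency check of the published metrics
#'
#' Recomputes ccr, sensitivity, specificity and precision from the stated
#' class sizes and misclassification counts (via the exact confusion-matrix
#' formulas) and diffs them against the printed values. The discrepancy list
#' is expected to be non-empty: a few printed entries are internally
#' inconsistent with the stated counts (for instance a test sensitivity
#' consistent with a 22/3 split printed beside a 21/4 ratio, and a
#' specificity pair that cannot arise from the stated two false positives
#' among six test negatives); the check surfaces these, it does not resolve
#' them.
#'
#' @param tolerance absolute percentage-point difference above which an
#'   entry is flagged (default 0.02, i.e. printed-precision agreement,
#'   tolerating truncation-vs-rounding in the last digit).
#' @return data.frame with columns `compound`, `set` (`cv`/`test`),
#'   `metric`, `computed`, `printed`, `difference`, `flagged`.
#' @export
reported_model_check <- function(tolerance = 0.02) {
  rm_ <- reported_models()
  out <- list()
  for (i in seq_len(nrow(rm_))) {
    row <- rm_[i, ]
    if (is.na(row$cv_fp)) next
    cmp <- list(
      cv = metrics_from_counts(row$n_train_pos, row$n_train_neg,
                               row$cv_fp, row$cv_fn),
      test = metrics_from_counts(row$n_test_pos, row$n_test_neg,
                                 row$test_fp, row$test_fn))
    printed <- list(
      cv = c(ccr = row$ccr_cv, sensitivity = row$sens_cv,
             specificity = row$spec_cv, precision = row$prec_cv),
      test = c(ccr = row$ccr_test, sensitivity = row$sens_test,
               specificity = row$spec_test, precision = row$prec_test))
    for (set in c("cv", "test")) {
      for (metric in c("ccr", "sensitivity", "specificity", "precision")) {
        comp <- cmp[[set]][[metric]]
        prt <- printed[[set]][[metric]]
        out[[length(out) + 1L]] <- data.frame(
          compound = row$compound, set = set, metric = metric,
          computed = comp, printed = prt, difference = comp - prt,
          flagged = abs(comp - prt) > tolerance)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

default_targets <- function() {
  rbind(data.frame(compound = compound_names(), mode = "discriminant"),
        data.frame(compound = "diacetylmorphine", mode = "regression"))
}

#' Full characterisation run
#'
#' Orchestrates the whole workflow on one sample set: fingerprint-region
#' selection, a single Duplex split shared by every target, per-target grid
#' search over pre-treatments and factor counts with 10-fold
#' cross-validation, final models with calibration/CV/test metrics, and a
#' Table-style report. Presence models are trained on all training samples;
#' the purity regression is trained on the heroin-positive training samples
#' only and evaluated on the heroin-positive test samples. A presence target
#' whose best cross-validated ccr does not beat the majority-class rate by
#' more than one percentage point is reported as having no significant
#' model.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `spectra`/`samples` (a `spectra_set` and `sample_table`) or `simulate`
#'   (list with `n` and optionals passed to [generate_spectra()]); `region`
#'   (default `c(650, 2000)`); `n_test` (default 20% rounded); `targets`
#'   (data.frame compound/mode; default: all eleven presence models plus the
#'   heroin purity regression); `pretreatments` (default all four); `a_max`
#'   (default 15); `folds` (default 10); `n_permutations` (default 0 — the
#'   permutation test is post-hoc validation and never changes model
#'   selection; set > 0 to run it per selected model); `seed`.
#' @return a `run_report`: `classification` (one row per presence target),
#'   `regression` (a `model_report` plus its configuration), `split`,
#'   `ratio_report`, `permutation` (list per target, when requested),
#'   `seed`.
#' @export
run_characterisation <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  region <- if (is.null(config$region)) c(650, 2000) else config$region
  a_max <- if (is.null(config$a_max)) 15L else as.integer(config$a_max)
  folds <- if (is.null(config$folds)) 10L else as.integer(config$folds)
  n_perm <- if (is.null(config$n_permutations)) 0L
    else as.integer(config$n_permutations)
  pretreat <- if (is.null(config$pretreatments)) pretreatment_methods()
    else config$pretreatments
  targets <- if (is.null(config$targets)) default_targets()
    else as.data.frame(config$targets)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    gen <- generate_spectra(
      n = if (is.null(sim$n)) 125L else sim$n,
      library = if (is.null(sim$library)) component_library() else sim$library,
      composition = if (is.null(sim$composition)) composition_model()
        else sim$composition,
      noise = if (is.null(sim$noise)) noise_model() else sim$noise,
      seed = if (is.null(sim$seed)) seed else sim$seed)
    spectra <- gen$spectra; samples <- gen$samples
  } else {
    spectra <- config$spectra; samples <- config$samples
    if (is.null(spectra) || is.null(samples))
      stop("config needs either 'simulate' or both 'spectra' and 'samples'")
  }

  fp <- select_region(spectra, region_spec(region[1L], region[2L]))
  n <- length(fp$sample_ids)
  n_test <- if (is.null(config$n_test)) round(0.2 * n) else config$n_test
  split <- duplex_split(fp, n_test)
  ratio <- verify_split(split, samples)

  x_train <- subset_samples(fp, split$train_ids)
  x_test <- subset_samples(fp, split$test_ids)
  lab_train <- samples[match(split$train_ids, samples$sample_id), ]
  lab_test <- samples[match(split$test_ids, samples$sample_id), ]

  cls_rows <- list(); perm_out <- list(); regression <- NULL
  for (i in seq_len(nrow(targets))) {
    compound <- resolve_compound(targets$compound[i])
    mode <- targets$mode[i]
    if (mode == "discriminant") {
      y_tr <- as.numeric(lab_train[[compound]])
      y_te <- as.numeric(lab_test[[compound]])
      npos <- sum(y_tr); nneg <- sum(1 - y_tr)
      base <- data.frame(compound = compound, mode = mode,
                         n_train_pos = npos, n_train_neg = nneg,
                         n_test_pos = sum(y_te), n_test_neg = sum(1 - y_te))
      if (npos < 2L || nneg < 2L) {
        cls_rows[[length(cls_rows) + 1L]] <- cbind(
          base, empty_cls_metrics("too few training samples in one class"))
        next
      }
      gs <- pls_grid_search(x_train, y_tr, pretreatments = pretreat,
                            a_max = min(a_max, npos + nneg - folds - 1L),
                            mode = "discriminant", folds = folds, seed = seed)
      majority <- 100 * max(mean(y_tr), 1 - mean(y_tr))
      best_ccr <- max(gs$table$ccr_cv)
      if (best_ccr <= majority + 1) {
        cls_rows[[length(cls_rows) + 1L]] <- cbind(
          base, empty_cls_metrics("no significant model"))
        next
      }
      model <- fit_pls(x_train, y_tr, n_factors = gs$best_factors,
                       preprocess = gs$best_method, mode = "discriminant")
      cv <- gs$cv
      pred_cal <- predict(model, x_train, type = "class")
      pred_cv <- cv$cv_predictions[, gs$best_factors] > model$class_threshold
      pred_te <- predict(model, x_test, type = "class")
      m_cal <- classification_metrics(y_tr == 1, pred_cal)
      m_cv <- classification_metrics(y_tr == 1, pred_cv)
      m_te <- classification_metrics(y_te == 1, pred_te)
      cls_rows[[length(cls_rows) + 1L]] <- cbind(base, data.frame(
        pretreatment = gs$best_method, n_factors = gs$best_factors,
        ccr_cal = m_cal$ccr, ccr_cv = m_cv$ccr, ccr_test = m_te$ccr,
        sens_cv = m_cv$sensitivity, sens_test = m_te$sensitivity,
        spec_cv = m_cv$specificity, spec_test = m_te$specificity,
        prec_cv = m_cv$precision, prec_test = m_te$precision,
        note = ""))
      if (n_perm > 0L)
        perm_out[[compound]] <- permutation_test(
          x_train, y_tr, n_factors = gs$best_factors,
          preprocess = gs$best_method, mode = "discriminant",
          n_permutations = n_perm, folds = folds, seed = seed)
    } else {                           # purity regression, positives only
      pos_tr <- split$train_ids[lab_train$diacetylmorphine]
      pos_te <- split$test_ids[lab_test$diacetylmorphine]
      xr_tr <- subset_samples(fp, pos_tr); xr_te <- subset_samples(fp, pos_te)
      y_tr <- samples$purity[match(pos_tr, samples$sample_id)]
      y_te <- samples$purity[match(pos_te, samples$sample_id)]
      gs <- pls_grid_search(xr_tr, y_tr, pretreatments = pretreat,
                            a_max = min(a_max, length(pos_tr) - folds - 1L),
                            mode = "regression", folds = folds, seed = seed)
      model <- fit_pls(xr_tr, y_tr, n_factors = gs$best_factors,
                       preprocess = gs$best_method, mode = "regression")
      rep_ <- regression_report(model, xr_tr, y_tr, xr_te, y_te, cv = gs$cv)
      regression <- list(compound = compound,
                         pretreatment = gs$best_method,
                         n_factors = gs$best_factors, report = rep_,
                         n_train = length(pos_tr), n_test = length(pos_te))
      if (n_perm > 0L)
        perm_out[["purity"]] <- permutation_test(
          xr_tr, y_tr, n_factors = gs$best_factors,
          preprocess = gs$best_method, mode = "regression",
          n_permutations = n_perm, folds = folds, seed = seed)
    }
  }
  structure(list(classification = do.call(rbind, cls_rows),
                 regression = regression, split = split,
                 ratio_report = ratio,
                 permutation = if (length(perm_out)) perm_out,
                 seed = seed),
            class = "run_report")
}

empty_cls_metrics <- function(note) {
  data.frame(pretreatment = NA_character_, n_factors = NA_integer_,
             ccr_cal = NA_real_, ccr_cv = NA_real_, ccr_test = NA_real_,
             sens_cv = NA_real_, sens_test = NA_real_,
             spec_cv = NA_real_, spec_test = NA_real_,
             prec_cv = NA_real_, prec_test = NA_real_, note = note)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report: ", nrow(x$classification), " presence models, ",
      if (is.null(x$regression)) "no" else "1", " regression model\n",
      sep = "")
  df <- x$classification
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, 2L)
  print(df, row.names = FALSE)
  if (!is.null(x$regression)) {
    cat("\npurity regression (", x$regression$pretreatment, ", ",
        x$regression$n_factors, " factors):\n", sep = "")
    print(x$regression$report)
  }
  invisible(x)
}
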