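#' Principal component analysis of pre-treated spectra
#'
#' Exploratory PCA by singular value decomposition. The chosen pre-treatment
#' is fitted on `x` and applied; the pre-treated matrix is then column
#' mean-centered (a no-op for `mean_center`/`autoscale`, which already
#' center) because uncentered PCA conflates the mean spectrum with variance.
#' Sign convention: within each component the loading element of largest
#' magnitude is positive.
#'
#' @param x a `spectra_set`.
#' @param k number of components, `k <= min(n_samples - 1, n_variables)`.
#' @param preprocess a method name from [pretreatment_methods()], a fitted
#'   `pretreat_state`, or `NULL` for centering only.
#' @return a `pca_model` with `scores` (n x k), `loadings` (p x k),
#'   `explained_variance_fraction`, `center`, `preprocess`, `wavenumbers`.
#' @export
fit_pca <- function(x, k = 3L, preprocess = "mean_center") {
  stopifnot(inherits(x, "spectra_set"))
  state <- if (is.null(preprocess)) NULL
    else if (inherits(preprocess, "pretreat_state")) preprocess
    else preprocess_fit(preprocess, x)
  xt <- if (is.null(state)) x else preprocess_apply(state, x)
  m <- as_abs_matrix(xt)
  n <- nrow(m); p <- ncol(m)
  k <- as.integer(k)
  if (k > min(n - 1L, p))
    stop("k must be <= min(n_samples - 1, n_variables) = ", min(n - 1L, p))
  ctr <- colMeans(m)
  mc <- sweep(m, 2L, ctr)
  sv <- svd(mc)
  total_var <- sum(sv$d^2)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]; sign(v[which.max(abs(v))])
  }, numeric(1L))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2L, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, flip, "*")
  rownames(scores) <- x$sample_ids
  rownames(loadings) <- format(x$wavenumbers, trim = TRUE)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = sv$d[seq_len(k)]^2 / total_var,
                 center = ctr, preprocess = state,
                 wavenumbers = x$wavenumbers, sample_ids = x$sample_ids),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model: ", nrow(x$scores), " samples, ", ncol(x$scores),
      " components\nexplained variance fraction: ",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Score-plot data with a class overlay
#'
#' Tags the first up-to-3 component scores with a compound's presence flags
#' and quantifies "visible clustering" as the mean silhouette width of the
#' binary grouping in that score space (positive values mean the two classes
#' separate; values near 0 mean no structure).
#'
#' @param model a `pca_model` with at least 1 component.
#' @param labels a `sample_table` covering the scored samples.
#' @param compound one of [compound_names()] (or `"heroin"`).
#' @return an `overlay` list: `scores` data.frame (ids, PCs, `positive`),
#'   `silhouette` (mean width, `NA` when a class is empty), `compound`.
#' @export
cluster_overlay <- function(model, labels, compound) {
  stopifnot(inherits(model, "pca_model"), inherits(labels, "sample_table"))
  compound <- resolve_compound(compound)
  idx <- match(model$sample_ids, labels$sample_id)
  if (anyNA(idx)) stop("labels do not cover all scored samples")
  pos <- labels[[compound]][idx]
  kk <- min(3L, ncol(model$scores))
  sc <- model$scores[, seq_len(kk), drop = FALSE]
  sil <- if (length(unique(pos)) < 2L) NA_real_ else {
    s <- cluster::silhouette(as.integer(pos) + 1L, stats::dist(sc))
    mean(s[, "sil_width"])
  }
  df <- data.frame(sample_id = model$sample_ids, sc,
                   positive = pos, check.names = FALSE)
  structure(list(scores = df, silhouette = sil, compound = compound),
            class = "overlay")
}

#' Correspondence between a PC loading and a reference spectrum
#'
#' Measures how much a component's loading pattern resembles a compound's
#' reference spectrum: the absolute Pearson correlation between the absolute
#' loading vector and the reference absorbance, plus the loading peaks lying
#' within `peak_window` cm^-1 of a reference peak. High correspondence
#' indicates that the clustering captured by that component is driven by the
#' compound's bands.
#'
#' @param model a `pca_model`.
#' @param reference a single-sample `spectra_set` on the same axis (or a
#'   numeric vector of the same length).
#' @param pc component index (default 1).
#' @param peak_window matching tolerance in cm^-1 (default 8, two grid steps
#'   at 4 cm^-1 resolution).
#' @return list with `correlation`, `matched_peaks` (data.frame of loading
#'   peak wavenumbers and their nearest reference peak), `pc`.
#' @export
loading_correspondence <- function(model, reference, pc = 1L,
                                   peak_window = 8) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(reference, "spectra_set")) {
    if (length(reference$wavenumbers) != length(model$wavenumbers) ||
        max(abs(reference$wavenumbers - model$wavenumbers)) > 1e-8)
      stop("reference axis does not match the model axis")
    ref <- as.numeric(reference$absorbance[1L, ])
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != length(model$wavenumbers))
      stop("reference length does not match the model axis")
  }
  ld <- abs(model$loadings[, pc])
  corr <- abs(stats::cor(ld, ref))
  wn <- model$wavenumbers
  lp <- wn[local_maxima(ld)]
  rp <- wn[local_maxima(ref)]
  matched <- if (length(lp) && length(rp)) {
    near <- vapply(lp, function(v) rp[which.min(abs(rp - v))], numeric(1L))
    keep <- abs(near - lp) <= peak_window
    data.frame(loading_peak = lp[keep], reference_peak = near[keep])
  } else data.frame(loading_peak = numeric(0), reference_peak = numeric(0))
  list(correlation = corr, matched_peaks = matched, pc = pc)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
}
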