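#' Spectral pre-treatments
#'
#' Four mutually exclusive pre-treatments are supported:
#' \describe{
#'   \item{`mean_center`}{subtract the per-wavenumber training mean.}
#'   \item{`autoscale`}{subtract the training mean and divide by the training
#'     standard deviation (n-1 denominator), per wavenumber.}
#'   \item{`snv`}{standard normal variate: per spectrum, subtract the row
#'     mean and divide by the row standard deviation. Removes multiplicative
#'     scatter and path-length effects; no fitted state.}
#'   \item{`savgol_2nd_derivative`}{Savitzky-Golay second derivative, local
#'     quadratic least squares over a 17-point window, per spectrum; no
#'     fitted state.}
#' }
#' Column statistics are always fitted on the training partition only and
#' applied unchanged to held-out data; anything else leaks test information.
#'
#' @name preprocessing
NULL

#' @rdname preprocessing
#' @return `pretreatment_methods()`: the four method names.
#' @export
pretreatment_methods <- function() {
  c("mean_center", "autoscale", "snv", "savgol_2nd_derivative")
}

as_abs_matrix <- function(x) {
  if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
}

check_axis <- function(state, x) {
  if (inherits(x, "spectra_set") && !is.null(state$wavenumbers)) {
    if (length(x$wavenumbers) != length(state$wavenumbers) ||
        max(abs(x$wavenumbers - state$wavenumbers)) > 1e-8)
      stop("wavenumber axis does not match the axis the state was fitted on")
  } else if (!is.null(state$n_vars) && ncol(as_abs_matrix(x)) != state$n_vars)
    stop("variable count does not match the fitting set")
}

#' Fit a pre-treatment state on training spectra
#'
#' @param method one of [pretreatment_methods()] (`"derivative"` is accepted
#'   as shorthand for `"savgol_2nd_derivative"`).
#' @param x training spectra (`spectra_set` or matrix).
#' @param window,poly_order Savitzky-Golay window (odd, default 17) and
#'   polynomial order (default 2); ignored by the other methods.
#' @return a `pretreat_state` holding the fitted column statistics (for
#'   `mean_center`/`autoscale`) or the filter parameters; `snv` and the
#'   derivative store no data-dependent state.
#' @export
preprocess_fit <- function(method, x, window = 17L, poly_order = 2L) {
  if (identical(method, "derivative")) method <- "savgol_2nd_derivative"
  method <- match.arg(method, pretreatment_methods())
  m <- as_abs_matrix(x)
  if (!nrow(m)) stop("cannot fit a pre-treatment on an empty set")
  wn <- if (inherits(x, "spectra_set")) x$wavenumbers else NULL
  st <- list(method = method, n_vars = ncol(m), wavenumbers = wn)
  if (method == "mean_center") {
    st$column_means <- colMeans(m)
  } else if (method == "autoscale") {
    st$column_means <- colMeans(m)
    st$column_sds <- apply(m, 2L, stats::sd)
    if (any(st$column_sds == 0)) {
      j <- which(st$column_sds == 0)[1L]
      stop("zero-variance column under autoscaling at wavenumber ",
           if (!is.null(wn)) wn[j] else j)
    }
  } else if (method == "savgol_2nd_derivative") {
    window <- as.integer(window); poly_order <- as.integer(poly_order)
    if (window %% 2L == 0L || window <= poly_order)
      stop("savgol window must be odd and greater than poly_order")
    st$savgol_params <- list(window = window, poly_order = poly_order)
  }
  structure(st, class = "pretreat_state")
}

#' Apply a fitted pre-treatment
#'
#' @param state a `pretreat_state` from [preprocess_fit()].
#' @param x spectra to transform (`spectra_set` or matrix) on the same axis
#'   as the fitting set.
#' @return transformed spectra, same class as `x`.
#' @export
preprocess_apply <- function(state, x) {
  stopifnot(inherits(state, "pretreat_state"))
  check_axis(state, x)
  m <- as_abs_matrix(x)
  out <- switch(state$method,
    mean_center = sweep(m, 2L, state$column_means),
    autoscale = sweep(sweep(m, 2L, state$column_means), 2L,
                      state$column_sds, "/"),
    snv = {
      mu <- rowMeans(m)
      sdv <- apply(m, 1L, stats::sd)
      if (any(sdv == 0)) {
        ids <- if (inherits(x, "spectra_set")) x$sample_ids else
          as.character(seq_len(nrow(m)))
        stop("constant spectrum (row sd 0) for sample '",
             ids[which(sdv == 0)[1L]], "'")
      }
      (m - mu) / sdv
    },
    savgol_2nd_derivative = savgol_filter(
      m, window = state$savgol_params$window,
      poly_order = state$savgol_params$poly_order)
  )
  if (inherits(x, "spectra_set"))
    spectra_set(out, x$wavenumbers, x$sample_ids)
  else out
}

#' Invert a scaling pre-treatment
#'
#' Only `mean_center` and `autoscale` are algebraically invertible.
#'
#' @param state a `pretreat_state`.
#' @param x transformed spectra.
#' @return spectra on the original scale.
#' @export
preprocess_invert <- function(state, x) {
  stopifnot(inherits(state, "pretreat_state"))
  m <- as_abs_matrix(x)
  out <- switch(state$method,
    mean_center = sweep(m, 2L, state$column_means, "+"),
    autoscale = sweep(sweep(m, 2L, state$column_sds, "*"), 2L,
                      state$column_means, "+"),
    stop("pre-treatment '", state$method, "' is not invertible"))
  if (inherits(x, "spectra_set"))
    spectra_set(out, x$wavenumbers, x$sample_ids)
  else out
}

#' Leakage-safe pre-treatment of a train/test pair
#'
#' Fits the state on the training set only and applies it to both sets.
#'
#' @inheritParams preprocess_fit
#' @param x_train,x_test spectra on a shared axis.
#' @return list with `train`, `test`, `state`.
#' @export
preprocess_train_test <- function(method, x_train, x_test, ...) {
  state <- preprocess_fit(method, x_train, ...)
  list(train = preprocess_apply(state, x_train),
       test = preprocess_apply(state, x_test),
       state = state)
}

# Savitzky-Golay derivative weights for every output position of an
# n-point row. Interior points share the symmetric window; the first/last
# half-window points use the window truncated at the row boundary (still a
# full least-squares quadratic fit, evaluated at the off-centre point), so
# output length equals input length.
savgol_weights <- function(n, window, poly_order, deriv) {
  h <- (window - 1L) %/% 2L
  wfor <- function(offsets) {
    A <- outer(offsets, 0:poly_order, "^")
    # row deriv+1 of (A'A)^-1 A' evaluates the deriv-th coefficient
    cf <- solve(crossprod(A), t(A))[deriv + 1L, ]
    cf * factorial(deriv)
  }
  interior <- wfor((-h):h)
  edges_lo <- lapply(seq_len(min(h, n)), function(j) {
    idx <- seq.int(max(1L, j - h), min(n, j + h))
    list(idx = idx, w = wfor(idx - j))
  })
  edges_hi <- lapply(seq.int(max(1L, n - h + 1L), n), function(j) {
    idx <- seq.int(max(1L, j - h), min(n, j + h))
    list(idx = idx, w = wfor(idx - j))
  })
  list(h = h, interior = interior, edges_lo = edges_lo, edges_hi = edges_hi)
}

#' Savitzky-Golay derivative filter
#'
#' Row-wise polynomial least-squares derivative. The derivative is taken with
#' respect to the point index; on a uniform grid with spacing `delta` cm^-1
#' the second derivative per cm^-2 is the result divided by `delta^2`
#' (`scale_delta`). At the first/last half-window points the window is
#' truncated at the boundary and the polynomial refitted, preserving the
#' output length.
#'
#' @param x matrix (rows = spectra) or numeric vector.
#' @param window odd window length, default 17.
#' @param poly_order polynomial order, default 2.
#' @param deriv derivative order, default 2.
#' @param scale_delta optional grid spacing; when given, the result is
#'   divided by `scale_delta^deriv` to express the derivative per x-unit.
#' @return filtered matrix (or vector), same shape as input.
#' @export
savgol_filter <- function(x, window = 17L, poly_order = 2L, deriv = 2L,
                          scale_delta = NULL) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  n <- ncol(m)
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= poly_order)
    stop("window must be odd and greater than poly_order")
  if (n < window) stop("row length (", n, ") shorter than window (", window, ")")
  w <- savgol_weights(n, window, poly_order, deriv)
  h <- w$h
  out <- matrix(0, nrow(m), n)
  # interior via a banded weight matrix (one crossprod for all rows)
  ii <- (h + 1L):(n - h)
  W <- matrix(0, n, length(ii))
  for (k in seq_along(ii)) W[(ii[k] - h):(ii[k] + h), k] <- w$interior
  out[, ii] <- m %*% W
  for (k in seq_along(w$edges_lo)) {
    e <- w$edges_lo[[k]]
    if (k <= h) out[, k] <- m[, e$idx, drop = FALSE] %*% e$w
  }
  hi_pos <- seq.int(max(1L, n - h + 1L), n)
  for (k in seq_along(hi_pos)) {
    if (hi_pos[k] > h) {
      e <- w$edges_hi[[k]]
      out[, hi_pos[k]] <- m[, e$idx, drop = FALSE] %*% e$w
    }
  }
  if (!is.null(scale_delta)) out <- out / scale_delta^deriv
  dimnames(out) <- dimnames(m)
  if (vec) drop(out) else out
}
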