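#' Construct a spectra set
#'
#' A `spectra_set` holds a samples-by-wavenumbers matrix of pseudo-absorbance
#' values together with its wavenumber axis and unique sample identifiers.
#' The axis is stored in descending wavenumber order (instrument convention
#' for mid-IR); ascending input is re-sorted and the reordering recorded in
#' the `"resorted"` attribute.
#'
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavenumber. Pseudo-absorbance, unitless.
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   monotone (either direction on input).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix rownames, or `"S1"..."Sn"` when absent.
#' @return an object of class `spectra_set` with fields `absorbance`,
#'   `wavenumbers`, `sample_ids`.
#' @export
spectra_set <- function(absorbance, wavenumbers,
                        sample_ids = rownames(absorbance)) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  sample_ids <- as.character(sample_ids)

  if (length(wavenumbers) != ncol(absorbance))
    stop("length(wavenumbers) must equal ncol(absorbance)")
  if (length(sample_ids) != nrow(absorbance))
    stop("length(sample_ids) must equal nrow(absorbance)")
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavenumber axis must be strictly monotone")
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop("duplicate sample id: ", dup)
  }
  if (!all(is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1L, ]
    stop("non-finite absorbance at sample '", sample_ids[bad[1L]],
         "', wavenumber ", wavenumbers[bad[2L]])
  }

  resorted <- FALSE
  if (length(d) && all(d > 0)) {           # ascending input: normalise
    ord <- order(wavenumbers, decreasing = TRUE)
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
    resorted <- TRUE
  }
  dimnames(absorbance) <- list(sample_ids, format(wavenumbers, trim = TRUE))
  structure(
    list(absorbance = absorbance, wavenumbers = wavenumbers,
         sample_ids = sample_ids),
    resorted = resorted, class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set: ", length(x$sample_ids), " samples x ",
      length(x$wavenumbers), " wavenumbers (",
      format(max(x$wavenumbers)), " - ", format(min(x$wavenumbers)),
      " cm^-1)\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample
#'
#' @param x a `spectra_set`.
#' @param ids character vector of sample ids (or logical/integer index).
#' @return a `spectra_set` restricted to the selected samples, in the order
#'   requested.
#' @export
subset_samples <- function(x, ids) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.character(ids)) {
    missing <- setdiff(ids, x$sample_ids)
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    idx <- match(ids, x$sample_ids)
  } else idx <- ids
  spectra_set(x$absorbance[idx, , drop = FALSE], x$wavenumbers,
              x$sample_ids[idx])
}

#' Pseudo-absorbance from ATR reflectance
#'
#' Converts raw reflectance R to the standard pseudo-absorbance log10(1/R).
#' Spectra exported by instrument software are usually already on this scale;
#' the helper exists for raw-reflectance input only.
#'
#' @param R reflectance values in (0, 1]; vector or matrix.
#' @return log10(1/R), same shape as input.
#' @export
pseudo_absorbance <- function(R) {
  if (any(R <= 0)) stop("reflectance must be positive")
  log10(1 / R)
}

#' Wavenumber region specification
#'
#' @param low,high region bounds in cm^-1, `low < high`. The interval is
#'   closed: boundary points on the axis are included.
#' @return a `region_spec` object.
#' @export
region_spec <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1,
            length(high) == 1)
  if (!(low < high)) stop("region requires low < high")
  structure(list(low = low, high = high), class = "region_spec")
}

#' Restrict a spectra set to a wavenumber region
#'
#' Keeps the columns with `low <= wavenumber <= high` (closed interval).
#' The default region is the mid-IR fingerprint region, 650-2000 cm^-1,
#' where compound-specific bands concentrate.
#'
#' @param x a `spectra_set`.
#' @param region a `region_spec`, or a numeric length-2 vector `c(low, high)`.
#' @return a `spectra_set` containing only the selected columns.
#' @export
select_region <- function(x, region = region_spec(650, 2000)) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.numeric(region) && length(region) == 2)
    region <- region_spec(min(region), max(region))
  stopifnot(inherits(region, "region_spec"))
  keep <- x$wavenumbers >= region$low & x$wavenumbers <= region$high
  if (!any(keep))
    stop("region [", region$low, ", ", region$high,
         "] selects no wavenumbers on the recorded axis")
  spectra_set(x$absorbance[, keep, drop = FALSE], x$wavenumbers[keep],
              x$sample_ids)
}

#' Read spectra from disk
#'
#' Two dialects are supported. `wide_csv`: one UTF-8 CSV, first column
#' `sample_id`, remaining column headers the wavenumbers in cm^-1, cells the
#' pseudo-absorbance ("." decimal). `jcamp_dx`: minimal JCAMP-DX reader for
#' single-spectrum `XYDATA=(X++(Y..Y))` files; `path` may be one file or a
#' directory, in which case every `*.jdx`/`*.dx` file becomes one sample
#' (file stem as sample id) and all files must share the axis.
#'
#' @param path file (or directory, for JCAMP) to read.
#' @param dialect `"wide_csv"` or `"jcamp_dx"`.
#' @return a validated `spectra_set` (axis descending, row order preserved).
#' @export
read_spectra <- function(path, dialect = c("wide_csv", "jcamp_dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "wide_csv") read_spectra_wide_csv(path) else
    read_spectra_jcamp(path)
}

read_spectra_wide_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("wide CSV needs sample_id plus >= 1 wavenumber column")
  ids <- df[[1L]]
  wn <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(wn))
    stop("non-numeric wavenumber header: ",
         names(df)[-1L][which(is.na(wn))[1L]])
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row '", ids[bad[1L]], "', column '",
         names(df)[-1L][bad[2L]], "'")
  }
  spectra_set(vals, wn, ids)
}

read_spectra_jcamp <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.(jdx|dx)$", ignore.case = TRUE,
               full.names = TRUE)
  else path
  if (!length(files)) stop("no JCAMP-DX files under ", path)
  specs <- lapply(files, read_one_jcamp)
  wn <- specs[[1L]]$wavenumbers
  for (s in specs[-1L])
    if (length(s$wavenumbers) != length(wn) ||
        max(abs(s$wavenumbers - wn)) > 1e-6)
      stop("JCAMP files do not share a common wavenumber axis")
  mat <- do.call(rbind, lapply(specs, `[[`, "y"))
  ids <- sub("\\.[^.]*$", "", basename(files))
  spectra_set(mat, wn, ids)
}

# Minimal JCAMP-DX: LDRs ##FIRSTX, ##LASTX, ##NPOINTS, ##XFACTOR, ##YFACTOR,
# then ##XYDATA=(X++(Y..Y)) lines "x y1 y2 ..." until ##END.
read_one_jcamp <- function(file) {
  lines <- readLines(file, warn = FALSE)
  ldr <- function(name, default = NA_real_) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(".*=\\s*", "", hit[1L]))
  }
  firstx <- ldr("FIRSTX"); lastx <- ldr("LASTX"); npts <- ldr("NPOINTS")
  xf <- ldr("XFACTOR", 1); yf <- ldr("YFACTOR", 1)
  start <- grep("^##XYDATA", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block in ", file)
  endln <- grep("^##END", lines, ignore.case = TRUE)
  endln <- if (length(endln)) min(endln[endln > start[1L]]) else length(lines) + 1L
  body <- lines[(start[1L] + 1L):(endln - 1L)]
  y <- unlist(lapply(body, function(ln) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    as.numeric(tok[-1L]) * yf        # first token is the line's abscissa
  }))
  if (is.na(npts)) npts <- length(y)
  if (length(y) != npts)
    stop("NPOINTS (", npts, ") does not match data (", length(y), ") in ", file)
  wn <- seq(firstx, lastx, length.out = npts) * xf
  list(wavenumbers = wn, y = y)
}

#' Write spectra to a wide CSV
#'
#' Inverse of [read_spectra()] for the `wide_csv` dialect; a read of the
#' written file reproduces ids and axis exactly and values to full `write.csv`
#' precision (~1e-15 relative).
#'
#' @param x a `spectra_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(sample_id = x$sample_ids, check.names = FALSE)
  vals <- as.data.frame(x$absorbance)
  names(vals) <- format(x$wavenumbers, trim = TRUE, digits = 15)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
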