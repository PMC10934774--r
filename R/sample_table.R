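#' Compounds tracked in the annotation schema
#'
#' The eleven compounds assayed per sample: heroin itself
#' (3,6-diacetylmorphine) and ten adulterants/impurities. Opium alkaloids
#' (morphine, codeine, papaverine, noscapine) and their acetylation products
#' (acetylcodeine, 6-monoacetylmorphine) are production impurities;
#' acetaminophen, caffeine, diacetamate and methacetin are cutting agents.
#'
#' @return character vector of the eleven compound identifiers, heroin first.
#' @export
compound_names <- function() {
  c("diacetylmorphine", "acetaminophen", "diacetamate", "caffeine",
    "codeine", "morphine", "acetylcodeine", "monoacetylmorphine",
    "papaverine", "noscapine", "methacetin")
}

# "heroin" is accepted anywhere a compound is named
resolve_compound <- function(compound) {
  if (identical(compound, "heroin")) compound <- "diacetylmorphine"
  if (!compound %in% compound_names())
    stop("unknown compound: ", compound)
  compound
}

#' Construct a sample annotation table
#'
#' @param sample_id character vector of unique ids.
#' @param purity numeric vector, mass fraction of 3,6-diacetylmorphine in
#'   `[0, 1]` (percent m/m divided by 100).
#' @param presence logical matrix or data.frame, one column per compound in
#'   [compound_names()], `TRUE` = positive.
#' @param check_consistency warn when `purity == 0` does not coincide with a
#'   negative heroin flag (and vice versa). The check warns rather than
#'   errors: genuine samples exist with purity barely above zero and sparse
#'   impurity patterns.
#' @return a `sample_table`: a data.frame with columns `sample_id`, `purity`
#'   and one logical column per compound.
#' @export
sample_table <- function(sample_id, purity, presence,
                         check_consistency = TRUE) {
  sample_id <- as.character(sample_id)
  purity <- as.numeric(purity)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1L])
  if (any(is.na(purity) | purity < 0 | purity > 1))
    stop("purity must be a fraction in [0, 1]")
  presence <- as.data.frame(presence)
  missing <- setdiff(compound_names(), names(presence))
  if (length(missing))
    stop("missing compound column(s): ", paste(missing, collapse = ", "))
  presence <- presence[compound_names()]
  if (any(vapply(presence, function(col) any(is.na(col)), logical(1L))))
    stop("every presence value must be explicitly set (no NA)")
  for (nm in names(presence)) presence[[nm]] <- as.logical(presence[[nm]])
  if (check_consistency) {
    mismatch <- xor(purity == 0, !presence$diacetylmorphine)
    if (any(mismatch))
      warning("purity/heroin-presence inconsistency for sample(s): ",
              paste(sample_id[mismatch], collapse = ", "))
  }
  out <- cbind(data.frame(sample_id = sample_id, purity = purity,
                          stringsAsFactors = FALSE), presence)
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Read a sample annotation table from CSV
#'
#' Expected header: `sample_id`, `purity_percent` (or `purity`), then the
#' eleven compound columns of [compound_names()] with `+` / `-` cells (the
#' Unicode minus is accepted). A `%`-suffixed purity is parsed and divided
#' by 100.
#'
#' @param path CSV file.
#' @param ... passed to [sample_table()] (e.g. `check_consistency`).
#' @return a `sample_table`.
#' @export
read_sample_table <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(df)) stop("header must contain 'sample_id'")
  pur_col <- intersect(c("purity_percent", "purity"), names(df))
  if (!length(pur_col)) stop("header must contain 'purity_percent' or 'purity'")
  missing <- setdiff(compound_names(), names(df))
  if (length(missing))
    stop("missing compound column(s): ", paste(missing, collapse = ", "))

  raw <- df[[pur_col[1L]]]
  pct <- grepl("%$", raw)
  purity <- suppressWarnings(as.numeric(sub("%$", "", raw)))
  if (anyNA(purity))
    stop("unparseable purity for sample '",
         df$sample_id[which(is.na(purity))[1L]], "'")
  purity[pct] <- purity[pct] / 100
  if (pur_col[1L] == "purity_percent") purity[!pct] <- purity[!pct] / 100

  presence <- lapply(compound_names(), function(nm) {
    cell <- trimws(df[[nm]])
    ok <- cell %in% c("+", "-", "−")
    if (!all(ok))
      stop("unknown presence symbol '", cell[!ok][1L], "' for sample '",
           df$sample_id[!ok][1L], "', compound '", nm, "'")
    cell == "+"
  })
  names(presence) <- compound_names()
  sample_table(df$sample_id, purity, as.data.frame(presence), ...)
}

#' Write a sample annotation table to CSV
#'
#' Inverse of [read_sample_table()]: purity as a `%`-suffixed
#' `purity_percent` column, presence as `+`/`-`.
#'
#' @param tab a `sample_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(tab, path) {
  stopifnot(inherits(tab, "sample_table"))
  out <- data.frame(sample_id = tab$sample_id,
                    purity_percent = sprintf("%.4f%%", tab$purity * 100))
  for (nm in compound_names())
    out[[nm]] <- ifelse(tab[[nm]], "+", "-")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled street-heroin assay panel
#'
#' A panel of 124 street heroin samples characterised by GC-MS (presence of
#' the eleven compounds) and UHPLC (heroin purity), shipped with the package
#' as the reference annotation fixture. Seven samples are heroin-negative;
#' purity of the positives spans 0.21-56.53 % m/m. Note: the study the panel
#' derives from counts 125 samples but prints 124 rows; the panel contains
#' exactly the printed rows.
#'
#' @return a `sample_table` with 124 rows.
#' @export
assay_panel <- function() {
  path <- system.file("extdata", "heroin_assay_panel.csv",
                      package = "ftirpls", mustWork = TRUE)
  read_sample_table(path)
}

#' Positive-sample counts per compound
#'
#' @param labels a `sample_table`.
#' @return named integer vector of positives per compound.
#' @export
count_positives <- function(labels) {
  stopifnot(inherits(labels, "sample_table"))
  vapply(compound_names(), function(nm) sum(labels[[nm]]), integer(1L))
}
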