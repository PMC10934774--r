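#' Synthetic ATR-FTIR mixture spectra
#'
#' The generator emulates the statistical structure of real street-heroin
#' spectra so every pipeline stage is testable without measured data:
#' spectra are Beer-Lambert linear combinations of per-compound band
#' signatures weighted by mass fractions, degraded by instrument artefacts
#' (additive noise, a low-order polynomial baseline and per-spectrum
#' multiplicative scatter — the effects SNV and derivative pre-treatments
#' are designed to remove). Band positions are loosely inspired by
#' carbonyl/aromatic chemistry but are synthetic stand-ins, not measured
#' reference spectra.
#'
#' @name synthetic_data
NULL

#' Synthetic component band library
#'
#' One band list per compound (the eleven assayed compounds plus a generic
#' `cutting_agent` standing for inert diluents such as sugars or chalk).
#' Band centers lie inside the 650-2000 cm^-1 fingerprint region and every
#' pair of signatures is distinct (pairwise cosine similarity < 0.95).
#'
#' @return data.frame with columns `component`, `center` (cm^-1), `width`
#'   (cm^-1), `amplitude`, `shape` (`gaussian` or `lorentzian`).
#' @export
component_library <- function() {
  band <- function(component, center, width, amplitude, shape = "gaussian")
    data.frame(component = component, center = center, width = width,
               amplitude = amplitude, shape = shape)
  rbind(
    band("diacetylmorphine", c(1735, 1600, 1365, 1245, 1175, 910),
         c(12, 10, 10, 14, 10, 8), c(1.0, 0.45, 0.5, 0.8, 0.6, 0.3)),
    band("acetaminophen", c(1650, 1610, 1565, 1505, 1225, 835),
         c(12, 8, 10, 10, 12, 8), c(0.9, 0.5, 0.6, 0.7, 0.6, 0.4)),
    band("diacetamate", c(1765, 1670, 1540, 1370, 1190, 910),
         c(10, 10, 10, 8, 12, 8), c(0.8, 0.7, 0.5, 0.4, 0.6, 0.25)),
    band("caffeine", c(1700, 1655, 1550, 1480, 1285, 745),
         c(12, 10, 8, 8, 10, 8), c(0.9, 0.8, 0.4, 0.5, 0.5, 0.4)),
    band("codeine", c(1630, 1500, 1270, 1115, 1050, 940),
         c(10, 8, 10, 8, 8, 8), c(0.5, 0.4, 0.5, 0.5, 0.6, 0.3)),
    band("morphine", c(1615, 1585, 1245, 1085, 945, 805),
         c(10, 8, 8, 8, 8, 8), c(0.5, 0.4, 0.4, 0.5, 0.4, 0.4)),
    band("acetylcodeine", c(1740, 1630, 1440, 1240, 1055, 900),
         c(10, 8, 8, 10, 8, 8), c(0.8, 0.35, 0.4, 0.6, 0.5, 0.25)),
    band("monoacetylmorphine", c(1730, 1610, 1445, 1235, 1035, 860),
         c(10, 8, 8, 10, 8, 8), c(0.7, 0.4, 0.35, 0.55, 0.45, 0.3)),
    band("papaverine", c(1610, 1510, 1460, 1275, 1025, 765),
         c(8, 8, 8, 8, 8, 8), c(0.6, 0.7, 0.4, 0.5, 0.5, 0.35),
         shape = "lorentzian"),
    band("noscapine", c(1760, 1620, 1495, 1395, 1080, 935),
         c(10, 8, 8, 8, 8, 8), c(0.75, 0.4, 0.4, 0.35, 0.45, 0.3)),
    band("methacetin", c(1660, 1510, 1245, 1030, 830),
         c(10, 8, 8, 8, 8), c(0.8, 0.6, 0.5, 0.4, 0.35)),
    band("cutting_agent", c(1420, 1150, 1080, 1020, 990, 850),
         c(30, 25, 25, 25, 20, 15), c(0.3, 0.5, 0.6, 0.55, 0.4, 0.2),
         shape = "lorentzian")
  )
}

#' Evaluate component signatures on a wavenumber axis
#'
#' @param library a band library, see [component_library()].
#' @param wavenumbers numeric axis in cm^-1.
#' @return matrix components x wavenumbers of unit-concentration absorbance.
#' @export
signature_matrix <- function(library = component_library(),
                             wavenumbers = default_axis()) {
  comps <- unique(library$component)
  S <- matrix(0, length(comps), length(wavenumbers),
              dimnames = list(comps, NULL))
  for (i in seq_len(nrow(library))) {
    b <- library[i, ]
    z <- (wavenumbers - b$center) / b$width
    shape <- if (b$shape == "gaussian") exp(-0.5 * z^2) else 1 / (1 + z^2)
    S[b$component, ] <- S[b$component, ] + b$amplitude * shape
  }
  S
}

#' Default fingerprint wavenumber axis
#'
#' 2000 down to 650 cm^-1 in 4 cm^-1 steps (338 points), matching a 4 cm^-1
#' resolution instrument after fingerprint-region selection.
#'
#' @return numeric vector, descending.
#' @export
default_axis <- function() seq(2000, 650, by = -4)

#' Composition model for synthetic street-heroin samples
#'
#' Defaults mirror the sample structure the analysis assumes: a 5.6%
#' heroin-negative rate; log-normal purity for positives with median 0.11
#' (range roughly 0.002-0.57, truncated); opium-alkaloid impurities and the
#' near-ubiquitous cutting agents present with high probability given
#' heroin; codeine sparse (23%) and morphine/codeine confined to low mass
#' fractions (most of both is acetylated during production); methacetin rare
#' (8%) and low-dosed. A fraction of the heroin-negative samples are
#' "confusable": they contain caffeine plus acetaminophen and therefore
#' resemble positives — the central difficulty the classification models
#' face.
#'
#' @param negative_rate probability a sample contains no heroin.
#' @param confusable_rate probability a negative contains caffeine and
#'   acetaminophen.
#' @param purity_meanlog,purity_sdlog log-normal parameters of positive
#'   purity.
#' @param purity_range truncation bounds for the purity fraction.
#' @param presence_prob named probabilities of each adulterant given heroin.
#' @param fraction_range named list of `c(lo, hi)` mass-fraction ranges for
#'   present adulterants.
#' @param detection_floor mass fraction below which a compound is reported
#'   absent.
#' @return a `composition_model` list of the above.
#' @export
composition_model <- function(
    negative_rate = 0.056,
    confusable_rate = 2 / 7,
    purity_meanlog = log(0.11),
    purity_sdlog = 0.6,
    purity_range = c(0.002, 0.60),
    presence_prob = c(acetaminophen = 0.98, diacetamate = 0.97,
                      caffeine = 0.99, codeine = 0.23, morphine = 0.95,
                      acetylcodeine = 0.99, monoacetylmorphine = 0.99,
                      papaverine = 0.96, noscapine = 0.99,
                      methacetin = 0.08),
    fraction_range = list(
      acetaminophen = c(0.05, 0.35), diacetamate = c(0.02, 0.10),
      caffeine = c(0.05, 0.35), codeine = c(0.002, 0.010),
      morphine = c(0.002, 0.010), acetylcodeine = c(0.010, 0.060),
      monoacetylmorphine = c(0.010, 0.080), papaverine = c(0.005, 0.030),
      noscapine = c(0.005, 0.040), methacetin = c(0.005, 0.020)),
    detection_floor = 5e-4) {
  structure(list(negative_rate = negative_rate,
                 confusable_rate = confusable_rate,
                 purity_meanlog = purity_meanlog,
                 purity_sdlog = purity_sdlog,
                 purity_range = purity_range,
                 presence_prob = presence_prob,
                 fraction_range = fraction_range,
                 detection_floor = detection_floor),
            class = "composition_model")
}

#' Instrument noise model
#'
#' @param additive_sd standard deviation of i.i.d. Gaussian noise per point
#'   (absorbance units).
#' @param baseline_order,baseline_amplitude order and coefficient scale of a
#'   random polynomial baseline per spectrum.
#' @param scatter_sdlog log-sd of the per-spectrum multiplicative scatter
#'   factor (log-normal around 1).
#' @param wavelength_jitter axis jitter in cm^-1 (off by default).
#' @return a `noise_model` list.
#' @export
noise_model <- function(additive_sd = 0.002, baseline_order = 2L,
                        baseline_amplitude = 0.02, scatter_sdlog = 0.10,
                        wavelength_jitter = 0) {
  if (additive_sd < 0 || baseline_amplitude < 0 || scatter_sdlog < 0 ||
      wavelength_jitter < 0)
    stop("noise magnitudes must be >= 0")
  structure(list(additive_sd = additive_sd,
                 baseline_order = as.integer(baseline_order),
                 baseline_amplitude = baseline_amplitude,
                 scatter_sdlog = scatter_sdlog,
                 wavelength_jitter = wavelength_jitter),
            class = "noise_model")
}

sample_composition <- function(n, composition) {
  comps <- compound_names()
  adulterants <- setdiff(comps, "diacetylmorphine")
  Fm <- matrix(0, n, length(comps) + 1L,
               dimnames = list(NULL, c(comps, "cutting_agent")))
  for (i in seq_len(n)) {
    negative <- stats::runif(1) < composition$negative_rate
    if (!negative) {
      repeat {
        pur <- stats::rlnorm(1, composition$purity_meanlog,
                             composition$purity_sdlog)
        if (pur >= composition$purity_range[1L] &&
            pur <= composition$purity_range[2L]) break
      }
      Fm[i, "diacetylmorphine"] <- pur
      for (a in adulterants) {
        if (stats::runif(1) < composition$presence_prob[[a]]) {
          r <- composition$fraction_range[[a]]
          Fm[i, a] <- stats::runif(1, r[1L], r[2L])
        }
      }
    } else if (stats::runif(1) < composition$confusable_rate) {
      Fm[i, "caffeine"] <- stats::runif(1, 0.20, 0.50)
      Fm[i, "acetaminophen"] <- stats::runif(1, 0.20, 0.50)
    }
    active <- sum(Fm[i, comps])
    excess <- active - 0.95
    if (excess > 0) {                 # rescale adulterants, never the purity
      adl <- sum(Fm[i, adulterants])
      if (adl < excess) stop("composition sampler produced fractions > 1")
      Fm[i, adulterants] <- Fm[i, adulterants] * (adl - excess) / adl
    }
    Fm[i, "cutting_agent"] <- 1 - sum(Fm[i, comps])
  }
  if (any(Fm < 0) || any(abs(rowSums(Fm) - 1) > 1e-9))
    stop("composition sampler produced invalid mass fractions")
  Fm
}

#' Generate a synthetic sample set
#'
#' Draws compositions, mixes component signatures linearly
#' (`spectrum = (fractions x signatures) * scatter + baseline + noise`) and
#' returns the spectra together with annotations carrying the purity and
#' presence flags derived from the true fractions (a compound is flagged
#' present when its fraction exceeds the composition's detection floor).
#' Identical arguments and seed give identical output.
#'
#' @param n number of samples.
#' @param library band library ([component_library()]).
#' @param composition a `composition_model`.
#' @param noise a `noise_model`.
#' @param wavenumbers axis (default [default_axis()]).
#' @param seed RNG seed.
#' @return list with `spectra` (a `spectra_set`), `samples` (a
#'   `sample_table`; true mass fractions in the `"fractions"` attribute).
#' @export
generate_spectra <- function(n, library = component_library(),
                             composition = composition_model(),
                             noise = noise_model(),
                             wavenumbers = default_axis(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- signature_matrix(library, wavenumbers)
  Fm <- sample_composition(n, composition)
  Fm <- Fm[, rownames(S), drop = FALSE]
  p <- length(wavenumbers)
  A <- Fm %*% S
  scatter <- if (noise$scatter_sdlog > 0)
    stats::rlnorm(n, 0, noise$scatter_sdlog) else rep(1, n)
  A <- A * scatter
  if (noise$baseline_amplitude > 0) {
    u <- seq(-1, 1, length.out = p)
    basis <- outer(u, 0:noise$baseline_order, "^")
    coefs <- matrix(stats::rnorm(n * (noise$baseline_order + 1L),
                                 0, noise$baseline_amplitude),
                    n, noise$baseline_order + 1L)
    A <- A + coefs %*% t(basis)
  }
  if (noise$additive_sd > 0)
    A <- A + matrix(stats::rnorm(n * p, 0, noise$additive_sd), n, p)
  ids <- sprintf("SYN%03d", seq_len(n))
  flags <- as.data.frame(Fm[, compound_names(), drop = FALSE] >
                           composition$detection_floor)
  labels <- sample_table(ids, Fm[, "diacetylmorphine"], flags,
                         check_consistency = FALSE)
  attr(labels, "fractions") <- Fm
  list(spectra = spectra_set(A, wavenumbers, ids), samples = labels)
}
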