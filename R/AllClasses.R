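#' @import methods
NULL

#' SpectralSeries: a perturbation-indexed series of 1D spectra
#'
#' Container for a series of spectra measured along an increasing external
#' perturbation trajectory (here: temperature). Rows of the intensity matrix
#' are spectra (one per temperature), columns are wavenumber channels. The
#' wavenumber axis is stored strictly ascending and the temperature axis
#' strictly increasing; readers sort incoming data into this canonical
#' orientation so that all downstream matrix code can assume it.
#'
#' @slot wavenumber numeric vector of length n, strictly increasing, in cm^-1.
#' @slot temperature numeric vector of length k (k >= 2), strictly increasing,
#'   in K.
#' @slot intensity k x n numeric matrix of absorbance values (a.u.);
#'   \code{intensity[i, j]} is the absorbance at \code{temperature[i]},
#'   \code{wavenumber[j]}.
#' @slot meta free-form provenance list (source file, generator parameters,
#'   preprocessing applied, ...).
#'
#' @seealso [spectralSeries()], [readSeries()], [generateSeries()]
#' @export
setClass("SpectralSeries",
  representation(
    wavenumber = "numeric",
    temperature = "numeric",
    intensity = "matrix",
    meta = "list"
  )
)

.validSpectralSeries <- function(object) {
  nu <- object@wavenumber
  tt <- object@temperature
  I <- object@intensity
  msg <- character()
  if (length(nu) < 2L) msg <- c(msg, "need at least 2 wavenumber points")
  if (length(tt) < 2L) msg <- c(msg, "need at least 2 spectra (k >= 2)")
  if (!is.numeric(I)) msg <- c(msg, "intensity must be numeric")
  if (anyNA(nu) || anyNA(tt) || anyNA(I)) msg <- c(msg, "missing values are not allowed")
  if (any(!is.finite(nu)) || any(!is.finite(tt)) || any(!is.finite(I))) {
    msg <- c(msg, "non-finite values are not allowed")
  }
  if (length(nu) >= 2L && any(diff(nu) <= 0)) {
    msg <- c(msg, "wavenumber axis must be strictly increasing")
  }
  if (length(tt) >= 2L && any(diff(tt) <= 0)) {
    msg <- c(msg, "temperature axis must be strictly increasing (duplicate temperatures?)")
  }
  if (nrow(I) != length(tt) || ncol(I) != length(nu)) {
    msg <- c(msg, sprintf(
      "intensity matrix must be k x n = %d x %d, got %d x %d",
      length(tt), length(nu), nrow(I), ncol(I)
    ))
  }
  if (length(msg)) msg else TRUE
}
setValidity("SpectralSeries", .validSpectralSeries)

#' Construct a SpectralSeries
#'
#' Axes are sorted into canonical orientation (ascending wavenumber,
#' increasing temperature) and the intensity matrix is permuted accordingly.
#'
#' @param wavenumber numeric wavenumber axis (cm^-1), length n.
#' @param temperature numeric perturbation axis (K), length k.
#' @param intensity k x n numeric matrix of absorbances.
#' @param meta optional provenance list.
#' @return A validated [SpectralSeries-class] object.
#' @examples
#' s <- spectralSeries(c(1000, 1004), c(250, 260),
#'                     matrix(1:4, 2, 2))
#' nWavenumbers(s)
#' @export
spectralSeries <- function(wavenumber, temperature, intensity, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  temperature <- as.numeric(temperature)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  dimnames(intensity) <- NULL
  onu <- order(wavenumber)
  ot <- order(temperature)
  obj <- new("SpectralSeries",
    wavenumber = wavenumber[onu],
    temperature = temperature[ot],
    intensity = intensity[ot, onu, drop = FALSE],
    meta = meta
  )
  validObject(obj)
  obj
}

#' DynamicSpectra: perturbation-induced deviations from a reference spectrum
#'
#' The dynamic spectrum at temperature T is the measured spectrum minus a
#' reference spectrum.  The reference is arbitrary in 2D-COS; the
#' conventional choice for an upward temperature trajectory is the first
#' (lowest-temperature) spectrum, so that the dynamic row at T_min is
#' exactly zero.
#'
#' @slot wavenumber wavenumber axis (cm^-1).
#' @slot temperature perturbation axis (K).
#' @slot dynamic k x n matrix of dynamic intensities.
#' @slot reference the reference spectrum (length n).
#' @slot referenceMode one of \code{"first"}, \code{"last"}, \code{"mean"},
#'   \code{"zero"}, or \code{"index:i"}.
#'
#' @seealso [dynamicSpectra()]
#' @export
setClass("DynamicSpectra",
  representation(
    wavenumber = "numeric",
    temperature = "numeric",
    dynamic = "matrix",
    reference = "numeric",
    referenceMode = "character"
  )
)

setValidity("DynamicSpectra", function(object) {
  msg <- character()
  k <- length(object@temperature)
  n <- length(object@wavenumber)
  if (nrow(object@dynamic) != k || ncol(object@dynamic) != n) {
    msg <- c(msg, "dynamic matrix dimensions do not match axes")
  }
  if (length(object@reference) != n) msg <- c(msg, "reference length must equal n")
  if (length(object@referenceMode) != 1L) msg <- c(msg, "referenceMode must be a single string")
  mode <- object@referenceMode
  idx <- if (identical(mode, "first")) 1L
         else if (identical(mode, "last")) k
         else if (grepl("^index:", mode)) as.integer(sub("^index:", "", mode))
         else NA_integer_
  if (!is.na(idx) && nrow(object@dynamic) >= idx &&
      any(object@dynamic[idx, ] != 0)) {
    msg <- c(msg, sprintf("dynamic row %d must be exactly zero for reference mode '%s'", idx, mode))
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationMaps: synchronous and asynchronous 2D correlation maps
#'
#' Holds the n x n synchronous map (symmetric, covariance-like, in-phase
#' changes), the n x n asynchronous map (antisymmetric with zero diagonal,
#' out-of-phase changes mediated by the discrete Hilbert transform), and the
#' k x k Hilbert-Noda matrix used to compute the latter.
#'
#' @slot wavenumber wavenumber axis (cm^-1), length n.
#' @slot sync n x n synchronous correlation map.
#' @slot async n x n asynchronous correlation map.
#' @slot noda k x k Hilbert-Noda transformation matrix.
#' @slot k number of spectra in the series.
#'
#' @seealso [correlate2d()], [synchronousMap()], [asynchronousMap()]
#' @export
setClass("CorrelationMaps",
  representation(
    wavenumber = "numeric",
    sync = "matrix",
    async = "matrix",
    noda = "matrix",
    k = "integer"
  )
)

setValidity("CorrelationMaps", function(object) {
  msg <- character()
  n <- length(object@wavenumber)
  if (!all(dim(object@sync) == n)) msg <- c(msg, "sync map must be n x n")
  if (!all(dim(object@async) == n)) msg <- c(msg, "async map must be n x n")
  if (!all(dim(object@noda) == object@k)) msg <- c(msg, "noda matrix must be k x k")
  scale <- max(abs(object@sync))
  if (scale > 0 && max(abs(object@sync - t(object@sync))) > 1e-12 * scale) {
    msg <- c(msg, "sync map must be symmetric (1e-12 relative)")
  }
  if (max(abs(object@async + t(object@async))) > 1e-12 * max(abs(object@async), 1e-300)) {
    msg <- c(msg, "async map must be antisymmetric")
  }
  if (any(diag(object@async) != 0)) msg <- c(msg, "async diagonal must be exactly zero")
  if (any(diag(object@noda) != 0)) msg <- c(msg, "noda diagonal must be exactly zero")
  if (length(msg)) msg else TRUE
})

#' BandSpec: one synthetic vibrational band and its temperature response
#'
#' A unit-height Gaussian or Lorentzian line shape whose amplitude responds
#' to temperature either as a logistic sigmoid (delayed onset at
#' \code{onsetT}, steepness scale \code{responseWidth}) or linearly across
#' the full temperature range.  \code{width} is the half-width at half
#' maximum (HWHM) in cm^-1.  \code{deltaAmplitude} is the signed absorbance
#' change over the full response (negative = band decreases on heating).
#'
#' @slot center band center (cm^-1).
#' @slot width HWHM (cm^-1), > 0.
#' @slot shape \code{"gaussian"} or \code{"lorentzian"}.
#' @slot baseAmplitude absorbance at zero response (a.u.), >= 0.
#' @slot deltaAmplitude signed absorbance change over the full response (a.u.).
#' @slot response \code{"sigmoid"} or \code{"linear"}.
#' @slot onsetT sigmoid midpoint temperature (K).
#' @slot responseWidth sigmoid steepness scale (K), > 0.
#'
#' @seealso [bandSpec()], [bandProfile()]
#' @export
setClass("BandSpec",
  representation(
    center = "numeric",
    width = "numeric",
    shape = "character",
    baseAmplitude = "numeric",
    deltaAmplitude = "numeric",
    response = "character",
    onsetT = "numeric",
    responseWidth = "numeric"
  )
)

setValidity("BandSpec", function(object) {
  msg <- character()
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  if (object@responseWidth <= 0) msg <- c(msg, "responseWidth must be > 0")
  if (!object@shape %in% c("gaussian", "lorentzian")) {
    msg <- c(msg, "shape must be 'gaussian' or 'lorentzian'")
  }
  if (!object@response %in% c("sigmoid", "linear")) {
    msg <- c(msg, "response must be 'sigmoid' or 'linear'")
  }
  if (object@baseAmplitude < 0) msg <- c(msg, "baseAmplitude must be >= 0")
  if (object@baseAmplitude + object@deltaAmplitude < 0) {
    msg <- c(msg, "baseAmplitude + deltaAmplitude must be >= 0 (absorbance never negative)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BandSpec
#'
#' @param center band center (cm^-1).
#' @param width half-width at half maximum (cm^-1).
#' @param shape line shape, \code{"gaussian"} (default) or \code{"lorentzian"}.
#' @param baseAmplitude absorbance at zero response (default 1).
#' @param deltaAmplitude signed absorbance change over the full response
#'   (default 0.2, i.e. 20\% of the default base).
#' @param response \code{"sigmoid"} (default) or \code{"linear"}.
#' @param onsetT sigmoid midpoint (K, default 295).
#' @param responseWidth sigmoid steepness scale (K, default 5).
#' @return A validated [BandSpec-class].
#' @examples
#' bandSpec(1031, width = 10, onsetT = 290)
#' @export
bandSpec <- function(center, width, shape = "gaussian",
                     baseAmplitude = 1, deltaAmplitude = 0.2,
                     response = "sigmoid", onsetT = 295, responseWidth = 5) {
  obj <- new("BandSpec",
    center = as.numeric(center), width = as.numeric(width),
    shape = shape, baseAmplitude = as.numeric(baseAmplitude),
    deltaAmplitude = as.numeric(deltaAmplitude), response = response,
    onsetT = as.numeric(onsetT), responseWidth = as.numeric(responseWidth)
  )
  validObject(obj)
  obj
}

#' SyntheticSpec: full design of a synthetic temperature-series acquisition
#'
#' Defaults emulate a temperature-perturbation FTIR-ATR acquisition: ten
#' spectra from 250 K to 340 K in 10 K steps at 4 cm^-1 resolution.
#'
#' @slot bands list of [BandSpec-class] objects.
#' @slot tMin,tMax,tStep temperature grid (K); \code{tMax - tMin} must be
#'   divisible by \code{tStep}; both endpoints are included.
#' @slot nuMin,nuMax,nuStep wavenumber grid (cm^-1).
#' @slot noiseSigma additive i.i.d. Gaussian noise sd per grid point (a.u.).
#' @slot seed RNG seed for the noise draw.
#'
#' @seealso [syntheticSpec()], [generateSeries()]
#' @export
setClass("SyntheticSpec",
  representation(
    bands = "list",
    tMin = "numeric", tMax = "numeric", tStep = "numeric",
    nuMin = "numeric", nuMax = "numeric", nuStep = "numeric",
    noiseSigma = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (!length(object@bands) || !all(vapply(object@bands, is, TRUE, "BandSpec"))) {
    msg <- c(msg, "bands must be a non-empty list of BandSpec objects")
  }
  if (object@tMin >= object@tMax) msg <- c(msg, "tMin must be < tMax")
  if (object@tStep <= 0) msg <- c(msg, "tStep must be > 0")
  nsteps <- (object@tMax - object@tMin) / object@tStep
  if (abs(nsteps - round(nsteps)) > 1e-9) {
    msg <- c(msg, "(tMax - tMin) must be divisible by tStep")
  }
  if (object@nuStep <= 0) msg <- c(msg, "nuStep must be > 0")
  if (object@nuMin >= object@nuMax) msg <- c(msg, "nuMin must be < nuMax")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticSpec
#'
#' @param bands list of [BandSpec-class] objects (a single BandSpec is
#'   wrapped automatically).
#' @param tMin,tMax,tStep temperature grid in K (defaults 250, 340, 10 —
#'   ten spectra).
#' @param nuMin,nuMax,nuStep wavenumber grid in cm^-1 (defaults 900, 1200, 4).
#' @param noiseSigma additive Gaussian noise sd (a.u., default 0).
#' @param seed integer RNG seed (default 1).
#' @return A validated [SyntheticSpec-class].
#' @examples
#' sp <- syntheticSpec(list(bandSpec(1031, 10), bandSpec(1108, 10, onsetT = 310)))
#' @export
syntheticSpec <- function(bands, tMin = 250, tMax = 340, tStep = 10,
                          nuMin = 900, nuMax = 1200, nuStep = 4,
                          noiseSigma = 0, seed = 1L) {
  if (is(bands, "BandSpec")) bands <- list(bands)
  obj <- new("SyntheticSpec",
    bands = bands, tMin = as.numeric(tMin), tMax = as.numeric(tMax),
    tStep = as.numeric(tStep), nuMin = as.numeric(nuMin),
    nuMax = as.numeric(nuMax), nuStep = as.numeric(nuStep),
    noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed)
  )
  validObject(obj)
  obj
}
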