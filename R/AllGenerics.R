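#' Accessors for spectral containers
#'
#' Accessor generics for the wavenumber axis, the perturbation (temperature)
#' axis, and the intensity/dynamic matrices of the package's S4 containers.
#'
#' @param x a [SpectralSeries-class], [DynamicSpectra-class] or
#'   [CorrelationMaps-class] object.
#' @return \code{wavenumbers} and \code{temperatures} return numeric vectors;
#'   \code{intensities} the k x n intensity matrix; \code{dynamicMatrix} the
#'   k x n dynamic-intensity matrix; \code{referenceSpectrum} the length-n
#'   reference; \code{syncMap}, \code{asyncMap} and \code{nodaMatrix} the
#'   corresponding matrices; \code{nSpectra}/\code{nWavenumbers} integer
#'   counts; \code{seriesMeta} the provenance list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("dynamicMatrix", function(x) standardGeneric("dynamicMatrix"))
#' @rdname accessors
#' @export
setGeneric("referenceSpectrum", function(x) standardGeneric("referenceSpectrum"))
#' @rdname accessors
#' @export
setGeneric("referenceMode", function(x) standardGeneric("referenceMode"))
#' @rdname accessors
#' @export
setGeneric("syncMap", function(x) standardGeneric("syncMap"))
#' @rdname accessors
#' @export
setGeneric("asyncMap", function(x) standardGeneric("asyncMap"))
#' @rdname accessors
#' @export
setGeneric("nodaMatrix", function(x) standardGeneric("nodaMatrix"))
#' @rdname accessors
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))
#' @rdname accessors
#' @export
setGeneric("nWavenumbers", function(x) standardGeneric("nWavenumbers"))
#' @rdname accessors
#' @export
setGeneric("seriesMeta", function(x) standardGeneric("seriesMeta"))

#' @rdname accessors
setMethod("wavenumbers", "SpectralSeries", function(x) x@wavenumber)
#' @rdname accessors
setMethod("temperatures", "SpectralSeries", function(x) x@temperature)
#' @rdname accessors
setMethod("intensities", "SpectralSeries", function(x) x@intensity)
#' @rdname accessors
setMethod("nSpectra", "SpectralSeries", function(x) length(x@temperature))
#' @rdname accessors
setMethod("nWavenumbers", "SpectralSeries", function(x) length(x@wavenumber))
#' @rdname accessors
setMethod("seriesMeta", "SpectralSeries", function(x) x@meta)

#' @rdname accessors
setMethod("wavenumbers", "DynamicSpectra", function(x) x@wavenumber)
#' @rdname accessors
setMethod("temperatures", "DynamicSpectra", function(x) x@temperature)
#' @rdname accessors
setMethod("dynamicMatrix", "DynamicSpectra", function(x) x@dynamic)
#' @rdname accessors
setMethod("referenceSpectrum", "DynamicSpectra", function(x) x@reference)
#' @rdname accessors
setMethod("referenceMode", "DynamicSpectra", function(x) x@referenceMode)
#' @rdname accessors
setMethod("nSpectra", "DynamicSpectra", function(x) length(x@temperature))
#' @rdname accessors
setMethod("nWavenumbers", "DynamicSpectra", function(x) length(x@wavenumber))

#' @rdname accessors
setMethod("wavenumbers", "CorrelationMaps", function(x) x@wavenumber)
#' @rdname accessors
setMethod("syncMap", "CorrelationMaps", function(x) x@sync)
#' @rdname accessors
setMethod("asyncMap", "CorrelationMaps", function(x) x@async)
#' @rdname accessors
setMethod("nodaMatrix", "CorrelationMaps", function(x) x@noda)
#' @rdname accessors
setMethod("nSpectra", "CorrelationMaps", function(x) x@k)
#' @rdname accessors
setMethod("nWavenumbers", "CorrelationMaps", function(x) length(x@wavenumber))

setMethod("show", "SpectralSeries", function(object) {
  cat(sprintf(
    "SpectralSeries: %d spectra x %d channels\n  wavenumber %g..%g cm-1  |  temperature %g..%g K\n",
    nSpectra(object), nWavenumbers(object),
    min(object@wavenumber), max(object@wavenumber),
    min(object@temperature), max(object@temperature)
  ))
  if (length(object@meta)) {
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "DynamicSpectra", function(object) {
  cat(sprintf(
    "DynamicSpectra: %d spectra x %d channels (reference: %s)\n",
    nSpectra(object), nWavenumbers(object), object@referenceMode
  ))
  invisible(object)
})

setMethod("show", "CorrelationMaps", function(object) {
  cat(sprintf(
    "CorrelationMaps: %d x %d (from k = %d spectra)\n  sync  range [%.3g, %.3g]\n  async range [%.3g, %.3g]\n",
    nWavenumbers(object), nWavenumbers(object), object@k,
    min(object@sync), max(object@sync),
    min(object@async), max(object@async)
  ))
  invisible(object)
})

setMethod("show", "BandSpec", function(object) {
  cat(sprintf(
    "BandSpec: %s at %g cm-1 (HWHM %g), A = %g %+g, %s response (onset %g K, width %g K)\n",
    object@shape, object@center, object@width, object@baseAmplitude,
    object@deltaAmplitude, object@response, object@onsetT, object@responseWidth
  ))
  invisible(object)
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d band(s), T %g..%g K step %g, nu %g..%g cm-1 step %g, noise sd %g, seed %d\n",
    length(object@bands), object@tMin, object@tMax, object@tStep,
    object@nuMin, object@nuMax, object@nuStep, object@noiseSigma, object@seed
  ))
  invisible(object)
})
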