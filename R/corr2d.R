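#' Hilbert-Noda transformation matrix
#'
#' The discrete antisymmetric matrix implementing the Hilbert transform
#' across the perturbation index: \code{M[i, i] = 0} and
#' \code{M[i, j] = 1 / (pi * (j - i))} for \code{i != j}.  Row/column indices
#' follow the temperature-sorted order of the spectra (ascending
#' perturbation), which is what gives the asynchronous map its "prior"
#' semantics.
#'
#' @param k number of spectra (integer >= 2).
#' @return a k x k numeric matrix.
#' @examples
#' hilbertNoda(3)[1, 2]  # 1/pi
#' @export
hilbertNoda <- function(k) {
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 2) {
    stop("k must be a single integer >= 2")
  }
  k <- as.integer(k)
  d <- outer(seq_len(k), seq_len(k), function(i, j) j - i)
  M <- ifelse(d == 0L, 0, 1 / (pi * d))
  M
}

#' Dynamic spectra: deviations from a reference spectrum
#'
#' Subtracts a reference spectrum from every spectrum of the series.  The
#' reference is in principle arbitrary; \code{"first"} (the spectrum at
#' T_min, the conventional choice for an upward temperature trajectory) is
#' the default, \code{"last"} uses the spectrum at T_max, \code{"mean"} the
#' pointwise average over all k spectra, \code{"zero"} no subtraction at all
#' (the dynamic matrix then equals the measured intensities), and an integer
#' i selects the i-th spectrum.
#'
#' @param series a [SpectralSeries-class].
#' @param reference \code{"first"}, \code{"last"}, \code{"mean"},
#'   \code{"zero"}, or an integer spectrum index.
#' @return a [DynamicSpectra-class].
#' @examples
#' sim <- generateSeries(syntheticSpec(bandSpec(1031, 10)))
#' dyn <- dynamicSpectra(sim$series)        # row at T_min is exactly zero
#' max(abs(dynamicMatrix(dyn)[1, ]))
#' @export
dynamicSpectra <- function(series, reference = "first") {
  stopifnot(is(series, "SpectralSeries"))
  I <- series@intensity
  k <- nrow(I)
  if (is.numeric(reference)) {
    idx <- as.integer(reference)
    if (length(idx) != 1L || is.na(idx) || idx < 1L || idx > k) {
      stop("reference index must be a single integer in 1..k")
    }
    ref <- I[idx, ]
    mode <- paste0("index:", idx)
  } else {
    mode <- match.arg(reference, c("first", "last", "mean", "zero"))
    ref <- switch(mode,
      first = I[1L, ],
      last = I[k, ],
      mean = colMeans(I),
      zero = rep(0, ncol(I))
    )
  }
  dyn <- sweep(I, 2L, ref, `-`)
  new("DynamicSpectra",
    wavenumber = series@wavenumber,
    temperature = series@temperature,
    dynamic = dyn,
    reference = as.numeric(ref),
    referenceMode = mode
  )
}

#' Synchronous 2D correlation map
#'
#' \code{sync(nu1, nu2) = 1/(k-1) * sum_i dyn(nu1, T_i) * dyn(nu2, T_i)}:
#' a covariance-like measure of in-phase (coincidental) intensity changes.
#' The result is symmetric with a non-negative diagonal (the auto-peaks).
#' Floating-point symmetry is enforced by explicit symmetrization; an
#' asymmetry above 1e-12 relative would indicate an internal error.
#'
#' @param dyn a [DynamicSpectra-class].
#' @return an n x n numeric matrix with wavenumber dimnames.
#' @export
synchronousMap <- function(dyn) {
  stopifnot(is(dyn, "DynamicSpectra"))
  k <- nSpectra(dyn)
  S <- crossprod(dyn@dynamic) / (k - 1)
  scale <- max(abs(S))
  if (scale > 0 && max(abs(S - t(S))) > 1e-12 * scale) {
    stop("internal error: synchronous map asymmetry exceeds 1e-12 relative")
  }
  S <- (S + t(S)) / 2
  dimnames(S) <- list(dyn@wavenumber, dyn@wavenumber)
  S
}

#' Asynchronous 2D correlation map
#'
#' \code{async(nu1, nu2) = 1/(k-1) * sum_i dyn(nu1, T_i) *
#' (sum_j M[i, j] dyn(nu2, T_j))} with M the Hilbert-Noda matrix: a measure
#' of out-of-phase (sequential) intensity changes.  The result is
#' antisymmetric with an exactly zero diagonal; channel pairs with
#' proportional dynamic traces give exactly zero.  The normalization
#' \code{1/(k-1)} sits outside both sums; some literature variants normalize
#' differently, which rescales the map but never changes any sign.
#'
#' @param dyn a [DynamicSpectra-class].
#' @return an n x n numeric matrix with wavenumber dimnames.
#' @export
asynchronousMap <- function(dyn) {
  stopifnot(is(dyn, "DynamicSpectra"))
  k <- nSpectra(dyn)
  if (k == 2L) {
    warning("k = 2 spectra: the asynchronous map is computed but sequential inference from it is unreliable")
  }
  M <- hilbertNoda(k)
  A <- crossprod(dyn@dynamic, M %*% dyn@dynamic) / (k - 1)
  A <- (A - t(A)) / 2
  diag(A) <- 0
  dimnames(A) <- list(dyn@wavenumber, dyn@wavenumber)
  A
}

#' Compute both 2D correlation maps from a series
#'
#' Convenience composition: dynamic spectra against the chosen reference,
#' then the synchronous and asynchronous maps.
#'
#' @param series a [SpectralSeries-class].
#' @param reference reference mode, see [dynamicSpectra()].
#' @return a [CorrelationMaps-class].
#' @examples
#' sim <- generateSeries(syntheticSpec(list(
#'   bandSpec(1000, 10, onsetT = 270), bandSpec(1100, 10, onsetT = 310))))
#' maps <- correlate2d(sim$series)
#' maps
#' @export
correlate2d <- function(series, reference = "first") {
  stopifnot(is(series, "SpectralSeries"))
  if (nWavenumbers(series) > 5000L) {
    warning(sprintf(
      "n = %d channels: dense n x n maps will be large; consider selectRegion()",
      nWavenumbers(series)
    ))
  }
  dyn <- dynamicSpectra(series, reference)
  obj <- new("CorrelationMaps",
    wavenumber = series@wavenumber,
    sync = synchronousMap(dyn),
    async = asynchronousMap(dyn),
    noda = hilbertNoda(nSpectra(series)),
    k = nSpectra(series)
  )
  validObject(obj)
  obj
}

#' Export / import correlation maps
#'
#' \code{writeMaps} writes the synchronous and asynchronous maps as two CSV
#' matrices whose first row and first column carry the wavenumber labels.
#' \code{readMapsCSV} reads such a pair back (the Hilbert-Noda matrix is
#' reconstructed from \code{k}).  \code{saveMaps}/\code{loadMaps} round-trip
#' the full object through a single compressed binary container (RDS),
#' intended for pipeline intermediates rather than archival.
#'
#' @param maps a [CorrelationMaps-class].
#' @param syncPath,asyncPath CSV paths for the two maps.
#' @param k the spectrum count recorded with the maps.
#' @param path RDS path.
#' @return the written paths (invisibly), or the re-read
#'   [CorrelationMaps-class].
#' @export
writeMaps <- function(maps, syncPath, asyncPath) {
  stopifnot(is(maps, "CorrelationMaps"))
  writeLabeled <- function(m, p) {
    fmt <- function(x) sprintf("%.17g", x)
    tab <- cbind(fmt(maps@wavenumber), apply(m, 2L, fmt))
    colnames(tab) <- c("wavenumber_cm-1", fmt(maps@wavenumber))
    con <- file(p, open = "wb")
    on.exit(close(con))
    utils::write.table(tab, con, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
  }
  writeLabeled(maps@sync, syncPath)
  writeLabeled(maps@async, asyncPath)
  invisible(c(syncPath, asyncPath))
}

#' @rdname writeMaps
#' @export
readMapsCSV <- function(syncPath, asyncPath, k) {
  readLabeled <- function(p) {
    df <- utils::read.csv(p, check.names = FALSE)
    nu <- as.numeric(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    dimnames(m) <- list(nu, nu)
    list(nu = nu, m = m)
  }
  s <- readLabeled(syncPath)
  a <- readLabeled(asyncPath)
  stopifnot(identical(s$nu, a$nu))
  obj <- new("CorrelationMaps",
    wavenumber = s$nu, sync = s$m, async = a$m,
    noda = hilbertNoda(k), k = as.integer(k)
  )
  validObject(obj)
  obj
}

#' @rdname writeMaps
#' @export
saveMaps <- function(maps, path) {
  stopifnot(is(maps, "CorrelationMaps"))
  saveRDS(maps, path)
  invisible(path)
}

#' @rdname writeMaps
#' @export
loadMaps <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "CorrelationMaps")) stop("not a CorrelationMaps container: ", path)
  validObject(obj)
  obj
}
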