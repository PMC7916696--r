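#' Read a spectral series from a wide CSV table
#'
#' Native interchange format: column 1 holds the wavenumber axis (header is a
#' free-form label, conventionally \code{wavenumber_cm-1}), columns 2..k+1
#' hold one spectrum each and are headed by their temperature in K.  Rows and
#' columns may arrive in any order; the returned series is sorted into the
#' canonical orientation (ascending wavenumber, increasing temperature).
#'
#' @param path path to a CSV file (comma-separated, '.' decimal, UTF-8,
#'   mandatory header row).
#' @return A validated [SpectralSeries-class].
#' @seealso [writeSeries()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' sim <- generateSeries(syntheticSpec(bandSpec(1031, 10)))
#' writeSeries(sim$series, f)
#' readSeries(f)
#' @export
readSeries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fill = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 3L) stop("need a wavenumber column plus at least 2 temperature columns")
  headers <- names(df)
  tempHeaders <- headers[-1]
  tt <- suppressWarnings(as.numeric(tempHeaders))
  if (anyNA(tt)) {
    stop("temperature column header(s) do not parse as numbers: ",
         paste(tempHeaders[is.na(tt)], collapse = ", "))
  }
  if (anyDuplicated(tt)) {
    stop("duplicate temperature column(s): ",
         paste(unique(tt[duplicated(tt)]), collapse = ", "))
  }
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, headers))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at data row %d, column '%s'",
                 bad[1L], headers[bad[2L]]))
  }
  nu <- num[, 1L]
  if (anyDuplicated(nu)) {
    stop("duplicate wavenumber row(s): ",
         paste(unique(nu[duplicated(nu)]), collapse = ", "))
  }
  # file stores spectra in columns (n x k); the container wants k x n
  spectralSeries(nu, tt, t(num[, -1L, drop = FALSE]),
                 meta = list(source = path))
}

#' Write a spectral series to a wide CSV table
#'
#' Numbers are written with 17 significant digits so that
#' \code{readSeries(writeSeries(s))} reproduces \code{s} to full double
#' precision (exact round trip).  Only the data table is written; \code{meta}
#' is not serialized.
#'
#' @param series a [SpectralSeries-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readSeries()]
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "SpectralSeries"))
  fmt <- function(x) sprintf("%.17g", x)
  tab <- cbind(fmt(series@wavenumber), apply(t(series@intensity), 2L, fmt))
  if (nWavenumbers(series) == 1L) tab <- matrix(tab, nrow = 1L)
  colnames(tab) <- c("wavenumber_cm-1", fmt(series@temperature))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(tab, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a series to a wavenumber window
#'
#' Keeps exactly the grid points inside the closed interval
#' \code{[nuLo, nuHi]}; no resampling.
#'
#' @param series a [SpectralSeries-class].
#' @param nuLo,nuHi window bounds in cm^-1, \code{nuLo < nuHi}.
#' @return the sub-series (a [SpectralSeries-class]).
#' @examples
#' sim <- generateSeries(syntheticSpec(bandSpec(1031, 10),
#'                                     nuMin = 800, nuMax = 1400))
#' selectRegion(sim$series, 900, 1200)
#' @export
selectRegion <- function(series, nuLo, nuHi) {
  stopifnot(is(series, "SpectralSeries"))
  if (!(nuLo < nuHi)) stop("nuLo must be < nuHi")
  keep <- series@wavenumber >= nuLo & series@wavenumber <= nuHi
  if (sum(keep) < 2L) {
    stop(sprintf("window [%g, %g] contains %d grid point(s); need at least 2",
                 nuLo, nuHi, sum(keep)))
  }
  spectralSeries(series@wavenumber[keep], series@temperature,
                 series@intensity[, keep, drop = FALSE],
                 meta = c(series@meta, list(region = c(nuLo, nuHi))))
}

#' Normalize each spectrum of a series
#'
#' Accounts for the effective number of absorbers probed in each acquisition.
#' \code{"band_area"} (default) divides each spectrum by the trapezoidal area
#' of an internal-standard window, by default 1045--1065 cm^-1 around the
#' ~1055 cm^-1 cellulose-backbone band, which is insensitive to the chemistry
#' of interest and so serves as an internal standard; \code{"vector"} divides
#' each spectrum by its Euclidean norm; \code{"none"} is the identity.
#'
#' @param series a [SpectralSeries-class].
#' @param mode \code{"band_area"}, \code{"vector"} or \code{"none"}.
#' @param window length-2 numeric internal-standard window (cm^-1), used by
#'   \code{"band_area"} only; must lie within the grid and contain at least
#'   two grid points.
#' @return the normalized [SpectralSeries-class].
#' @export
normalizeSeries <- function(series, mode = c("band_area", "vector", "none"),
                            window = c(1045, 1065)) {
  stopifnot(is(series, "SpectralSeries"))
  mode <- match.arg(mode)
  if (mode == "none") return(series)
  I <- series@intensity
  if (mode == "vector") {
    nrm <- sqrt(rowSums(I^2))
    if (any(nrm < 1e-300)) stop("zero-norm spectrum; cannot vector-normalize")
    I <- I / nrm
  } else {
    nu <- series@wavenumber
    if (window[1] < nu[1] || window[2] > nu[length(nu)]) {
      stop(sprintf("internal-standard window [%g, %g] lies outside the grid [%g, %g]",
                   window[1], window[2], nu[1], nu[length(nu)]))
    }
    inw <- nu >= window[1] & nu <= window[2]
    if (sum(inw) < 2L) stop("internal-standard window must contain at least 2 grid points")
    area <- apply(I[, inw, drop = FALSE], 1L, function(y) pracma::trapz(nu[inw], y))
    if (any(abs(area) < 1e-300)) stop("zero band area in the internal-standard window")
    I <- I / area
  }
  spectralSeries(series@wavenumber, series@temperature, I,
                 meta = c(series@meta, list(normalized = mode)))
}

#' Baseline-correct each spectrum of a series
#'
#' \code{"linear_endpoints"} subtracts, per spectrum, the straight line
#' through the first and the last grid point of the current region; the
#' corrected endpoints are exactly zero.  \code{"none"} is the identity.
#'
#' @param series a [SpectralSeries-class].
#' @param mode \code{"linear_endpoints"} or \code{"none"}.
#' @return the corrected [SpectralSeries-class].
#' @export
baselineCorrect <- function(series, mode = c("linear_endpoints", "none")) {
  stopifnot(is(series, "SpectralSeries"))
  mode <- match.arg(mode)
  if (mode == "none") return(series)
  nu <- series@wavenumber
  n <- length(nu)
  # Lagrange form: exact at both endpoints, so endpoints become exactly 0
  wR <- (nu - nu[1]) / (nu[n] - nu[1])
  wL <- (nu[n] - nu) / (nu[n] - nu[1])
  I <- series@intensity
  base <- outer(I[, 1L], wL) + outer(I[, n], wR)
  spectralSeries(nu, series@temperature, I - base,
                 meta = c(series@meta, list(baseline = mode)))
}

#' Resample a series onto a uniform temperature grid
#'
#' The discrete Hilbert-Noda formalism assumes spectra sampled at a constant
#' perturbation increment.  Unevenly spaced series are converted by linear
#' interpolation of every wavenumber channel onto a uniform grid with the
#' same endpoints and the same number of spectra k.  A series whose spacing
#' is already uniform is returned unchanged (bit-identical).
#'
#' @param series a [SpectralSeries-class] with k >= 3.
#' @param axis resampling axis; only \code{"temperature"} is supported.
#' @return the resampled [SpectralSeries-class].
#' @export
resampleEven <- function(series, axis = c("temperature")) {
  stopifnot(is(series, "SpectralSeries"))
  axis <- match.arg(axis)
  tt <- series@temperature
  k <- length(tt)
  if (k < 3L) stop("resampling needs k >= 3 spectra")
  steps <- diff(tt)
  if (max(steps) - min(steps) <= 1e-9 * max(abs(tt))) return(series)
  ttNew <- seq(tt[1L], tt[k], length.out = k)
  I <- apply(series@intensity, 2L, function(y) {
    stats::approx(tt, y, xout = ttNew, method = "linear")$y
  })
  spectralSeries(series@wavenumber, ttNew, I,
                 meta = c(series@meta, list(resampled = "temperature")))
}
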