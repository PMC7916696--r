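#' Evaluate one synthetic band on a wavenumber grid at one temperature
#'
#' The band is a unit-height line shape scaled by a temperature-dependent
#' amplitude \code{A(T) = baseAmplitude + deltaAmplitude * r(T)} with
#' response fraction \code{r(T) in [0, 1]}:
#' sigmoid \code{r(T) = 1 / (1 + exp(-(T - onsetT) / responseWidth))},
#' linear \code{r(T) = (T - tRange[1]) / (tRange[2] - tRange[1])}.
#' With \code{width} the HWHM w, the gaussian shape is
#' \code{exp(-log(2) ((nu - c)/w)^2)} and the lorentzian
#' \code{1 / (1 + ((nu - c)/w)^2)}; both are exactly 1 at the band center.
#'
#' @param band a [BandSpec-class].
#' @param nu numeric wavenumber grid (cm^-1).
#' @param temperature a single temperature (K).
#' @param tRange length-2 numeric \code{c(tMin, tMax)}; required for
#'   \code{response = "linear"}, ignored for sigmoids.
#' @return numeric vector of intensities on \code{nu}.
#' @examples
#' b <- bandSpec(1031, 10, onsetT = 290)
#' bandProfile(b, 1031, 290)  # baseAmplitude + deltaAmplitude/2 at midpoint
#' @export
bandProfile <- function(band, nu, temperature, tRange = NULL) {
  stopifnot(is(band, "BandSpec"), length(temperature) == 1L)
  r <- responseFraction(band, temperature, tRange)
  amp <- band@baseAmplitude + band@deltaAmplitude * r
  z <- (nu - band@center) / band@width
  shape <- switch(band@shape,
    gaussian = exp(-log(2) * z^2),
    lorentzian = 1 / (1 + z^2)
  )
  amp * shape
}

responseFraction <- function(band, temperature, tRange = NULL) {
  switch(band@response,
    sigmoid = 1 / (1 + exp(-(temperature - band@onsetT) / band@responseWidth)),
    linear = {
      if (is.null(tRange)) {
        stop("tRange = c(tMin, tMax) is required for a linear response")
      }
      (temperature - tRange[1]) / (tRange[2] - tRange[1])
    }
  )
}

# Effective onset used to derive the ground-truth ordering: the temperature
# at which a band has completed half of its response.
effectiveOnset <- function(band, tRange) {
  switch(band@response,
    sigmoid = band@onsetT,
    linear = mean(tRange)
  )
}

withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic temperature-series with known ground truth
#'
#' Sums all band profiles on the wavenumber grid at each temperature of the
#' grid, adds i.i.d. zero-mean Gaussian noise (sd \code{noiseSigma}), and
#' derives the ground-truth sequential order of band responses from the band
#' parameters alone (never from the noisy matrix).  Identical
#' \code{SyntheticSpec} (including seed) gives bit-identical output.
#'
#' The ground truth lists every unordered pair of responding bands
#' (\code{deltaAmplitude != 0}) once, with \code{center_a < center_b} and a
#' relation of band a with respect to band b: \code{"before"} if a's
#' effective onset is lower, \code{"after"} if higher, \code{"simultaneous"}
#' if the onsets are equal and the response shapes identical, and
#' \code{"ambiguous"} for an onset tie between different response shapes
#' (such pairs carry no defined order).
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements \code{series} ([SpectralSeries-class]) and
#'   \code{truth} (data frame \code{center_a}, \code{center_b},
#'   \code{relation}).
#' @examples
#' sim <- generateSeries(syntheticSpec(list(
#'   bandSpec(1000, 10, onsetT = 270),
#'   bandSpec(1100, 10, onsetT = 310))))
#' sim$truth
#' @export
generateSeries <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  nu <- seq(spec@nuMin, spec@nuMax, by = spec@nuStep)
  tt <- seq(spec@tMin, spec@tMax, by = spec@tStep)
  tRange <- c(spec@tMin, spec@tMax)

  minWidth <- min(vapply(spec@bands, function(b) b@width, 0))
  if (spec@nuStep > minWidth) {
    warning(sprintf(
      "wavenumber step (%g cm-1) exceeds the narrowest band HWHM (%g cm-1); bands may be undersampled",
      spec@nuStep, minWidth
    ))
  }

  I <- matrix(0, nrow = length(tt), ncol = length(nu))
  for (i in seq_along(tt)) {
    for (b in spec@bands) {
      I[i, ] <- I[i, ] + bandProfile(b, nu, tt[i], tRange)
    }
  }
  if (spec@noiseSigma > 0) {
    noise <- withSeed(spec@seed, matrix(
      stats::rnorm(length(I), sd = spec@noiseSigma),
      nrow = nrow(I)
    ))
    I <- I + noise
  }

  series <- spectralSeries(nu, tt, I, meta = list(
    source = "synthetic",
    n_bands = length(spec@bands),
    noise_sigma = spec@noiseSigma,
    seed = spec@seed
  ))
  list(series = series, truth = groundTruth(spec))
}

#' Ground-truth response ordering of a synthetic design
#'
#' @param spec a [SyntheticSpec-class].
#' @return data frame with columns \code{center_a}, \code{center_b},
#'   \code{relation} (see [generateSeries()]).
#' @export
groundTruth <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  tRange <- c(spec@tMin, spec@tMax)
  resp <- Filter(function(b) b@deltaAmplitude != 0, spec@bands)
  resp <- resp[order(vapply(resp, function(b) b@center, 0))]
  out <- list()
  if (length(resp) >= 2L) {
    for (i in seq_len(length(resp) - 1L)) {
      for (j in seq(i + 1L, length(resp))) {
        a <- resp[[i]]; b <- resp[[j]]
        oa <- effectiveOnset(a, tRange); ob <- effectiveOnset(b, tRange)
        rel <- if (oa < ob) "before"
               else if (oa > ob) "after"
               else if (identical(a@response, b@response)) "simultaneous"
               else "ambiguous"
        out[[length(out) + 1L]] <- data.frame(
          center_a = a@center, center_b = b@center,
          relation = rel, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(center_a = numeric(), center_b = numeric(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Serialize / deserialize a SyntheticSpec as a YAML block
#'
#' \code{syntheticSpecToYAML} writes (or returns) a YAML document whose
#' top-level \code{synthetic:} section fully describes the design;
#' \code{syntheticSpecFromYAML} reads one back.  The same block is accepted
#' inside a pipeline configuration (see [readRunConfig()]).
#'
#' @param spec a [SyntheticSpec-class].
#' @param path file to write; if \code{NULL} the YAML string is returned.
#' @return \code{syntheticSpecToYAML}: the YAML string, invisibly if written
#'   to a file. \code{syntheticSpecFromYAML}: a [SyntheticSpec-class].
#' @export
syntheticSpecToYAML <- function(spec, path = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  lst <- list(synthetic = syntheticSpecAsList(spec))
  txt <- yaml::as.yaml(lst)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

syntheticSpecAsList <- function(spec) {
  list(
    bands = lapply(spec@bands, function(b) list(
      center = b@center, width = b@width, shape = b@shape,
      base_amplitude = b@baseAmplitude, delta_amplitude = b@deltaAmplitude,
      response = b@response, onset_T = b@onsetT,
      response_width = b@responseWidth
    )),
    t_min = spec@tMin, t_max = spec@tMax, t_step = spec@tStep,
    nu_min = spec@nuMin, nu_max = spec@nuMax, nu_step = spec@nuStep,
    noise_sigma = spec@noiseSigma, seed = spec@seed
  )
}

#' @rdname syntheticSpecToYAML
#' @param x path to a YAML file, a YAML string, or an already-parsed list
#'   (either the \code{synthetic:} block itself or a document containing one).
#' @export
syntheticSpecFromYAML <- function(x) {
  lst <- if (is.list(x)) x
         else if (length(x) == 1L && file.exists(x)) yaml::read_yaml(x)
         else yaml::yaml.load(x)
  if (!is.null(lst$synthetic)) lst <- lst$synthetic
  syntheticSpecFromList(lst)
}

syntheticSpecFromList <- function(lst) {
  stopifnot(!is.null(lst$bands))
  bands <- lapply(lst$bands, function(b) bandSpec(
    center = b[["center"]], width = b[["width"]],
    shape = b[["shape"]] %||% "gaussian",
    baseAmplitude = b[["base_amplitude"]] %||% 1,
    deltaAmplitude = b[["delta_amplitude"]] %||% 0.2,
    response = b[["response"]] %||% "sigmoid",
    onsetT = b[["onset_T"]] %||% 295,
    responseWidth = b[["response_width"]] %||% 5
  ))
  syntheticSpec(
    bands,
    tMin = lst[["t_min"]] %||% 250, tMax = lst[["t_max"]] %||% 340,
    tStep = lst[["t_step"]] %||% 10,
    nuMin = lst[["nu_min"]] %||% 900, nuMax = lst[["nu_max"]] %||% 1200,
    nuStep = lst[["nu_step"]] %||% 4,
    noiseSigma = lst[["noise_sigma"]] %||% 0,
    seed = lst[["seed"]] %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
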