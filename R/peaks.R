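signLabel <- function(value, eps) {
  if (abs(value) < eps) "~0" else if (value > 0) "+" else "-"
}

# local maxima of a vector; endpoints count when they dominate their neighbor
localMaxima1d <- function(y) {
  n <- length(y)
  if (n == 1L) return(1L)
  up <- c(TRUE, diff(y) > 0)
  down <- c(diff(y) < 0, TRUE)
  which(up & down)
}

# local maxima of a matrix over the 8-neighborhood, restricted to `mask`
localMaxima2d <- function(V, mask) {
  n <- nrow(V)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(idx)
  keep <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    ii <- max(1L, i - 1L):min(n, i + 1L)
    jj <- max(1L, j - 1L):min(n, j + 1L)
    V[i, j] >= max(V[ii, jj])
  }, logical(1L))
  idx[keep, , drop = FALSE]
}

#' Detect auto-peaks on the synchronous diagonal
#'
#' Auto-peaks are local maxima of the synchronous map's diagonal; the
#' diagonal value at nu measures the overall susceptibility of the band at nu
#' to the perturbation and is always non-negative.  Maxima below
#' \code{thresholdFrac} times the largest diagonal value are discarded.
#'
#' @param maps a [CorrelationMaps-class].
#' @param thresholdFrac detection threshold as a fraction of the maximum
#'   diagonal value, in (0, 1); default 0.05.
#' @return data frame of peaks with columns \code{nu1}, \code{nu2},
#'   \code{kind}, \code{sync_sign}, \code{async_sign}, \code{sync_value},
#'   \code{async_value}, \code{prominence} (fraction of the map maximum).
#'   Empty (zero rows) for an all-zero map.
#' @export
detectAutopeaks <- function(maps, thresholdFrac = 0.05) {
  stopifnot(is(maps, "CorrelationMaps"))
  if (!(thresholdFrac > 0 && thresholdFrac < 1)) {
    stop("thresholdFrac must be in (0, 1)")
  }
  d <- diag(maps@sync)
  top <- max(d)
  empty <- data.frame(
    nu1 = numeric(), nu2 = numeric(), kind = character(),
    sync_sign = character(), async_sign = character(),
    sync_value = numeric(), async_value = numeric(),
    prominence = numeric(), stringsAsFactors = FALSE
  )
  if (top <= 0) return(empty)
  cand <- localMaxima1d(d)
  cand <- cand[d[cand] >= thresholdFrac * top]
  if (!length(cand)) return(empty)
  if (any(d[cand] < 0)) {
    stop("internal error: negative synchronous diagonal extremum (auto-peaks are always positive)")
  }
  nu <- maps@wavenumber[cand]
  data.frame(
    nu1 = nu, nu2 = nu, kind = "auto",
    sync_sign = "+", async_sign = "~0",
    sync_value = d[cand], async_value = 0,
    prominence = d[cand] / top, stringsAsFactors = FALSE
  )
}

#' Detect cross-peaks off the diagonal of both maps
#'
#' Candidate cross-peaks are 8-neighborhood local maxima of |sync| and of
#' |async| at least \code{minSeparation} cm^-1 away from the diagonal and
#' above \code{thresholdFrac} times the respective map's off-diagonal
#' maximum.  Candidates from the two maps closer than \code{minSeparation}
#' (Chebyshev distance) are merged, keeping the coordinate of the strongest.
#' Each peak is annotated with both maps' values and signs at its coordinate;
#' a sign whose magnitude is below \code{signEpsilon} times the map maximum
#' is reported as \code{"~0"}.  A map whose overall magnitude is below 1e-10
#' of the joint correlation scale (e.g. the asynchronous map of a perfectly
#' in-phase system) is treated as identically zero: it contributes no
#' candidates and all its signs read \code{"~0"}.  Only the lower triangle
#' (nu1 > nu2) is reported; the mirror peaks follow from
#' symmetry/antisymmetry of the maps.
#'
#' @param maps a [CorrelationMaps-class].
#' @param thresholdFrac detection threshold fraction, in (0, 1); default 0.05.
#' @param minSeparation minimum |nu1 - nu2| in cm^-1 (at least one grid
#'   step); default two grid steps.
#' @param signEpsilon fraction of the map maximum below which a value is
#'   labeled \code{"~0"}; default 0.05.
#' @return data frame of peaks (see [detectAutopeaks()] for columns).
#' @export
detectCrosspeaks <- function(maps, thresholdFrac = 0.05,
                             minSeparation = NULL, signEpsilon = 0.05) {
  stopifnot(is(maps, "CorrelationMaps"))
  if (!(thresholdFrac > 0 && thresholdFrac < 1)) {
    stop("thresholdFrac must be in (0, 1)")
  }
  nu <- maps@wavenumber
  step <- stats::median(diff(nu))
  if (is.null(minSeparation)) minSeparation <- 2 * step
  if (minSeparation < step) stop("minSeparation must be at least the grid spacing")

  dist <- abs(outer(nu, nu, `-`))
  lower <- outer(nu, nu, `>`)          # nu1 > nu2 triangle (row index = nu1)
  offdiag <- dist >= minSeparation & lower

  empty <- data.frame(
    nu1 = numeric(), nu2 = numeric(), kind = character(),
    sync_sign = character(), async_sign = character(),
    sync_value = numeric(), async_value = numeric(),
    prominence = numeric(), stringsAsFactors = FALSE
  )
  if (!any(offdiag)) return(empty)

  # a map whose largest magnitude is below 1e-10 of the overall correlation
  # scale is numerically zero (e.g. the asynchronous map of a perfectly
  # in-phase system); it contributes no candidates and only "~0" signs
  globalTop <- max(abs(maps@sync), abs(maps@async))
  cands <- list()
  for (m in list(abs(maps@sync), abs(maps@async))) {
    top <- max(m[offdiag])
    if (top <= 1e-10 * globalTop) next
    mask <- offdiag & m >= thresholdFrac * top
    hits <- localMaxima2d(m, mask)
    if (nrow(hits)) {
      cands[[length(cands) + 1L]] <- data.frame(
        i = hits[, 1L], j = hits[, 2L],
        strength = m[hits]
      )
    }
  }
  if (!length(cands)) return(empty)
  cand <- do.call(rbind, cands)
  cand <- cand[order(-cand$strength), , drop = FALSE]

  # greedy merge: keep the strongest representative of each cluster
  kept <- cand[0, ]
  for (r in seq_len(nrow(cand))) {
    if (!nrow(kept)) {
      kept <- cand[r, , drop = FALSE]
      next
    }
    cheb <- pmax(abs(nu[kept$i] - nu[cand$i[r]]),
                 abs(nu[kept$j] - nu[cand$j[r]]))
    if (all(cheb >= minSeparation)) kept <- rbind(kept, cand[r, ])
  }

  syncEps <- signEpsilon * max(max(abs(maps@sync)), 1e-10 * globalTop)
  asyncEps <- signEpsilon * max(max(abs(maps@async)), 1e-10 * globalTop)
  sv <- maps@sync[cbind(kept$i, kept$j)]
  av <- maps@async[cbind(kept$i, kept$j)]
  out <- data.frame(
    nu1 = nu[kept$i], nu2 = nu[kept$j], kind = "cross",
    sync_sign = vapply(sv, signLabel, "", eps = syncEps),
    async_sign = vapply(av, signLabel, "", eps = asyncEps),
    sync_value = sv, async_value = av,
    prominence = kept$strength / globalTop,
    stringsAsFactors = FALSE
  )
  out[order(out$nu1, out$nu2), , drop = FALSE]
}

#' Horizontal slice of the asynchronous map
#'
#' Extracts the asynchronous row at a fixed nu2 over all nu1 — the standard
#' view for reading sequential order off a crowded asynchronous map.  nu2 is
#' snapped to the nearest grid point.
#'
#' @param maps a [CorrelationMaps-class].
#' @param nu2 the fixed wavenumber (cm^-1), within the grid range.
#' @return data frame with columns \code{nu1} and \code{async}; the snapped
#'   nu2 is stored in \code{attr(, "nu2")}.
#' @export
sliceAsync <- function(maps, nu2) {
  stopifnot(is(maps, "CorrelationMaps"), length(nu2) == 1L)
  nu <- maps@wavenumber
  if (nu2 < nu[1] || nu2 > nu[length(nu)]) {
    stop(sprintf("nu2 = %g outside the grid range [%g, %g]", nu2, nu[1], nu[length(nu)]))
  }
  j <- which.min(abs(nu - nu2))
  # async[i, j] = async(nu1 = nu[i], nu2 = nu[j]): the slice is column j
  out <- data.frame(nu1 = nu, async = maps@async[, j])
  attr(out, "nu2") <- nu[j]
  out
}
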