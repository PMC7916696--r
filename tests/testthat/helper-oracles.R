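# Independent brute-force oracles for the 2D correlation maps: naive
# elementwise loops over the defining sums, written without any matrix
# algebra so they cannot share a code path with the implementation.

oracleNoda <- function(k) {
  M <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) M[i, j] <- 1 / (pi * (j - i))
    }
  }
  M
}

# dyn: k x n matrix of dynamic intensities
oracleSync <- function(dyn) {
  k <- nrow(dyn); n <- ncol(dyn)
  S <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      acc <- 0
      for (i in seq_len(k)) acc <- acc + dyn[i, a] * dyn[i, b]
      S[a, b] <- acc / (k - 1)
    }
  }
  S
}

oracleAsync <- function(dyn) {
  k <- nrow(dyn); n <- ncol(dyn)
  M <- oracleNoda(k)
  A <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      acc <- 0
      for (i in seq_len(k)) {
        inner <- 0
        for (j in seq_len(k)) inner <- inner + M[i, j] * dyn[j, b]
        acc <- acc + dyn[i, a] * inner
      }
      A[a, b] <- acc / (k - 1)
    }
  }
  A
}

# a random series wrapped in the container, with a "zero" reference so the
# dynamic matrix equals the raw one
randomDynamic <- function(k, n) {
  m <- matrix(stats::rnorm(k * n), k, n)
  s <- spectralSeries(seq_len(n) * 4 + 900, seq_len(k) * 10 + 240, m)
  dynamicSpectra(s, "zero")
}

# standard three-band design used across end-to-end tests: well-separated
# gaussian bands (>= 3 HWHM apart) with staggered onsets (>= 2 response
# widths apart) on the 250-340 K, 10 K step acquisition grid
threeBandSpec <- function(noiseSigma = 0, seed = 1L) {
  syntheticSpec(list(
    bandSpec(1000, 10, onsetT = 270, responseWidth = 5),
    bandSpec(1060, 10, onsetT = 290, responseWidth = 5),
    bandSpec(1120, 10, onsetT = 310, responseWidth = 5)
  ), noiseSigma = noiseSigma, seed = seed)
}
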