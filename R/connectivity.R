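# Weighted phase lag index (wPLI) estimated across trials per frequency
# bin, then averaged within each band. Being built from the imaginary part
# of the cross-spectrum, wPLI is blind to zero-lag (instantaneously mixed)
# coupling, which makes it robust to volume conduction / spatial leakage.

#' Per-trial cross-spectral substrate for connectivity
#'
#' Computes the tapered FFT of every trial and keeps the in-band bins; the
#' cross-spectrum of a pair is `S_k,ij(f) = X_k,i(f) * Conj(X_k,j(f))`
#' (see [cross_spectrum_pair()]).
#'
#' @param epochs An `epochset` extracted with the band's analysis window.
#' @param band One row of [band_specs()].
#' @return An object of class `cross_spectra` holding the complex
#'   trial x channel x bin array, bin frequencies, band and labels.
#' @export
trial_cross_spectra <- function(epochs, band) {
  if (is.data.frame(band)) band <- as.list(band[1, ])
  d <- dim(epochs$trials)
  if (d[1] < 2L) stop("need at least two trials")
  bins <- band_bins(d[3], epochs$fs, band)
  if (length(bins) == 0L) stop("no FFT bin falls inside the band")
  X <- trial_fft(epochs)[, , bins, drop = FALSE]
  structure(list(X = X, freqs = (bins - 1L) * epochs$fs / d[3],
                 band = band, labels = epochs$channel_labels),
            class = "cross_spectra")
}

#' @rdname trial_cross_spectra
#' @param xs A `cross_spectra` object.
#' @param i,j Channel labels or indices.
#' @return `cross_spectrum_pair`: complex trial x bin matrix of
#'   `S_k,ij(f)`.
#' @export
cross_spectrum_pair <- function(xs, i, j) {
  if (is.character(i)) i <- match(i, xs$labels)
  if (is.character(j)) j <- match(j, xs$labels)
  xs$X[, i, , drop = TRUE] * Conj(xs$X[, j, , drop = TRUE])
}

#' Weighted phase lag index matrix
#'
#' Per frequency bin,
#' `wPLI_ij(f) = |sum_k Im S_k,ij(f)| / sum_k |Im S_k,ij(f)|`
#' (0 when the denominator is 0: no imaginary cross-spectral mass means no
#' detectable lagged synchrony); the band value is the mean over in-band
#' bins. The estimator is the plain (non-debiased) wPLI.
#'
#' @param xs A `cross_spectra` object from [trial_cross_spectra()].
#' @return A symmetric channel x channel matrix in `[0, 1]` with `NA`
#'   diagonal, with attributes `band` and `estimator`.
#' @export
wpli <- function(xs) {
  stopifnot(inherits(xs, "cross_spectra"))
  d <- dim(xs$X)  # trials x channels x bins
  nc <- d[2]; nb <- d[3]
  num <- array(0, c(nc, nc, nb))
  den <- array(0, c(nc, nc, nb))
  sabs <- array(0, c(nc, nc, nb))
  for (b in seq_len(nb)) {
    Zr <- Re(xs$X[, , b, drop = TRUE]); Zi <- Im(xs$X[, , b, drop = TRUE])
    if (is.null(dim(Zr))) { Zr <- matrix(Zr, ncol = nc); Zi <- matrix(Zi, ncol = nc) }
    for (k in seq_len(d[1])) {
      O <- outer(Zi[k, ], Zr[k, ])
      ims <- O - t(O)
      num[, , b] <- num[, , b] + ims
      den[, , b] <- den[, , b] + abs(ims)
      mag <- sqrt(Zr[k, ]^2 + Zi[k, ]^2)
      sabs[, , b] <- sabs[, , b] + outer(mag, mag)
    }
  }
  # rounding guard: bins whose imaginary mass sits at machine noise
  # relative to the pair's strongest in-band cross-magnitude carry no
  # lagged coupling; the denominator convention (0/0 -> 0) applies there
  scale <- apply(sabs, c(1, 2), max)
  W <- matrix(0, nc, nc)
  for (b in seq_len(nb)) {
    d_b <- den[, , b]
    d_b[d_b < 1e-11 * scale] <- 0
    w <- matrix(0, nc, nc)
    nz <- d_b > 0
    w[nz] <- abs(num[, , b][nz]) / d_b[nz]
    W <- W + w
  }
  W <- W / nb
  diag(W) <- NA_real_
  dimnames(W) <- list(xs$labels, xs$labels)
  attr(W, "band") <- xs$band$name
  attr(W, "estimator") <- "wPLI (non-debiased, across trials)"
  W
}

#' Aggregate a channel connectivity matrix to region pairs
#'
#' Entry (A, B), A != B, is the mean of `W[i, j]` over all channel pairs
#' with channel i in region A and channel j in region B. Within-region
#' channel pairs are never used; region pairs with no sampled channel pair
#' are `NA` (regions not covered by the implantation).
#'
#' @param W Symmetric channel matrix from [wpli()].
#' @param map Channel map (`channel_label`, `roi`).
#' @return Symmetric region x region matrix with `NA` diagonal.
#' @export
aggregate_pairs_to_roi <- function(W, map) {
  roi <- map$roi[match(rownames(W), map$channel_label)]
  rois <- unique(roi[!is.na(roi)])
  if (length(rois) < 2L) stop("channel map covers fewer than two regions")
  nr <- length(rois)
  out <- matrix(NA_real_, nr, nr, dimnames = list(rois, rois))
  for (a in seq_len(nr - 1L)) {
    for (b in (a + 1L):nr) {
      ia <- which(roi == rois[a]); ib <- which(roi == rois[b])
      vals <- W[ia, ib, drop = FALSE]
      if (length(vals) > 0L && any(!is.na(vals))) {
        out[a, b] <- out[b, a] <- mean(vals, na.rm = TRUE)
      }
    }
  }
  for (at in c("band", "estimator")) attr(out, at) <- attr(W, at)
  out
}
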