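# Band-averaged spectral measures computed from the tapered adaptive
# windows. FFT bins are assigned to a band when the bin center lies in
# [f_low, f_high) -- half-open so the shared band edges (4, 8, 13 Hz) are
# counted once.

band_bins <- function(n, fs, band) {
  f <- (seq_len(n) - 1L) * fs / n
  which(f >= band$f_low & f < band$f_high & f <= fs / 2)
}

trial_fft <- function(epochs) {
  d <- dim(epochs$trials)
  X <- array(0i, dim = d)
  for (k in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      X[k, c, ] <- stats::fft(epochs$trials[k, c, ])
    }
  }
  X
}

taper_energy <- function(epochs) {
  if (is.null(epochs$window)) dim(epochs$trials)[3]
  else sum(epochs$window$taper^2)
}

#' Band power spectral density per channel
#'
#' One-sided periodogram density of each tapered trial,
#' `2 |X(f)|^2 / (fs * sum(taper^2))`, averaged across trials and then
#' across the FFT bins whose centers fall inside the band.
#'
#' @param epochs An `epochset` extracted with the band's analysis window.
#' @param band One row of [band_specs()].
#' @return Named numeric vector, one power density (uV^2/Hz) per channel.
#' @export
band_psd <- function(epochs, band) {
  if (is.data.frame(band)) band <- as.list(band[1, ])
  if (!is.null(epochs$window) &&
      abs(epochs$window$band$f_low - band$f_low) > 1e-9) {
    stop("epochs were extracted with a different band's window")
  }
  d <- dim(epochs$trials)
  bins <- band_bins(d[3], epochs$fs, band)
  if (length(bins) == 0L) stop("no FFT bin falls inside the band")
  X <- trial_fft(epochs)
  norm <- epochs$fs * taper_energy(epochs)
  out <- vapply(seq_len(d[2]), function(c) {
    mean(2 * Mod(X[, c, bins, drop = FALSE])^2 / norm)
  }, numeric(1))
  names(out) <- epochs$channel_labels
  out
}

#' Band inter-trial coherence per channel
#'
#' Per FFT bin, the resultant length of the per-trial unit phase vectors,
#' `|mean_k exp(i arg X_k(f))|`, averaged over the in-band bins.
#'
#' @inheritParams band_psd
#' @return Named numeric vector in `[0, 1]`, one value per channel.
#' @export
band_itc <- function(epochs, band) {
  if (is.data.frame(band)) band <- as.list(band[1, ])
  d <- dim(epochs$trials)
  if (d[1] < 2L) stop("ITC needs at least two trials")
  bins <- band_bins(d[3], epochs$fs, band)
  if (length(bins) == 0L) stop("no FFT bin falls inside the band")
  X <- trial_fft(epochs)
  out <- vapply(seq_len(d[2]), function(c) {
    Z <- X[, c, bins, drop = FALSE]
    m <- Mod(Z); m[m == 0] <- 1
    mean(Mod(apply(Z / m, c(2, 3), mean)))
  }, numeric(1))
  names(out) <- epochs$channel_labels
  out
}

#' Aggregate per-channel values to regions
#'
#' Region value = arithmetic mean of the channels mapped to that region.
#' Channels absent from the map are excluded; regions with no mapped
#' channel are absent from the output.
#'
#' @param values Named numeric vector (names are channel labels).
#' @param map Channel map data.frame (`channel_label`, `roi`).
#' @return Named numeric vector, one value per region.
#' @export
aggregate_units_to_roi <- function(values, map) {
  if (nrow(map) == 0L) stop("empty channel map")
  roi <- map$roi[match(names(values), map$channel_label)]
  keep <- !is.na(roi)
  if (!any(keep)) {
    warning("no channel is mapped to a region")
    return(stats::setNames(numeric(0), character(0)))
  }
  agg <- tapply(values[keep], roi[keep], mean)
  stats::setNames(as.numeric(agg), dimnames(agg)[[1]])[unique(roi[keep])]
}
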