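#' Canonical frequency bands
#'
#' @return data.frame with columns `name`, `f_low`, `f_high` for the four
#'   canonical bands: delta 1-4 Hz, theta 4-8 Hz, alpha 8-13 Hz,
#'   beta 13-30 Hz.
#' @export
band_specs <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             f_low = c(1, 4, 8, 13), f_high = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

round_half_up <- function(x) floor(x + 0.5)

#' Tukey (tapered cosine) window
#'
#' @param n Window length in samples.
#' @param r Cosine fraction in `[0, 1]` (0 = rectangular, 1 = Hann).
#' @return Numeric vector of length `n`, maximum 1.
#' @export
tukey_window <- function(n, r = 0.25) {
  stopifnot(n >= 1, r >= 0, r <= 1)
  if (n == 1L) return(1)
  k <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- k < r / 2
  hi <- k > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * k[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * k[hi] / r - 2 / r + 1)))
  w
}

#' Band-adaptive analysis window
#'
#' The analysis window accommodates five cycles of the band's lowest
#' frequency (e.g. 5 s for delta 1-4 Hz) and is positioned so that the
#' discharge peak falls at 3/8 of the window length, leaving more samples
#' after the discharge than before. A Tukey taper (cosine fraction
#' `tukey_r`) is used so that the flat top covers the peak.
#'
#' @param band One row of [band_specs()] (or a list with `name`, `f_low`,
#'   `f_high`).
#' @param fs Sampling rate in Hz; must exceed `2 * f_high`.
#' @param tukey_r Tukey cosine fraction, default 0.25.
#' @return An object of class `analysis_window` with `n_samples`,
#'   `peak_index` (1-based sample at which the marker sits), `taper`, and
#'   the band.
#' @export
build_window <- function(band, fs, tukey_r = 0.25) {
  if (is.data.frame(band)) band <- as.list(band[1, ])
  if (!is.finite(band$f_low) || band$f_low <= 0 || band$f_low >= band$f_high) {
    stop("invalid band")
  }
  if (fs <= 2 * band$f_high) stop("fs must exceed twice the band's f_high")
  n <- round_half_up(fs * 5 / band$f_low)
  peak <- round_half_up(3 / 8 * n)
  structure(list(band = band, fs = fs, n_samples = as.integer(n),
                 peak_index = as.integer(peak),
                 taper = tukey_window(n, tukey_r)),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> %s [%g-%g Hz]: %d samples @ %g Hz, peak at %d\n",
              x$band$name, x$band$f_low, x$band$f_high, x$n_samples, x$fs,
              x$peak_index))
  invisible(x)
}

new_epochset <- function(trials, condition, window, fs, t0, channel_labels) {
  structure(list(trials = trials, condition = condition, window = window,
                 fs = fs, t0 = t0, channel_labels = channel_labels),
            class = "epochset")
}

#' @export
print.epochset <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<epochset> %s: %d trial(s) x %d channel(s) x %d samples @ %g Hz\n",
              x$condition, d[1], d[2], d[3], x$fs))
  invisible(x)
}

n_trials <- function(ep) dim(ep$trials)[1]

#' Extract tapered, marker-locked epochs
#'
#' Slices the recording so that each event marker sits at the window's peak
#' sample and multiplies every trial by the window taper. Trials that would
#' cross the recording edges are dropped; if more than `n_keep` survive, a
#' seeded uniform subsample of exactly `n_keep` trials is returned (used to
#' balance trial counts between conditions).
#'
#' @param rec A preprocessed [recording()].
#' @param events Event data.frame (`onset_s`, `condition`, `label`).
#' @param window An [build_window()] result.
#' @param condition Which condition to extract (`"IED"` or `"no_IED"`).
#' @param n_keep Optional cap on the number of trials.
#' @param seed Seed for the balancing subsample.
#' @return An `epochset` (trial x channel x sample array).
#' @export
extract_epochs <- function(rec, events, window, condition,
                           n_keep = NULL, seed = 1L) {
  ev <- events[events$condition == condition, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events of condition ", condition)
  n <- window$n_samples
  marker <- round_half_up(ev$onset_s * rec$fs) + 1L
  start <- marker - window$peak_index + 1L
  ok <- start >= 1L & (start + n - 1L) <= ncol(rec$data)
  starts <- start[ok]
  if (length(starts) == 0L) stop("no surviving events of condition ", condition)
  if (!is.null(n_keep) && length(starts) > n_keep) {
    starts <- sort(with_seed(seed, sample(starts, n_keep)))
  }
  nc <- nrow(rec$data)
  trials <- array(0, dim = c(length(starts), nc, n))
  for (k in seq_along(starts)) {
    seg <- rec$data[, starts[k] + 0:(n - 1L), drop = FALSE]
    trials[k, , ] <- sweep(seg, 2L, window$taper, `*`)
  }
  new_epochset(trials, condition, window, rec$fs,
               t0 = -(window$peak_index - 1L) / rec$fs, rec$labels)
}

#' Extract fixed wide epochs for time-frequency analysis
#'
#' Discharge trials span -2 to +3 s around the intracranial discharge peak;
#' control trials span -2.5 to +2.5 s around their marker. No taper is
#' applied: wavelet edge effects are handled through the cone of influence.
#'
#' @inheritParams extract_epochs
#' @return An `epochset` with `t0` giving the time of the first sample
#'   relative to the marker.
#' @export
extract_tf_epochs <- function(rec, events, condition,
                              n_keep = NULL, seed = 1L) {
  span <- if (condition == "IED") c(-2, 3) else c(-2.5, 2.5)
  ev <- events[events$condition == condition, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events of condition ", condition)
  n <- as.integer(round((span[2] - span[1]) * rec$fs))
  marker <- round_half_up(ev$onset_s * rec$fs) + 1L
  start <- marker + as.integer(round(span[1] * rec$fs))
  ok <- start >= 1L & (start + n - 1L) <= ncol(rec$data)
  starts <- start[ok]
  if (length(starts) == 0L) stop("no surviving events of condition ", condition)
  if (!is.null(n_keep) && length(starts) > n_keep) {
    starts <- sort(with_seed(seed, sample(starts, n_keep)))
  }
  nc <- nrow(rec$data)
  trials <- array(0, dim = c(length(starts), nc, n))
  for (k in seq_along(starts)) {
    trials[k, , ] <- rec$data[, starts[k] + 0:(n - 1L), drop = FALSE]
  }
  new_epochset(trials, condition, window = NULL, rec$fs,
               t0 = span[1], rec$labels)
}

#' Select a single channel from an epoch set
#'
#' @param epochs An `epochset`.
#' @param channel Channel label or index.
#' @return An `epochset` with one channel.
#' @export
epochs_channel <- function(epochs, channel) {
  i <- if (is.character(channel)) match(channel, epochs$channel_labels)
       else as.integer(channel)
  if (is.na(i)) stop("channel not found: ", channel)
  epochs$trials <- epochs$trials[, i, , drop = FALSE]
  epochs$channel_labels <- epochs$channel_labels[i]
  epochs
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
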