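# Squared magnitude response |H(e^jw)|^2 of a digital IIR filter on the
# n-point FFT grid (both spectral halves). Multiplying a spectrum by this
# applies the filter forward and backward (zero phase); on long continuous
# recordings this matches filtfilt away from the edges.
iir_mag2 <- function(filt, n) {
  w <- 2 * pi * (seq_len(n) - 1L) / n
  z <- exp(-1i * w)
  horner <- function(cf) {
    acc <- rep(0i, n)
    for (c in cf) acc <- acc * z + c
    acc
  }
  Mod(horner(filt$b) / horner(filt$a))^2
}

# Apply a zero-phase (forward-backward) IIR filter to all channels at once
# via the FFT.
zp_filter <- function(data, filt) {
  n <- ncol(data)
  G <- iir_mag2(filt, n)
  X <- stats::mvfft(t(data))
  t(Re(stats::mvfft(X * G, inverse = TRUE))) / n
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a 4th-order Butterworth band-pass applied
#' forward and backward, i.e. zero phase distortion and an effective
#' 8th-order magnitude response. The forward-backward pass is applied in
#' the frequency domain (all channels at once); on continuous recordings
#' this is identical to `filtfilt` away from the recording edges.
#'
#' @param rec A [recording()].
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @return Filtered [recording()].
#' @export
bandpass <- function(rec, low = 1, high = 35) {
  stopifnot(inherits(rec, "recording"))
  if (high >= rec$fs / 2) stop("band edge at or above Nyquist")
  if (low <= 0 || low >= high) stop("invalid band edges")
  bf <- signal::butter(4, c(low, high) / (rec$fs / 2), type = "pass")
  rec$data <- zp_filter(rec$data, bf)
  rec
}

#' Downsample with anti-alias filtering
#'
#' Applies a zero-phase 8th-order Chebyshev type-I low-pass at 0.8 times the
#' output Nyquist, then resamples. Integer decimation factors take every
#' q-th sample; rational ratios are interpolated on the new sample grid with
#' a natural cubic spline (the signal is already band-limited well below the
#' new Nyquist). Output length is `floor(n * fs_out / fs)`.
#'
#' @param rec A [recording()].
#' @param fs_out Target sampling rate in Hz.
#' @return Downsampled [recording()].
#' @export
downsample <- function(rec, fs_out = 200) {
  stopifnot(inherits(rec, "recording"))
  if (fs_out > rec$fs) stop("fs_out exceeds input sampling rate")
  if (fs_out == rec$fs) return(rec)
  n <- ncol(rec$data)
  cf <- signal::cheby1(8, 0.05, 0.8 * fs_out / rec$fs)
  filt <- zp_filter(rec$data, cf)
  n_out <- floor(n * fs_out / rec$fs)
  q <- rec$fs / fs_out
  if (abs(q - round(q)) < 1e-9) {
    idx <- 1L + round(q) * (seq_len(n_out) - 1L)
    rec$data <- filt[, idx, drop = FALSE]
  } else {
    t_in <- (seq_len(n) - 1L) / rec$fs
    t_out <- (seq_len(n_out) - 1L) / fs_out
    rec$data <- t(apply(filt, 1, function(ch) {
      stats::spline(t_in, ch, xout = t_out, method = "natural")$y
    }))
  }
  rec$fs <- fs_out
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' each output sample has zero mean over channels.
#'
#' @param rec A [recording()] with at least two channels.
#' @return Re-referenced [recording()].
#' @export
common_average <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) < 2L) stop("common average needs >= 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "common_average"
  rec
}

#' Bipolar derivation for depth-electrode recordings
#'
#' Forms the difference between contacts adjacent on the same shaft. A pair
#' is retained only if at least one member lies in gray matter. The pair
#' label is `"A1-A2"`; its region is the region of the gray-matter member,
#' and when both members are gray matter the deeper contact (lower contact
#' index) wins.
#'
#' @param rec An intracranial [recording()] whose `annotations` carry
#'   `shaft`, `contact`, `gray_matter` and `roi` columns.
#' @return A bipolar [recording()]; annotations keep the resolved region.
#' @export
bipolar <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  an <- rec$annotations
  if (is.null(an) || !all(c("shaft", "contact", "gray_matter") %in% names(an))) {
    stop("bipolar derivation needs shaft/contact/gray_matter annotations")
  }
  rows <- list(); dat <- list()
  for (sh in unique(an$shaft)) {
    idx <- which(an$shaft == sh)
    idx <- idx[order(an$contact[idx])]
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      if (an$contact[j] != an$contact[i] + 1L) next  # non-adjacent gap
      if (!(an$gray_matter[i] || an$gray_matter[j])) next
      roi <- if (an$gray_matter[i] && an$gray_matter[j]) {
        an$roi[i]                       # deeper (lower-index) contact
      } else if (an$gray_matter[i]) an$roi[i] else an$roi[j]
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0(rec$labels[i], "-", rec$labels[j]),
        shaft = sh, contact = an$contact[i], gray_matter = TRUE,
        roi = roi, stringsAsFactors = FALSE)
      dat[[length(dat) + 1L]] <- rec$data[i, ] - rec$data[j, ]
    }
  }
  if (length(dat) == 0L) stop("no bipolar pair retained")
  an2 <- do.call(rbind, rows)
  recording(do.call(rbind, dat), fs = rec$fs, labels = an2$label,
            modality = "intracranial",
            annotations = an2[, c("shaft", "contact", "gray_matter", "roi")],
            reference = "bipolar")
}

#' Standard preprocessing chain
#'
#' Downsamples to 200 Hz, band-pass filters 1-35 Hz, then re-references:
#' common average for scalp recordings, bipolar derivation for intracranial
#' recordings. Channels listed in `bad_channels` are dropped first.
#'
#' @param rec A [recording()].
#' @param fs_out Target rate (default 200 Hz).
#' @param low,high Filter band (default 1-35 Hz).
#' @param reref Re-referencing scheme; default follows the modality.
#' @param bad_channels Channel labels to drop before processing.
#' @return Preprocessed [recording()].
#' @export
preprocess <- function(rec, fs_out = 200, low = 1, high = 35,
                       reref = NULL, bad_channels = NULL) {
  if (!is.null(bad_channels)) {
    keep <- !(rec$labels %in% bad_channels)
    if (!any(keep)) stop("all channels marked bad")
    rec$data <- rec$data[keep, , drop = FALSE]
    rec$labels <- rec$labels[keep]
    rec$modality <- rec$modality[keep]
    if (!is.null(rec$annotations)) {
      rec$annotations <- rec$annotations[keep, , drop = FALSE]
    }
  }
  rec <- downsample(rec, fs_out)
  rec <- bandpass(rec, low, high)
  if (is.null(reref)) {
    reref <- if (all(rec$modality == "intracranial")) "bipolar"
             else "common_average"
  }
  switch(reref,
         common_average = common_average(rec),
         bipolar = bipolar(rec),
         none = rec,
         stop("unknown reref scheme: ", reref))
}
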