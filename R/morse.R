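# Generalized Morse wavelet (symmetry gamma = 3, time-bandwidth P^2 = 40),
# evaluated in the frequency domain. The response is peak-normalized to 2 at
# the center frequency, so the analytic coefficient of a unit-amplitude
# sinusoid has magnitude 1.

#' Log-spaced wavelet frequency axis
#'
#' @param fmin,fmax Frequency limits in Hz (default 1-40).
#' @param voices Voices per octave (default 10).
#' @return Strictly increasing frequency vector.
#' @export
morse_freqs <- function(fmin = 1, fmax = 40, voices = 10) {
  2^(seq(log2(fmin), log2(fmax) + 1e-12, by = 1 / voices))
}

morse_hat <- function(r, gamma = 3, tbw = 40) {
  beta <- tbw / gamma
  h <- numeric(length(r))
  pos <- r > 0
  h[pos] <- 2 * exp(beta * log(r[pos]) - (beta / gamma) * (r[pos]^gamma - 1))
  h
}

#' Morse wavelet transform of a single trial
#'
#' FFT-based analytic wavelet transform on a log-spaced frequency axis
#' (10 voices/octave, 1-40 Hz by default), using the generalized Morse
#' wavelet with symmetry 3 and time-bandwidth 40.
#'
#' @param x Numeric vector (one channel of one trial).
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies (default [morse_freqs()]).
#' @param gamma,tbw Morse symmetry and time-bandwidth parameters.
#' @return List with `coef` (complex `length(freqs)` x `length(x)` matrix),
#'   `freqs`, and `coi_halfwidth_s` (per-frequency half-width of the cone
#'   of influence, the e-folding time of the wavelet envelope).
#' @export
morse_transform <- function(x, fs, freqs = morse_freqs(),
                            gamma = 3, tbw = 40) {
  n <- length(x)
  if (n < fs / min(freqs)) {
    stop("trial shorter than one cycle of the lowest analysis frequency")
  }
  X <- stats::fft(x)
  fgrid <- (seq_len(n) - 1L) * fs / n
  fgrid[fgrid > fs / 2] <- 0     # negative-frequency bins: zeroed below
  coef <- matrix(0i, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    h <- morse_hat(fgrid / freqs[i], gamma, tbw)
    coef[i, ] <- stats::fft(X * h, inverse = TRUE) / n
  }
  list(coef = coef, freqs = freqs,
       coi_halfwidth_s = morse_coi_halfwidth(freqs, gamma, tbw))
}

# e-folding time of the wavelet's temporal envelope at 1 Hz, scaled as 1/f.
morse_coi_halfwidth <- function(freqs, gamma = 3, tbw = 40) {
  t1 <- morse_efold_1hz(gamma, tbw)
  t1 / freqs
}

morse_efold_1hz <- local({
  cache <- list()
  function(gamma, tbw) {
    key <- paste(gamma, tbw)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fs <- 64; n <- 4096L
    fgrid <- (seq_len(n) - 1L) * fs / n
    fgrid[fgrid > fs / 2] <- 0
    h <- morse_hat(fgrid / 1, gamma, tbw)
    psi <- stats::fft(h, inverse = TRUE) / n
    env <- Mod(psi)
    drop_idx <- which(env[seq_len(n %/% 2)] < env[1] / exp(1))[1]
    t1 <- (drop_idx - 1L) / fs
    cache[[key]] <<- t1
    t1
  }
})

new_tfmap <- function(values, freqs, times, coi_halfwidth_s, kind) {
  stopifnot(nrow(values) == length(freqs), ncol(values) == length(times))
  structure(list(values = values, freqs = freqs, times = times,
                 coi_halfwidth_s = coi_halfwidth_s, kind = kind),
            class = "tfmap")
}

#' @export
print.tfmap <- function(x, ...) {
  cat(sprintf("<tfmap:%s> %d freqs [%.3g-%.3g Hz] x %d times [%.3g-%.3g s]\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Logical mask of pixels inside the cone of influence
#'
#' @param map A `tfmap`.
#' @return Logical matrix, `TRUE` where the estimate is unaffected by the
#'   epoch edges.
#' @export
coi_mask <- function(map) {
  tmin <- min(map$times); tmax <- max(map$times)
  outer(map$coi_halfwidth_s, map$times,
        function(hw, t) (t - tmin) >= hw & (tmax - t) >= hw)
}

tf_times <- function(epochs) {
  n <- dim(epochs$trials)[3]
  epochs$t0 + (seq_len(n) - 1L) / epochs$fs
}

# Wavelet power/phasor accumulation over the trials of a single-channel
# epoch set.
tf_accumulate <- function(epochs, freqs) {
  stopifnot(dim(epochs$trials)[2] == 1L)
  nt <- n_trials(epochs)
  n <- dim(epochs$trials)[3]
  pow <- matrix(0, length(freqs), n)
  phasor <- matrix(0i, length(freqs), n)
  coi_hw <- NULL
  for (k in seq_len(nt)) {
    w <- morse_transform(epochs$trials[k, 1, ], epochs$fs, freqs)
    coi_hw <- w$coi_halfwidth_s
    pow <- pow + Mod(w$coef)^2
    m <- Mod(w$coef); m[m == 0] <- 1
    phasor <- phasor + w$coef / m
  }
  list(mean_power = pow / nt, mean_phasor = phasor / nt, coi_hw = coi_hw)
}

#' Per-frequency baseline power of an epoch set
#'
#' Mean wavelet power over all trials and time points, per frequency. Used
#' as the common decibel reference for both conditions' ERSP maps (the
#' control condition then reads ~0 dB, and any common baseline cancels in
#' the paired condition contrast).
#'
#' @param epochs Single-channel `epochset`.
#' @param freqs Wavelet frequency axis.
#' @return Numeric vector, one mean power per frequency.
#' @export
tf_baseline_power <- function(epochs, freqs = morse_freqs()) {
  rowMeans(tf_accumulate(epochs, freqs)$mean_power)
}

#' Event-related spectral perturbation
#'
#' `ERSP(f, t) = 10 log10(mean_trials |W(f, t)|^2 / baseline(f))`, in dB.
#'
#' @param epochs Single-channel `epochset`.
#' @param baseline_power Positive per-frequency baseline vector
#'   (see [tf_baseline_power()]).
#' @param freqs Wavelet frequency axis.
#' @return A `tfmap` of kind `"ersp"`.
#' @export
ersp <- function(epochs, baseline_power, freqs = morse_freqs()) {
  if (n_trials(epochs) < 1L) stop("need at least one trial")
  if (any(baseline_power <= 0)) stop("baseline power must be positive")
  acc <- tf_accumulate(epochs, freqs)
  vals <- 10 * log10(sweep(acc$mean_power, 1L, baseline_power, `/`))
  new_tfmap(vals, freqs, tf_times(epochs), acc$coi_hw, "ersp")
}

#' Inter-trial (phase) coherence
#'
#' `ITC(f, t) = |mean_k exp(i arg W_k(f, t))|`, the resultant length of the
#' per-trial unit phase vectors; 1 for perfectly phase-locked trials,
#' ~`sqrt(pi/4)/sqrt(N)` for N trials with independent uniform phases.
#'
#' @param epochs Single-channel `epochset` with at least two trials.
#' @param freqs Wavelet frequency axis.
#' @return A `tfmap` of kind `"itc"` with values in `[0, 1]`.
#' @export
itc <- function(epochs, freqs = morse_freqs()) {
  if (n_trials(epochs) < 2L) stop("ITC needs at least two trials")
  acc <- tf_accumulate(epochs, freqs)
  new_tfmap(Mod(acc$mean_phasor), freqs, tf_times(epochs), acc$coi_hw, "itc")
}
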