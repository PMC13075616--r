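# Synthetic multi-patient cohort generator. Each "patient" is a pair of
# simultaneous recordings -- depth contacts sampling a set of region sources
# and scalp sensors observing a depth-attenuated linear mixture of the same
# sources -- plus an event list of discharge (IED) and control (no-IED)
# markers. The generator programs a recoverable ground truth: a
# spike-and-slow-wave transient in one medial temporal source that is kept
# below the scalp noise floor, and band-limited source-pair coupling with a
# known constant phase lag whose gain increases during discharge epochs.

#' Configuration of the synthetic cohort
#'
#' Defaults encode the study conditions the pipeline is designed for: nine
#' patients, an equal number of epochs per condition, a hippocampal
#' discharge source invisible on the scalp (peak below half a background
#' SD), 12 core regions sampled in every patient plus two patient-specific
#' extra regions (so the "sampled in at least five patients" gate retains
#' exactly the 12 core regions), and per-band coupled cliques plus a
#' stationary interhemispheric backbone (see [coupling_cliques()]) whose
#' clique gain rises during discharge epochs.
#'
#' @param n_patients Number of synthetic patients.
#' @param n_epochs_per_condition Markers per condition per patient.
#' @param fs_raw Acquisition sampling rate in Hz.
#' @param duration Recording duration in seconds.
#' @param source_roi_labels Region labels of the core sources (one source
#'   per region), in the ipsi/contra namespace of [load_atlas()].
#' @param extra_roi_pool Regions cycled through as the two patient-specific
#'   extra sources.
#' @param ied_source_label Region carrying the discharge transient.
#' @param ied_waveform List: `spike_width_ms`, `spike_amplitude` (uV),
#'   `slow_wave_width_ms`, `slow_wave_amplitude` (uV).
#' @param coupling_spec List of couplings, each a list with `pair`
#'   (two region labels), `band` (name in [band_specs()]), `phase_lag_rad`
#'   in (-pi, pi], `gain_noIED`, `gain_IED` (uV amplitude of the shared
#'   oscillation; gains must be >= 0).
#' @param n_scalp Number of scalp sensors.
#' @param scalp_negative_margin Ratio of the scalp discharge peak to the
#'   scalp background SD; must be < 1 (enforced by rescaling the mixing
#'   column of the discharge source).
#' @param noise_exponent Spectral slope of the 1/f^a background noise.
#' @param noise_sd Background SD per source (uV).
#' @param sensor_noise_sd Scalp sensor noise SD (uV).
#' @param seed Root seed; all per-patient randomness is expanded from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 9L,
                         n_epochs_per_condition = 20L,
                         fs_raw = 400,
                         duration = 270,
                         source_roi_labels = c(
                           "Lateralorbitofrontal_ipsi", "Lateralorbitofrontal_contra",
                           "Rostralmiddlefrontal_ipsi", "Rostralmiddlefrontal_contra",
                           "Inferiortemporal_ipsi", "Inferiortemporal_contra",
                           "Middletemporal_ipsi", "Middletemporal_contra",
                           "Hippocampus_ipsi", "Hippocampus_contra",
                           "Fusiform_ipsi", "Amygdala_ipsi"),
                         extra_roi_pool = c(
                           "Insula_ipsi", "Superiorfrontal_contra",
                           "Precuneus_contra", "Entorhinal_ipsi",
                           "Parahippocampal_ipsi", "Superiortemporal_contra",
                           "Posteriorcingulate_contra", "Lingual_contra"),
                         ied_source_label = "Hippocampus_ipsi",
                         ied_waveform = list(spike_width_ms = 70,
                                             spike_amplitude = 150,
                                             slow_wave_width_ms = 300,
                                             slow_wave_amplitude = 60),
                         coupling_spec = coupling_cliques(),
                         n_scalp = 32L,
                         scalp_negative_margin = 0.5,
                         noise_exponent = 1,
                         noise_sd = 10,
                         sensor_noise_sd = 5,
                         seed = 1L) {
  stopifnot(n_patients >= 1L, n_epochs_per_condition >= 1L,
            fs_raw > 0, duration > 0, n_scalp >= 2L,
            scalp_negative_margin < 1, scalp_negative_margin > 0)
  for (cs in coupling_spec) {
    stopifnot(length(cs$pair) == 2L,
              cs$gain_noIED >= 0, cs$gain_IED >= 0,
              cs$phase_lag_rad > -pi, cs$phase_lag_rad <= pi + 1e-12,
              cs$band %in% band_specs()$name,
              all(cs$pair %in% c(source_roi_labels, extra_roi_pool)))
  }
  stopifnot(ied_source_label %in% source_roi_labels)
  structure(list(n_patients = as.integer(n_patients),
                 n_epochs_per_condition = as.integer(n_epochs_per_condition),
                 fs_raw = fs_raw, duration = duration,
                 source_roi_labels = source_roi_labels,
                 extra_roi_pool = extra_roi_pool,
                 ied_source_label = ied_source_label,
                 ied_waveform = ied_waveform,
                 coupling_spec = coupling_spec,
                 n_scalp = as.integer(n_scalp),
                 scalp_negative_margin = scalp_negative_margin,
                 noise_exponent = noise_exponent,
                 noise_sd = noise_sd, sensor_noise_sd = sensor_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default coupling scheme: discharge-locked cliques plus a stationary
#' backbone
#'
#' Each band carries (a) six pairwise couplings forming a
#' hippocampus-anchored 4-region clique of ipsilateral (and, in delta,
#' bilateral prefrontal) regions whose gain rises during discharge epochs,
#' and (b) one condition-independent interhemispheric homologous pair (a
#' stationary connectivity backbone, so the strongest edge of the matrix is
#' comparable across conditions). Phase lags are distinct and kept in
#' (pi/4, 3pi/4), away from 0 and pi where lagged coupling is invisible to
#' the weighted phase lag index. A clique (rather than a single pair) is
#' what raises both segregation (triangles) and integration (short paths)
#' when its gain increases, mirroring the concomitant increase of both
#' network measures this pipeline is designed to detect.
#'
#' @param gain_noIED,gain_IED Clique shared-oscillation amplitude (uV)
#'   outside / inside discharge epochs.
#' @param gain_backbone Amplitude of the stationary interhemispheric pair.
#' @return A coupling_spec list for [synth_config()].
#' @export
coupling_cliques <- function(gain_noIED = 2, gain_IED = 10,
                             gain_backbone = 8) {
  cliques <- list(
    delta = c("Hippocampus_ipsi", "Rostralmiddlefrontal_ipsi",
              "Lateralorbitofrontal_ipsi", "Rostralmiddlefrontal_contra"),
    theta = c("Hippocampus_ipsi", "Amygdala_ipsi", "Fusiform_ipsi",
              "Inferiortemporal_ipsi"),
    alpha = c("Hippocampus_ipsi", "Inferiortemporal_ipsi",
              "Middletemporal_ipsi", "Fusiform_ipsi"),
    beta  = c("Hippocampus_ipsi", "Middletemporal_ipsi",
              "Lateralorbitofrontal_ipsi", "Amygdala_ipsi"))
  backbone <- list(
    delta = c("Rostralmiddlefrontal_ipsi", "Rostralmiddlefrontal_contra"),
    theta = c("Inferiortemporal_ipsi", "Inferiortemporal_contra"),
    alpha = c("Middletemporal_ipsi", "Middletemporal_contra"),
    beta  = c("Lateralorbitofrontal_ipsi", "Lateralorbitofrontal_contra"))
  out <- list()
  for (band in names(cliques)) {
    pairs <- utils::combn(cliques[[band]], 2, simplify = FALSE)
    lags <- seq(pi / 4, 3 * pi / 4, length.out = length(pairs))
    for (k in seq_along(pairs)) {
      out[[length(out) + 1L]] <- list(pair = pairs[[k]], band = band,
                                      phase_lag_rad = lags[k],
                                      gain_noIED = gain_noIED,
                                      gain_IED = gain_IED)
    }
    out[[length(out) + 1L]] <- list(pair = backbone[[band]], band = band,
                                    phase_lag_rad = pi / 2,
                                    gain_noIED = gain_backbone,
                                    gain_IED = gain_backbone)
  }
  out
}

#' Matched null configuration
#'
#' Switches every programmed effect off: discharge amplitudes set to zero
#' and `gain_IED` set equal to `gain_noIED`, leaving the two conditions
#' statistically exchangeable.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_config` with no condition effect.
#' @export
null_config <- function(cfg) {
  cfg$ied_waveform$spike_amplitude <- 0
  cfg$ied_waveform$slow_wave_amplitude <- 0
  cfg$coupling_spec <- lapply(cfg$coupling_spec, function(cs) {
    cs$gain_IED <- cs$gain_noIED
    cs
  })
  cfg
}

#' Programmed ground truth of a configuration
#'
#' @param cfg A [synth_config()].
#' @return data.frame with one row per coupled pair (`source_a`,
#'   `source_b`, `band`, `phase_lag_rad`, `gain_noIED`, `gain_IED`,
#'   `zero_lag` flagging pairs invisible to wPLI by design) and attribute
#'   `ied_roi`.
#' @export
ground_truth <- function(cfg) {
  rows <- lapply(cfg$coupling_spec, function(cs) {
    data.frame(source_a = cs$pair[1], source_b = cs$pair[2], band = cs$band,
               phase_lag_rad = cs$phase_lag_rad,
               gain_noIED = cs$gain_noIED, gain_IED = cs$gain_IED,
               zero_lag = cs$phase_lag_rad == 0,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_a = character(0), source_b = character(0),
               band = character(0), phase_lag_rad = numeric(0),
               gain_noIED = numeric(0), gain_IED = numeric(0),
               zero_lag = logical(0))
  attr(out, "ied_roi") <- cfg$ied_source_label
  out
}

seed_for <- function(cfg, patient_index, comp) {
  as.integer((as.numeric(cfg$seed) * 1009 + patient_index * 10007 +
                comp * 101) %% (.Machine$integer.max - 1L)) + 1L
}

# 1/f^a Gaussian noise with unit SD, via spectral shaping of white noise.
onef_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))          # avoid dividing the DC term by 0
  f <- pmin(f, n - f + 1)             # two-sided frequency index
  W <- W * f^(-exponent / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Analytic (one-sided spectrum) band-limited Gaussian noise with unit-SD
# real part: white noise spectrally shaped by the forward-backward
# magnitude of a 2nd-order Butterworth band-pass. The real part is the
# shared oscillation; multiplying by exp(-1i * lag) before taking the real
# part rotates its phase by a constant lag at every frequency.
band_noise_analytic <- local({
  gcache <- list()
  function(n, fs, f_low, f_high) {
  key <- paste(n, fs, f_low, f_high)
  if (is.null(gcache[[key]])) {
    bf <- signal::butter(2, c(f_low, f_high) / (fs / 2), type = "pass")
    gcache[[key]] <<- iir_mag2(bf, n)
  }
  G <- gcache[[key]]
  W <- stats::fft(stats::rnorm(n)) * G
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  A <- stats::fft(W * h, inverse = TRUE) / n
  A / stats::sd(Re(A))
  }
})

# Spike (difference of Gaussians, `width_ms` at the base) followed by a
# half-cosine slow wave. Returns the waveform and the index of its peak.
ied_template <- function(wf, fs) {
  sw <- wf$spike_width_ms / 1000
  slw <- wf$slow_wave_width_ms / 1000
  t <- seq(-2 * sw, 2 * sw + slw, by = 1 / fs)
  s1 <- exp(-t^2 / (2 * (sw / 6)^2))
  s2 <- exp(-t^2 / (2 * (sw / 2)^2))
  spike <- s1 - 0.5 * s2
  spike <- spike / max(spike) * wf$spike_amplitude
  t0 <- 1.5 * sw
  inwave <- t >= t0 & t <= t0 + slw
  slow <- numeric(length(t))
  slow[inwave] <- -sin(pi * (t[inwave] - t0) / slw) * wf$slow_wave_amplitude
  w <- spike + slow
  list(waveform = w, peak = which.max(abs(w)))
}

place_markers <- function(cfg, patient_index) {
  n_mark <- 2L * cfg$n_epochs_per_condition
  spacing <- 6.5                      # > longest analysis window (5.5 s)
  margin <- 3.6                       # TF epochs need 2.5 s before, 3 s after
  need <- 2 * margin + (n_mark - 1L) * spacing + 0.5
  if (need > cfg$duration) {
    stop(sprintf("duration %.1f s too short for %d non-overlapping epochs (need %.1f s)",
                 cfg$duration, n_mark, need))
  }
  with_seed(seed_for(cfg, patient_index, 1L), {
    onset <- margin + (seq_len(n_mark) - 1L) * spacing +
      stats::runif(n_mark, 0, 0.5)
    cond <- sample(rep(c("IED", "no_IED"), cfg$n_epochs_per_condition))
    data.frame(onset_s = onset, condition = cond,
               label = ifelse(cond == "IED", cfg$ied_source_label, "none"),
               stringsAsFactors = FALSE)
  })
}

patient_rois <- function(cfg, patient_index) {
  n_extra <- min(2L, length(cfg$extra_roi_pool))
  if (n_extra == 0L) return(cfg$source_roi_labels)
  pool <- cfg$extra_roi_pool
  idx <- ((patient_index - 1L) * n_extra + seq_len(n_extra) - 1L) %% length(pool) + 1L
  c(cfg$source_roi_labels, pool[idx])
}

#' Generate one synthetic patient
#'
#' Deterministic given `(cfg, patient_index)`. The intracranial recording
#' samples every source with a two-contact depth shaft (deep gray-matter
#' contact on the source, shallow white-matter contact); the scalp
#' recording is the depth-attenuated linear mixture of the sources plus
#' sensor noise, with the discharge-source mixing column rescaled so the
#' scalp transient peak stays at `scalp_negative_margin` background SDs.
#'
#' @param cfg A [synth_config()].
#' @param patient_index Patient number (1-based).
#' @param include_scalp Generate the scalp modality (skipping it leaves the
#'   intracranial data and events bit-identical; the per-component seed
#'   streams are independent).
#' @return List with `ieeg` and `scalp` [recording()]s, `events`
#'   (marker data.frame with a `detector` attribute of detector-style
#'   events), `channel_map` for the depth contacts, `mixing`
#'   (scalp x source matrix actually applied), `source_rois`, and
#'   `truth` ([ground_truth()]).
#' @export
generate_patient <- function(cfg, patient_index = 1L, include_scalp = TRUE) {
  stopifnot(inherits(cfg, "synth_config"),
            patient_index >= 1L, patient_index <= cfg$n_patients)
  fs <- cfg$fs_raw
  n <- as.integer(round(cfg$duration * fs))
  rois <- patient_rois(cfg, patient_index)
  ns <- length(rois)
  events <- place_markers(cfg, patient_index)
  marker_idx <- round_half_up(events$onset_s * fs) + 1L
  ied_idx <- marker_idx[events$condition == "IED"]

  src <- with_seed(seed_for(cfg, patient_index, 2L), {
    t(vapply(seq_len(ns), function(i) {
      cfg$noise_sd * onef_noise(n, cfg$noise_exponent)
    }, numeric(n)))
  })
  rownames(src) <- rois

  # Band-limited coupling with a known constant phase lag: a shared
  # oscillation is added to both sources, the second copy rotated in phase
  # by Hilbert rotation; its amplitude switches from gain_noIED to gain_IED
  # inside discharge epochs.
  bands <- band_specs()
  gain_env <- rep(1, n)
  for (mi in ied_idx) {
    # covers the longest analysis window around the marker (-1.9 to +3.2 s)
    lo <- max(1L, mi - as.integer(2 * fs))
    hi <- min(n, mi + as.integer(3.2 * fs))
    gain_env[lo:hi] <- NA              # marked; filled per coupling below
  }
  in_ied <- is.na(gain_env)
  with_seed(seed_for(cfg, patient_index, 3L), {
    for (cs in cfg$coupling_spec) {
      b <- bands[bands$name == cs$band, ]
      A <- band_noise_analytic(n, fs, b$f_low, b$f_high)
      g <- ifelse(in_ied, cs$gain_IED, cs$gain_noIED)
      src[cs$pair[1], ] <- src[cs$pair[1], ] + g * Re(A)
      src[cs$pair[2], ] <- src[cs$pair[2], ] +
        g * Re(A * exp(-1i * cs$phase_lag_rad))
    }
  })

  # Discharge transient, peak-aligned to every IED marker.
  tmpl <- ied_template(cfg$ied_waveform, fs)
  for (mi in ied_idx) {
    at <- mi - tmpl$peak + seq_along(tmpl$waveform)
    ok <- at >= 1L & at <= n
    src[cfg$ied_source_label, at[ok]] <-
      src[cfg$ied_source_label, at[ok]] + tmpl$waveform[ok]
  }

  # Depth contacts: two per source shaft, deep contact in gray matter.
  local_sd <- 3
  ref_sd <- 5
  contacts <- with_seed(seed_for(cfg, patient_index, 4L), {
    ref <- ref_sd * stats::rnorm(n)   # amplifier reference, cancels in bipolar
    out <- matrix(0, 2L * ns, n)
    for (i in seq_len(ns)) {
      out[2L * i - 1L, ] <- src[i, ] + local_sd * stats::rnorm(n) + ref
      out[2L * i, ] <- 0.2 * src[i, ] + local_sd * stats::rnorm(n) + ref
    }
    out
  })
  shaft <- rep(sprintf("S%02d", seq_len(ns)), each = 2L)
  contact <- rep(1:2, ns)
  clabels <- paste0(shaft, "C", contact)
  ann <- data.frame(shaft = shaft, contact = contact,
                    gray_matter = contact == 1L,
                    roi = ifelse(contact == 1L, rep(rois, each = 2L), NA),
                    stringsAsFactors = FALSE)
  ieeg <- recording(contacts, fs = fs, labels = clabels,
                    modality = "intracranial", annotations = ann)

  # Scalp mixing with depth attenuation; medial temporal sources are
  # strongly attenuated, and the discharge column is rescaled so that the
  # transient peak sits at `scalp_negative_margin` background SDs.
  M <- NULL; scalp <- NULL
  if (include_scalp) {
  deep <- c("Hippocampus", "Amygdala", "Entorhinal", "Parahippocampal")
  atten <- ifelse(sub("_(ipsi|contra)$", "", rois) %in% deep, 0.05, 1)
  mix_noise <- with_seed(seed_for(cfg, patient_index, 5L), {
    M <- matrix(stats::rnorm(cfg$n_scalp * ns, sd = 0.3), cfg$n_scalp, ns)
    M <- sweep(M, 2L, atten, `*`)
    list(M = M, sensor = cfg$sensor_noise_sd *
           matrix(stats::rnorm(cfg$n_scalp * n), cfg$n_scalp, n))
  })
  M <- mix_noise$M
  bg <- M %*% src + mix_noise$sensor
  # background SD excluding the transient contribution
  ied_row <- match(cfg$ied_source_label, rois)
  peak_amp <- max(abs(tmpl$waveform))
  if (peak_amp > 0) {
    bg_sd <- apply(bg, 1, stats::sd)
    ratio <- max(abs(M[, ied_row]) * peak_amp / bg_sd)
    if (ratio > 0) M[, ied_row] <- M[, ied_row] *
        (cfg$scalp_negative_margin / ratio)
  }
  scalp_dat <- M %*% src + mix_noise$sensor
  scalp <- recording(scalp_dat, fs = fs,
                     labels = sprintf("E%03d", seq_len(cfg$n_scalp)),
                     modality = "scalp")
  }

  # Detector-style events: every discharge hits the discharge region; a low
  # spurious rate elsewhere exercises the irritative-zone rule.
  detector <- with_seed(seed_for(cfg, patient_index, 6L), {
    spur_rois <- setdiff(rois, cfg$ied_source_label)[1:2]
    spur <- lapply(spur_rois, function(r) {
      k <- stats::rpois(1, length(ied_idx) / 8)
      if (k == 0) return(NULL)
      data.frame(time_s = sort(stats::runif(k, 0, cfg$duration)),
                 label = r, stringsAsFactors = FALSE)
    })
    det <- rbind(data.frame(time_s = events$onset_s[events$condition == "IED"],
                            label = cfg$ied_source_label,
                            stringsAsFactors = FALSE),
                 do.call(rbind, spur))
    det[order(det$time_s), , drop = FALSE]
  })
  attr(events, "detector") <- detector

  cmap <- data.frame(channel_label = clabels,
                     roi = ann$roi,
                     hemisphere = ifelse(grepl("_ipsi$", rep(rois, each = 2L)),
                                         "ipsi", "contra"),
                     gray_matter = ann$gray_matter,
                     shaft = shaft, contact = contact,
                     stringsAsFactors = FALSE)

  list(ieeg = ieeg, scalp = scalp, events = events, channel_map = cmap,
       mixing = M, source_rois = rois, truth = ground_truth(cfg),
       patient_index = patient_index)
}

#' Generate a full synthetic cohort
#'
#' @param cfg A [synth_config()].
#' @param include_scalp Generate the scalp modality for every patient.
#' @return List of [generate_patient()] results, one per patient.
#' @export
synth_cohort <- function(cfg, include_scalp = TRUE) {
  lapply(seq_len(cfg$n_patients),
         function(i) generate_patient(cfg, i, include_scalp))
}

#' Write a generated patient to disk
#'
#' EDF per modality, markers as TSV, channel map as TSV; the configuration
#' (JSON) and ground truth (TSV) are written once at the cohort root.
#'
#' @param patient A [generate_patient()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- patient$patient_index
  write_recording(patient$ieeg, file.path(dir, sprintf("p%02d_ieeg.edf", p)))
  write_recording(patient$scalp, file.path(dir, sprintf("p%02d_scalp.edf", p)))
  write_events(patient$events, file.path(dir, sprintf("p%02d_events.tsv", p)))
  write_channel_map(patient$channel_map,
                    file.path(dir, sprintf("p%02d_channels.tsv", p)))
  invisible(dir)
}

#' @rdname write_patient
#' @param cfg A [synth_config()].
#' @export
write_cohort_meta <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(ground_truth(cfg), file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
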