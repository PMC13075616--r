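test_that("generation is bit-reproducible and event lists are well-formed", {
  cfg <- tiny_cfg()
  p1 <- generate_patient(cfg, 2)
  p2 <- generate_patient(cfg, 2)
  expect_identical(p1$ieeg$data, p2$ieeg$data)
  expect_identical(p1$scalp$data, p2$scalp$data)
  expect_identical(p1$events, p2$events)
  ev <- p1$events
  expect_false(is.unsorted(ev$onset_s))
  expect_true(all(ev$onset_s > 0 & ev$onset_s < cfg$duration))
  expect_true(all(table(ev$condition) >= cfg$n_epochs_per_condition))
  # patients differ from each other
  expect_false(identical(p1$ieeg$data, generate_patient(cfg, 1)$ieeg$data))
  expect_error(generate_patient(tiny_cfg(duration = 30), 1), "too short")
})

test_that("config invariants are enforced", {
  expect_error(synth_config(scalp_negative_margin = 1.2), "scalp_negative_margin")
  bad <- list(list(pair = c("Hippocampus_ipsi", "Amygdala_ipsi"),
                   band = "gamma", phase_lag_rad = 1,
                   gain_noIED = 1, gain_IED = 1))
  expect_error(synth_config(coupling_spec = bad))
  bad2 <- list(list(pair = c("Hippocampus_ipsi", "Amygdala_ipsi"),
                    band = "theta", phase_lag_rad = 1,
                    gain_noIED = -1, gain_IED = 1))
  expect_error(synth_config(coupling_spec = bad2))
})

test_that("ground truth reports the programmed couplings and flags zero lag", {
  one <- list(list(pair = c("Hippocampus_ipsi", "Amygdala_ipsi"),
                   band = "theta", phase_lag_rad = 0,
                   gain_noIED = 1, gain_IED = 3))
  cfg <- tiny_cfg(coupling_spec = one)
  gt <- ground_truth(cfg)
  expect_equal(nrow(gt), 1L)
  expect_true(gt$zero_lag)             # invisible to wPLI by design
  expect_equal(attr(gt, "ied_roi"), "Hippocampus_ipsi")
  gt0 <- ground_truth(null_config(cfg))
  expect_equal(gt0$gain_IED, gt0$gain_noIED)
})

test_that("discharges are scalp-negative but intracranially conspicuous", {
  p <- default_patient()
  cfg <- synth_config()
  fs <- cfg$fs_raw
  mk <- iednet:::round_half_up(p$events$onset_s[p$events$condition == "IED"] * fs) + 1L
  sc <- p$scalp$data
  away <- setdiff(seq_len(ncol(sc)),
                  unlist(lapply(mk, function(m) (m - 2 * fs):(m + 2 * fs))))
  for (ch in seq_len(nrow(sc))) {
    defl <- abs(mean(sc[ch, mk]) - mean(sc[ch, away]))
    expect_lt(defl, stats::sd(sc[ch, away]))   # averaged peak below noise floor
  }
  ie <- preprocess(p$ieeg)
  hip <- which(ie$annotations$roi == "Hippocampus_ipsi")
  mk2 <- iednet:::round_half_up(p$events$onset_s[p$events$condition == "IED"] * ie$fs) + 1L
  x <- ie$data[hip, ]
  expect_gt(abs(mean(x[mk2])) / stats::sd(x), 5)
})

test_that("null configuration removes the discharge transient", {
  cfg0 <- null_config(tiny_cfg())
  p <- generate_patient(cfg0, 1, include_scalp = FALSE)
  ie <- preprocess(p$ieeg)
  hip <- which(ie$annotations$roi == "Hippocampus_ipsi")
  mk <- iednet:::round_half_up(p$events$onset_s[p$events$condition == "IED"] * ie$fs) + 1L
  x <- ie$data[hip, ]
  expect_lt(abs(mean(x[mk])) / stats::sd(x), 1)
})

test_that("background spectra follow the programmed 1/f slope", {
  p <- default_patient()
  # uncoupled deep region: background + local noise only
  i <- which(p$channel_map$roi == "Hippocampus_contra")
  ps <- stats::spec.pgram(stats::ts(p$ieeg$data[i, ], frequency = 400),
                          spans = 51, taper = 0.1, plot = FALSE)
  sel <- ps$freq >= 2 & ps$freq <= 30
  slope <- stats::coef(stats::lm(log(ps$spec[sel]) ~ log(ps$freq[sel])))[2]
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("the programmed phase lag is recoverable from the recordings", {
  one <- list(list(pair = c("Hippocampus_ipsi", "Amygdala_ipsi"),
                   band = "theta", phase_lag_rad = pi / 4,
                   gain_noIED = 8, gain_IED = 8))
  cfg <- synth_config(n_epochs_per_condition = 50L, duration = 700,
                      coupling_spec = one, seed = 9L)
  p <- generate_patient(cfg, 1, include_scalp = FALSE)
  ie <- preprocess(p$ieeg)
  b <- band_specs()[2, ]
  ep <- extract_epochs(ie, p$events, build_window(b, ie$fs), "no_IED")
  xs <- trial_cross_spectra(ep, b)
  i1 <- which(ie$annotations$roi == "Hippocampus_ipsi")
  i2 <- which(ie$annotations$roi == "Amygdala_ipsi")
  S <- cross_spectrum_pair(xs, i1, i2)
  bin <- which.min(abs(xs$freqs - (b$f_low + b$f_high) / 2))
  expect_lt(abs(Arg(mean(S[, bin])) - pi / 4), 0.2)
})

test_that("patient files round-trip through the on-disk layout", {
  cfg <- tiny_cfg()
  p <- generate_patient(cfg, 1)
  dir <- tempfile()
  write_patient(p, dir)
  write_cohort_meta(cfg, dir)
  expect_true(all(file.exists(file.path(dir,
    c("p01_ieeg.edf", "p01_scalp.edf", "p01_events.tsv",
      "p01_channels.tsv", "config.json", "ground_truth.tsv")))))
  back <- read_recording(file.path(dir, "p01_ieeg.edf"), "intracranial")
  expect_identical(back$labels, p$ieeg$labels)
  expect_lte(max(abs(back$data - p$ieeg$data)),
             max(edf_quantization_step(p$ieeg)))
  expect_equal(read_events(file.path(dir, "p01_events.tsv"))$onset_s,
               p$events$onset_s, tolerance = 1e-9)
})
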