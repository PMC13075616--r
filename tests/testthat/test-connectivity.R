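sin_pair_epochs <- function(dphi, n_trials = 3, f0 = 10, fs = 200, n = 500) {
  t <- (seq_len(n) - 1) / fs
  x1 <- cos(2 * pi * f0 * t)
  x2 <- cos(2 * pi * f0 * t - dphi)
  tr <- array(0, dim = c(n_trials, 2, n))
  for (k in seq_len(n_trials)) { tr[k, 1, ] <- x1; tr[k, 2, ] <- x2 }
  epochs_from_matrix(tr, fs, labels = c("a", "b"))
}

test_that("cross-spectra carry the programmed phase and conjugate symmetry", {
  ep <- sin_pair_epochs(pi / 3)
  xs <- trial_cross_spectra(ep, band_specs()[3, ])
  bin <- which.min(abs(xs$freqs - 10))
  # self cross-spectrum is real
  expect_equal(max(abs(Im(cross_spectrum_pair(xs, 1, 1)))), 0)
  S12 <- cross_spectrum_pair(xs, "a", "b")
  expect_equal(Arg(S12[1, bin]), pi / 3, tolerance = 0.01)
  expect_equal(cross_spectrum_pair(xs, 2, 1), Conj(S12))
})

test_that("wPLI hits its analytic limits", {
  # zero lag (identical up to positive scaling): invisible by design
  ep0 <- sin_pair_epochs(0)
  ep0$trials[, 2, ] <- 3 * ep0$trials[, 1, ]
  W0 <- wpli(trial_cross_spectra(ep0, band_specs()[3, ]))
  expect_equal(W0["a", "b"], 0)
  # constant quarter-cycle lag across the band, noiseless: the imaginary
  # cross-spectrum has the same sign in every trial and bin
  set.seed(20)
  tr <- lagged_pair_trials(8, 500, 200, 8, 13, pi / 2, 1, noise_sd = 0)
  W1 <- wpli(trial_cross_spectra(epochs_from_matrix(tr, 200,
                                                    labels = c("a", "b")),
                                 band_specs()[3, ]))
  expect_equal(W1["a", "b"], 1, tolerance = 1e-9)
  expect_true(is.na(W1[1, 1]) && is.na(W1[2, 2]))
  expect_equal(W1, t(W1))
})

test_that("wPLI of independent or linearly mixed noise stays at the floor", {
  set.seed(21)
  fs <- 200; n <- 250
  mk <- function(mixed) {
    tr <- array(0, dim = c(200, 2, n))
    for (k in 1:200) {
      n1 <- rnorm(n); n2 <- rnorm(n); cmn <- rnorm(n)
      if (mixed) { tr[k, 1, ] <- n1 + 0.6 * cmn; tr[k, 2, ] <- n2 + 0.9 * cmn }
      else { tr[k, 1, ] <- n1; tr[k, 2, ] <- n2 }
    }
    epochs_from_matrix(tr, fs, labels = c("a", "b"))
  }
  Wind <- wpli(trial_cross_spectra(mk(FALSE), band_specs()[2, ]))
  expect_lt(Wind["a", "b"], 0.15)
  # zero-lag common-source mixing (spatial leakage) cannot create wPLI
  Wmix <- wpli(trial_cross_spectra(mk(TRUE), band_specs()[2, ]))
  expect_lt(Wmix["a", "b"], 0.15)
})

test_that("estimated wPLI rises monotonically with the programmed gain", {
  set.seed(22)
  gains <- c(0.1, 0.25, 0.5, 1, 2)
  w <- vapply(gains, function(g) {
    tr <- lagged_pair_trials(100, 250, 200, 4, 8, pi / 2, g)
    ep <- epochs_from_matrix(tr, 200, labels = c("a", "b"))
    wpli(trial_cross_spectra(ep, band_specs()[2, ]))["a", "b"]
  }, numeric(1))
  expect_gt(cor(gains, w, method = "spearman"), 0.9)
})

test_that("channel-pair aggregation to region pairs averages across regions", {
  W <- matrix(NA_real_, 4, 4,
              dimnames = list(c("a1", "a2", "b1", "c1"),
                              c("a1", "a2", "b1", "c1")))
  W["a1", "b1"] <- W["b1", "a1"] <- 0.2
  W["a2", "b1"] <- W["b1", "a2"] <- 0.4
  W["a1", "a2"] <- W["a2", "a1"] <- 0.9   # within-region pair: ignored
  map <- data.frame(channel_label = c("a1", "a2", "b1", "c1"),
                    roi = c("A", "A", "B", "C"))
  R <- aggregate_pairs_to_roi(W, map)
  expect_equal(R["A", "B"], 0.3)
  expect_true(is.na(R["A", "C"]))          # no sampled channel pair
  expect_true(is.na(R["B", "C"]))
  expect_equal(R, t(R))
  # single channel per region restricts the channel matrix
  W2 <- matrix(c(NA, 0.7, 0.7, NA), 2, 2,
               dimnames = list(c("b1", "c1"), c("b1", "c1")))
  map2 <- map[3:4, ]
  expect_equal(aggregate_pairs_to_roi(W2, map2)["B", "C"], 0.7)
  expect_error(aggregate_pairs_to_roi(W2, map2[1, ]), "fewer than two")
})
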