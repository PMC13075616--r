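test_that("band power concentrates in the band containing the tone", {
  fs <- 200
  n <- 500
  t <- (seq_len(n) - 1) / fs
  tr <- do.call(rbind, replicate(4, sin(2 * pi * 10 * t), simplify = FALSE))
  ep <- epochs_from_matrix(tr, fs)
  alpha <- band_psd(ep, band_specs()[3, ])
  beta <- band_psd(ep, band_specs()[4, ])
  expect_gt(alpha[1], 10 * beta[1])
  # quadratic in amplitude
  ep2 <- ep; ep2$trials <- 2 * ep$trials
  expect_equal(band_psd(ep2, band_specs()[3, ]), 4 * alpha, tolerance = 1e-12)
  ep0 <- ep; ep0$trials[] <- 0
  expect_equal(unname(band_psd(ep0, band_specs()[3, ])), 0)
})

test_that("band powers integrate back to the tapered-trial variance", {
  set.seed(12)
  fs <- 200
  n <- 1000
  # band-limited signal so the 1-35 Hz partition captures the mass
  x <- iednet:::zp_filter(rbind(stats::rnorm(n * 8)),
                          signal::butter(4, c(2, 25) / (fs / 2), "pass"))
  w <- tukey_window(n, 0.25)
  trials <- t(vapply(seq_len(8), function(k) {
    x[1, (k - 1) * n + seq_len(n)] * w
  }, numeric(n)))
  ep <- epochs_from_matrix(trials, fs)
  partition <- data.frame(name = c("p1", "p2", "p3", "p4", "p5"),
                          f_low = c(1, 4, 8, 13, 30),
                          f_high = c(4, 8, 13, 30, 35))
  total <- 0
  for (i in seq_len(nrow(partition))) {
    b <- as.list(partition[i, ])
    nb <- length(iednet:::band_bins(n, fs, b))
    total <- total + mean(band_psd(ep, b)) * nb * fs / n
  }
  # Parseval: the one-sided density integrates to the mean square of the
  # (tapered) trial under the rectangular 1/n normalization
  expected <- mean(rowSums(trials^2)) / n
  expect_equal(total, expected, tolerance = 0.05)
})

test_that("band ITC separates phase-locked from jittered trials", {
  fs <- 200
  n <- 500
  t <- (seq_len(n) - 1) / fs
  locked <- do.call(rbind, replicate(20, sin(2 * pi * 10 * t) + 0.01 * 1:0,
                                     simplify = FALSE))
  ep <- epochs_from_matrix(locked, fs)
  expect_equal(unname(band_itc(ep, band_specs()[3, ])), 1, tolerance = 1e-9)
  # time jitter spanning a full cycle of the band center kills phase locking
  set.seed(13)
  f0 <- 10.5
  jit <- t(vapply(seq_len(100), function(k) {
    sin(2 * pi * f0 * (t - stats::runif(1, -1 / f0, 1 / f0))) +
      0.1 * stats::rnorm(n)
  }, numeric(n)))
  expect_lt(band_itc(epochs_from_matrix(jit, fs), band_specs()[3, ])[1], 0.15)
  expect_error(band_itc(epochs_from_matrix(locked[1, , drop = FALSE], fs),
                        band_specs()[3, ]), "two trials")
})

test_that("region aggregation averages mapped channels and drops the rest", {
  map <- data.frame(channel_label = c("c1", "c2", "c3"),
                    roi = c("A", "A", "B"))
  v <- c(c1 = 2, c2 = 4, c3 = 7, c4 = 99)
  out <- aggregate_units_to_roi(v, map)
  expect_equal(unname(out[c("A", "B")]), c(3, 7))
  expect_false("c4" %in% names(out))
  # permutation invariance in channel order
  out2 <- aggregate_units_to_roi(v[c(4, 3, 1, 2)], map)
  expect_equal(out2[sort(names(out2))], out[sort(names(out))])
  # single-channel region is the identity
  expect_equal(unname(out["B"]), unname(v["c3"]))
  expect_warning(res <- aggregate_units_to_roi(c(x = 1), map), "no channel")
  expect_length(res, 0)
  expect_error(aggregate_units_to_roi(v, map[0, ]), "empty")
})
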