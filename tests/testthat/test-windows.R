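test_that("adaptive windows hold five cycles of f_low with the peak at 3/8", {
  fs <- 200
  delta <- build_window(band_specs()[1, ], fs)
  expect_equal(delta$n_samples, 1000L)       # 5 s for delta 1-4 Hz
  expect_equal(delta$peak_index, 375L)
  beta <- build_window(band_specs()[4, ], fs)
  expect_equal(beta$n_samples, 77L)          # round(200 * 5 / 13)
  expect_error(build_window(list(name = "x", f_low = 0, f_high = 4), fs),
               "invalid band")
  # higher f_low always gives shorter windows
  lens <- vapply(seq_len(4), function(i) build_window(band_specs()[i, ], fs)$n_samples,
                 integer(1))
  expect_true(all(diff(lens) < 0))
  # flat top of the default Tukey taper covers the discharge peak
  for (i in 1:4) {
    w <- build_window(band_specs()[i, ], fs)
    expect_gte(w$taper[w$peak_index], 0.99)
  }
  expect_equal(max(tukey_window(101, 0.25)), 1)
})

make_rec <- function(n = 12000, fs = 200) {
  set.seed(11)
  recording(rbind(rnorm(n), rnorm(n)), fs, c("a", "b"))
}

test_that("epoch extraction places the marker at the window peak, tapered", {
  fs <- 200
  rec <- make_rec()
  win <- build_window(band_specs()[1, ], fs)
  ev <- data.frame(onset_s = c(20, 30), condition = "IED", label = "x")
  ep <- extract_epochs(rec, ev, win, "IED")
  expect_equal(dim(ep$trials), c(2L, 2L, 1000L))
  m <- round(20 * fs) + 1
  seg <- rec$data[1, (m - win$peak_index + 1):(m - win$peak_index + 1000)]
  expect_equal(ep$trials[1, 1, ], seg * win$taper)
})

test_that("balancing subsamples to the requested count, reproducibly", {
  rec <- make_rec()
  win <- build_window(band_specs()[4, ], 200)
  ev <- data.frame(onset_s = sort(c(seq(4, 49, by = 5), seq(26.5, 56.5, by = 5))),
                   condition = rep("x", 17), label = "x")
  ev$condition <- ifelse(ev$onset_s %in% seq(4, 49, by = 5), "IED", "no_IED")
  n_keep <- min(table(ev$condition))
  e1 <- extract_epochs(rec, ev, win, "IED", n_keep = n_keep, seed = 5)
  e2 <- extract_epochs(rec, ev, win, "no_IED", n_keep = n_keep, seed = 5)
  expect_equal(n_trials(e1), 7L)
  expect_equal(n_trials(e2), 7L)
  e1b <- extract_epochs(rec, ev, win, "IED", n_keep = n_keep, seed = 5)
  expect_identical(e1$trials, e1b$trials)
})

test_that("trials crossing the recording edges are dropped", {
  rec <- make_rec()
  win <- build_window(band_specs()[1, ], 200)
  ev <- data.frame(onset_s = c(0.1, 30), condition = "IED", label = "x")
  ep <- extract_epochs(rec, ev, win, "IED")
  expect_equal(n_trials(ep), 1L)
  expect_error(extract_epochs(rec, ev[1, ], win, "IED"), "surviving")
})

test_that("time-frequency epochs use the stated asymmetric/symmetric spans", {
  fs <- 200
  rec <- make_rec()
  ev <- data.frame(onset_s = c(10, 59.2), condition = c("IED", "IED"),
                   label = "x")
  ep <- extract_tf_epochs(rec, ev, "IED")
  expect_equal(dim(ep$trials)[3], 1000L)     # -2..3 s at 200 Hz
  times <- ep$t0 + (seq_len(1000) - 1) / fs
  expect_equal(which(times == 0), 401L)      # 400 samples precede the peak
  expect_equal(n_trials(ep), 1L)             # marker 0.8 s from the end drops
  ev2 <- data.frame(onset_s = 10, condition = "no_IED", label = "none")
  ep2 <- extract_tf_epochs(rec, ev2, "no_IED")
  expect_equal(dim(ep2$trials)[3], 1000L)    # -2.5..2.5 s
  expect_equal(ep2$t0, -2.5)
  expect_equal(which(ep2$t0 + (seq_len(1000) - 1) / fs == 0), 501L)
})
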