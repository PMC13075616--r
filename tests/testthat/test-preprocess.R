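tone <- function(f, fs, dur = 10) sin(2 * pi * f * seq(0, dur - 1 / fs, by = 1 / fs))

test_that("band-pass is zero-phase with the specified band behaviour", {
  fs <- 200
  n <- 4000
  imp <- numeric(n); imp[n / 2] <- 1
  rec <- recording(rbind(imp), fs, "imp")
  out <- bandpass(rec)$data[1, ]
  pk <- which.max(abs(out))
  k <- 300
  expect_lt(max(abs(out[pk + 1:k] - out[pk - 1:k])), 1e-10 * max(abs(out)))

  # 10 Hz inside the band survives within 2 percent
  x10 <- bandpass(recording(rbind(tone(10, fs)), fs, "t"))$data[1, ]
  mid <- 500:1500
  expect_equal(max(abs(x10[mid])), 1, tolerance = 0.02)

  # 0.1 Hz well below the 1 Hz edge loses more than 20 dB
  x01 <- bandpass(recording(rbind(tone(0.1, fs, 40)), fs, "t"))$data[1, ]
  expect_lt(max(abs(x01)), 10^(-20 / 20))

  expect_error(bandpass(recording(rbind(imp), fs, "t"), high = 120), "Nyquist")
})

test_that("downsampling keeps in-band content and kills aliases", {
  fs <- 1000
  rec <- recording(rbind(tone(30, fs), tone(150, fs)), fs, c("a", "b"))
  out <- downsample(rec, 200)
  expect_equal(ncol(out$data), 2000L)   # floor(10 s * 200 Hz)
  expect_equal(out$fs, 200)
  mid <- 500:1500
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.02)
  expect_lt(max(abs(out$data[2, mid])), 10^(-40 / 20))
  expect_error(downsample(rec, 2000), "exceeds")
})

test_that("common average zeroes the channel mean and is idempotent", {
  set.seed(2)
  rec <- recording(matrix(rnorm(5 * 500), 5), 100, paste0("E", 1:5))
  car <- common_average(rec)
  expect_lt(max(abs(colMeans(car$data))), 1e-12 * stats::sd(car$data))
  # invariant to adding a common offset
  rec2 <- rec; rec2$data <- rec2$data + 42
  expect_equal(common_average(rec2)$data, car$data)
  # idempotent
  expect_equal(common_average(car)$data, car$data)
  # two antisymmetric channels are already average-free
  x <- rnorm(100)
  rec3 <- recording(rbind(x, -x), 100, c("a", "b"))
  expect_equal(common_average(rec3)$data, rec3$data)
  expect_error(common_average(recording(rbind(x), 100, "a")), ">= 2")
})

shaft_rec <- function(gray, data = NULL, rois = NULL) {
  k <- length(gray)
  if (is.null(data)) data <- matrix(rnorm(k * 100), k)
  if (is.null(rois)) rois <- rep("Hippocampus_ipsi", k)
  recording(data, 100, paste0("A", seq_len(k)), "intracranial",
            annotations = data.frame(shaft = "A", contact = seq_len(k),
                                     gray_matter = gray, roi = rois))
}

test_that("bipolar derivation pairs adjacent contacts and applies the gray rule", {
  # common signal cancels exactly
  s <- sin(seq(0, 10, length.out = 100))
  rec <- shaft_rec(c(TRUE, TRUE), data = rbind(s + 1, s + 1))
  expect_equal(max(abs(bipolar(rec)$data)), 0)

  # gray flags (F,T,T,F): all three adjacent pairs keep >= 1 gray member
  rec4 <- shaft_rec(c(FALSE, TRUE, TRUE, FALSE),
                    rois = c(NA, "Hippocampus_ipsi", "Amygdala_ipsi", NA))
  bp <- bipolar(rec4)
  expect_identical(bp$labels, c("A1-A2", "A2-A3", "A3-A4"))
  # pair ROI: gray member, deeper contact when both gray
  expect_identical(bp$annotations$roi,
                   c("Hippocampus_ipsi", "Hippocampus_ipsi", "Amygdala_ipsi"))

  # all-white shaft yields nothing
  expect_error(bipolar(shaft_rec(c(FALSE, FALSE))), "no bipolar pair")
  expect_error(bipolar(recording(matrix(0, 2, 10), 100, c("x", "y"),
                                 "intracranial")), "annotations")
})

test_that("bipolar output ignores a shared amplifier reference", {
  set.seed(3)
  base <- matrix(rnorm(4 * 200), 4)
  ref <- rnorm(200)
  r1 <- shaft_rec(rep(TRUE, 4), data = base)
  r2 <- shaft_rec(rep(TRUE, 4), data = sweep(base, 2, -ref))
  expect_equal(bipolar(r1)$data, bipolar(r2)$data)
})
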