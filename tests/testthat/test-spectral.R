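# spectral module: Welch estimator and band summaries against analytic
# oracles (sine power A^2/2, Parseval, scaling equivariance).

sine_rec <- function(f, fs = 512, secs = 16, amp = 1) {
  t <- (0:(secs * fs - 1)) / fs
  x <- amp * sin(2 * pi * f * t)
  new_recording(rbind(x, -x), fs, montage_1020(2))
}

test_that("unit sine: in-band integrated power is A^2/2", {
  rec <- sine_rec(10)
  ps <- welch_psd(rec, welch_config(1024, 512))
  df <- 512 / 1024
  sel <- ps$freqs_hz >= 9 & ps$freqs_hz <= 11
  expect_equal(sum(ps$power[1, sel]) * df, 0.5, tolerance = 0.02)
  # Parseval: total integral ~ time-domain variance
  expect_equal(sum(ps$power[1, ]) * df, stats::var(rec$data[1, ]),
               tolerance = 0.02)
})

test_that("zero signal gives identically zero PSD and K bookkeeping holds", {
  rec <- new_recording(matrix(0, 2, 4096), 512, montage_1020(2))
  ps <- welch_psd(rec, welch_config(1024, 512))
  expect_true(all(ps$power == 0))
  # K = floor((N - M)/(M - D)) + 1
  expect_equal(ps$n_segments, floor((4096 - 1024) / (1024 - 512)) + 1)
  ps2 <- welch_psd(rec, welch_config(1024, 0))
  expect_equal(ps2$n_segments, 4)
  expect_error(welch_psd(rec, welch_config(8192, 0)), "exceeds")
})

test_that("Parseval holds for arbitrary signals within 2%", {
  set.seed(7)
  for (i in 1:3) {
    x <- as.numeric(stats::filter(rnorm(8192), rep(1, 4), "convolution",
                                  sides = 1))
    x[is.na(x)] <- 0
    rec <- new_recording(rbind(x, x), 256, montage_1020(2))
    ps <- welch_psd(rec, welch_config(512, 256))
    df <- 256 / 512
    expect_equal(sum(ps$power[1, ]) * df, mean(x^2), tolerance = 0.02)
  }
})

test_that("scaling a recording by c shifts band power by 20*log10(c)", {
  set.seed(8)
  rec <- new_recording(matrix(rnorm(2 * 4096, sd = 3), 2), 256,
                       montage_1020(2))
  bp1 <- band_power(welch_psd(rec, welch_config(512, 256)))
  rec2 <- rec
  rec2$data <- rec$data * 5
  bp2 <- band_power(welch_psd(rec2, welch_config(512, 256)))
  expect_equal(bp2$whole_brain - bp1$whole_brain,
               rep(20 * log10(5), 9), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("flat densities map to exact dB values; bins are [low, high)", {
  freqs <- (0:256) * 0.5
  fake <- structure(list(freqs_hz = freqs,
                         power = matrix(1, 2, length(freqs)),
                         n_segments = 1), class = "ms_psd")
  expect_equal(unname(band_power(fake)$whole_brain), rep(0, 9))
  fake$power <- matrix(10, 2, length(freqs))
  expect_equal(unname(band_power(fake)$whole_brain), rep(10, 9))
  # half-open bins: a spike exactly at 13 Hz belongs to beta1, not alpha2
  fake$power <- matrix(1, 2, length(freqs))
  fake$power[, freqs == 13] <- 1e6
  bp <- band_power(fake)
  expect_equal(unname(bp$whole_brain[["alpha2"]]), 0)
  expect_gt(bp$whole_brain[["beta1"]], 10)
  bad <- band_scheme_default()
  bad$low_hz[1] <- 500
  bad$high_hz[1] <- 600
  expect_error(band_power(fake, bad), "outside")
})

test_that("epoch segmentation never crosses epoch boundaries", {
  # two epochs with very different content: a segment spanning the boundary
  # would leak power between them
  fs <- 256
  m <- montage_1020(2)
  x1 <- sin(2 * pi * 6 * (0:(2 * fs - 1)) / fs)
  x2 <- sin(2 * pi * 30 * (0:(2 * fs - 1)) / fs)
  arr <- array(0, dim = c(2, 2 * fs, 2))
  arr[1, , 1] <- x1; arr[2, , 1] <- -x1
  arr[1, , 2] <- x2; arr[2, , 2] <- -x2
  ep <- structure(list(data = arr, fs_hz = fs, epoch_length_s = 2,
                       rejected = c(FALSE, FALSE), reasons = c("", ""),
                       montage = m, annotations = character()),
                  class = "ms_epochs")
  ps <- welch_psd(ep, welch_config(256, 128, fs_hz = fs))
  manual <- (welch_psd(new_recording(arr[, , 1], fs, m),
                       welch_config(256, 128))$power +
             welch_psd(new_recording(arr[, , 2], fs, m),
                       welch_config(256, 128))$power) / 2
  expect_equal(ps$power, manual, tolerance = 1e-12, ignore_attr = TRUE)
  # rejected epochs are skipped
  ep$rejected <- c(FALSE, TRUE)
  ps2 <- welch_psd(ep, welch_config(256, 128, fs_hz = fs))
  expect_equal(ps2$power,
               welch_psd(new_recording(arr[, , 1], fs, m),
                         welch_config(256, 128))$power, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("band_table: schema, deterministic order, all-zero exclusion", {
  m <- montage_1020(8)
  set.seed(9)
  recs <- list(
    "s1|pre" = new_recording(matrix(rnorm(8 * 1024), 8), 256, m),
    "s1|post" = new_recording(matrix(0, 8, 1024), 256, m))
  info <- data.frame(subject_id = c("s1", "s1"), group = "TMNMT",
                     condition = c("pre", "post"))
  expect_warning(tab <- band_table(recs, info, welch_config(256, 128)),
                 "non-finite")
  expect_equal(nrow(tab), 9)        # zero recording dropped
  expect_equal(tab$band, band_scheme_default()$band)
})
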