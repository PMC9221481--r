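# Signal conditioning chain.

make_rec <- function(samples, fs = 1000, triggers = NULL, task = "PIMA") {
  signal_record(samples, fs_hz = fs, triggers = triggers, task = task)
}

test_that("plateau cut keeps exactly the trigger-2 to trigger-3 window", {
  fs <- 1000
  rec <- make_rec(matrix(rnorm(30 * fs), 1,
                         dimnames = list("ch", NULL)), fs,
                  triggers = c(0, 5, 25))
  out <- cut_trial(rec, "plateau")
  expect_equal(ncol(out$samples) / fs, 20)
  # the retained samples are the original window
  expect_equal(out$samples[1, ], rec$samples[1, (5 * fs + 1):(25 * fs)])
})

test_that("short MVIC plateaus are extended backwards to three seconds", {
  fs <- 250
  rec <- make_rec(matrix(rnorm(10 * fs), 1, dimnames = list("ch", NULL)), fs,
                  triggers = c(0, 6, 8), task = "MVIC")
  out <- cut_trial(rec, "mvic")
  expect_equal(ncol(out$samples) / fs, 3)
  # window ends at trigger 3
  expect_equal(out$samples[1, ncol(out$samples)], rec$samples[1, 8 * fs])
  # extension bounded by trigger 1
  rec2 <- make_rec(matrix(rnorm(3 * fs), 1, dimnames = list("ch", NULL)), fs,
                   triggers = c(1.5, 1.6, 2.9))
  expect_error(cut_trial(rec2, "mvic"), "cannot reach")
})

test_that("full mode and invalid triggers behave as documented", {
  fs <- 100
  rec <- make_rec(matrix(1:400, 1, dimnames = list("ch", NULL)), fs,
                  triggers = c(0, 1, 3))
  expect_identical(cut_trial(rec, "full"), rec)
  rec$triggers <- c(0, 3, 3)
  expect_error(signal_record(rec$samples, fs, triggers = c(0, 3, 3)),
               "triggers")
  expect_error(cut_trial(make_rec(matrix(0, 1, 400,
                                         dimnames = list("ch", NULL)), fs),
                         "plateau"), "no triggers")
})

test_that("notch filter suppresses 50 Hz and passes 10 Hz", {
  fs <- 1000
  t <- seq(1 / fs, 8, by = 1 / fs)
  tone50 <- sin(2 * pi * 50 * t)
  tone10 <- sin(2 * pi * 10 * t)
  expect_lt(sd(notch_filter(tone50, fs)), 0.1 * sd(tone50))
  expect_equal(sd(notch_filter(tone10, fs)), sd(tone10), tolerance = 0.01)
  expect_identical(notch_filter(numeric(1000), fs), numeric(1000))
  expect_error(notch_filter(tone10, 80, band = c(49, 51)), "Nyquist")
})

test_that("bandpass removes DC and preserves the 10 Hz component", {
  fs <- 1000
  t <- seq(1 / fs, 8, by = 1 / fs)
  expect_equal(mean(bandpass_filter(rep(5, 4000), fs)), 0, tolerance = 1e-9)
  tone10 <- sin(2 * pi * 10 * t)
  expect_equal(sd(bandpass_filter(tone10, fs)), sd(tone10), tolerance = 0.05)
  expect_equal(bandpass_filter(numeric(2000), fs), numeric(2000))
  expect_error(bandpass_filter(tone10, 250), "Nyquist")
})

test_that("downsampling keeps length arithmetic and spectral content", {
  expect_length(downsample(rnorm(1000), 1000, 250), 250)
  fs <- 1000
  t <- seq(1 / fs, 8, by = 1 / fs)
  d <- downsample(sin(2 * pi * 10 * t), 1000, 250)
  expect_equal(peak_frequency(d, 250), 10, tolerance = 0.2)
  cst <- downsample(rep(2.5, 1000), 1000, 250)
  expect_equal(cst, rep(2.5, 250), tolerance = 1e-9)
  expect_error(downsample(rnorm(100), 1000, 300), "integer multiple")
})

test_that("drift removal leaves fast components and kills slow trends", {
  fs <- 250
  t <- seq(1 / fs, 20, by = 1 / fs)
  sine <- sin(2 * pi * 10 * t)
  ramp <- seq(0, 5, length.out = length(t))
  out <- remove_drift(ramp + sine, fs)
  expect_lt(sd(out - sine), 0.05 * sd(sine))
  expect_lt(abs(mean(out)), 0.01)
  expect_lt(max(abs(remove_drift(rep(7.3, 2000), fs))), 1e-6)
  expect_equal(remove_drift(sine, fs), sine, tolerance = 0.05)
  s3 <- sin(2 * pi * 3 * t)
  expect_equal(sd(remove_drift(s3, fs)), sd(s3), tolerance = 0.05)
})

test_that("region averaging means member channels and reports missing ones", {
  map <- default_region_map()
  fs <- 250
  n <- 500
  s <- sin(2 * pi * 7 * seq_len(n) / fs)
  chans <- unlist(map$channels)
  samples <- matrix(rnorm(length(chans) * n), length(chans),
                    dimnames = list(chans, NULL))
  # FM region from two identical channels reproduces the channel
  samples["Fpz", ] <- s; samples["Fz", ] <- s
  rec <- make_rec(samples, fs)
  out <- average_regions(rec, map)
  expect_equal(nrow(out$samples), 10)
  expect_identical(rownames(out$samples),
                   c("FM", "C", "CP", "POc", "AFle", "TLle", "POle",
                     "AFri", "TLri", "POri"))
  expect_equal(out$samples["FM", ], s, tolerance = 1e-12)
  # cancellation of opposite channels
  samples["CP1", ] <- s; samples["CP2", ] <- -s
  out2 <- average_regions(make_rec(samples, fs), map)
  expect_equal(max(abs(out2$samples["CP", ])), 0, tolerance = 1e-12)
  # direct mean check on a multi-channel region
  expect_equal(out$samples["POc", ],
               colMeans(samples[c("Pz", "POz", "Oz"), ]), tolerance = 1e-12)
  expect_error(average_regions(make_rec(samples[-1, , drop = FALSE], fs), map),
               "Fpz")
})

test_that("region map enforces the sub-region invariants", {
  map <- default_region_map()
  expect_length(map$channels, 10)
  expect_equal(length(unlist(map$channels)), 63)
  expect_false("CPz" %in% unlist(map$channels))
  expect_setequal(unique(map$region), c("EEGcen", "EEGle", "EEGri"))
  expect_equal(sum(map$region == "EEGcen"), 4)
})

test_that("records are truncated to the shortest duration", {
  fs <- 100
  mk <- function(sec) make_rec(matrix(rnorm(sec * fs), 1,
                                      dimnames = list("ch", NULL)), fs)
  out <- truncate_to_common_length(list(mk(19), mk(25), mk(40)))
  expect_equal(vapply(out, function(r) ncol(r$samples) / fs, numeric(1)),
               c(19, 19, 19))
  same <- truncate_to_common_length(list(mk(5), mk(5)))
  expect_equal(vapply(same, function(r) ncol(r$samples) / fs, numeric(1)),
               c(5, 5))
  one <- truncate_to_common_length(list(mk(7)))
  expect_equal(ncol(one[[1]]$samples) / fs, 7)
  expect_error(truncate_to_common_length(list()), "empty")
})

test_that("the conditioning chain is linear and lands at 250 Hz", {
  spec <- trial_spec(duration_s = 8, seed = 31)
  rec <- make_trial_pair(spec)$a
  out <- preprocess_record(rec)
  expect_equal(out$fs_hz, 250)
  zero <- rec
  zero$samples[] <- 0
  out0 <- preprocess_record(zero)
  expect_equal(max(abs(out0$samples)), 0, tolerance = 1e-9)
})

test_that("region averaging commutes with the linear filters", {
  map <- default_region_map()
  fs <- 1000
  n <- 2000
  chans <- map$channels$FM
  samples <- matrix(rnorm(2 * n), 2, dimnames = list(chans, NULL))
  rec <- make_rec(samples, fs)
  filt <- function(x) notch_filter(bandpass_filter(x, fs), fs)
  avg_then_filt <- filt(colMeans(samples))
  filt_then_avg <- colMeans(rbind(filt(samples[1, ]), filt(samples[2, ])))
  expect_equal(avg_then_filt, filt_then_avg, tolerance = 1e-8)
})
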