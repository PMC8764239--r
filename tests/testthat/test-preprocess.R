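# Preprocessing: filter response contracts, re-referencing, channel
# selection, epoching, and the pipeline-order properties.

test_that("bandpass passes in-band tones and removes out-of-band power", {
  r10 <- tone_rec(10)
  out <- bandpass_filter(r10, 0.5, 90)
  expect_equal(sd(out$data), sd(r10$data), tolerance = 0.01)
  r120 <- tone_rec(120)
  out120 <- bandpass_filter(r120, 0.5, 90)
  expect_lt(sd(out120$data), 0.10 * sd(r120$data))
  # >= 20 dB one octave outside both edges
  r180 <- tone_rec(180)
  expect_lt(sd(bandpass_filter(r180, 0.5, 90)$data),
            0.1 * sd(r180$data))
  r_low <- tone_rec(0.25, dur = 8)
  expect_lt(sd(bandpass_filter(r_low, 0.5, 90)$data),
            0.1 * sd(r_low$data))
})

test_that("bandpass removes DC offset and is zero phase", {
  rec <- tone_rec(10)
  rec$data <- rec$data + 50
  out <- bandpass_filter(rec, 0.5, 90)
  expect_lt(abs(mean(out$data)), 0.5)
  # zero phase: in-band tone unshifted (max cross-correlation at lag 0)
  r <- tone_rec(25, dur = 1)
  f <- bandpass_filter(r, 0.5, 90)
  cc <- vapply(-3:3, function(l) {
    idx <- 100:900
    cor(r$data[1, idx], f$data[1, idx + l])
  }, 0)
  expect_equal(which.max(cc), 4L)   # lag 0
  expect_error(bandpass_filter(rec, 10, 600), class = "tinnconn_input_error")
  expect_error(bandpass_filter(rec, 0, 90), class = "tinnconn_input_error")
})

test_that("notch removes line frequency and spares neighbors", {
  r50 <- tone_rec(50)
  expect_lt(sd(notch_filter(r50)$data), 0.1 * sd(r50$data))
  r40 <- tone_rec(40)
  expect_equal(sd(notch_filter(r40)$data), sd(r40$data), tolerance = 0.01)
  # mixture: the 10 Hz component survives intact
  t_ <- seq_len(2000) / 1000
  mix <- eeg_recording(matrix(sin(2 * pi * 50 * t_) + sin(2 * pi * 10 * t_),
                              1), 1000, "c1")
  cleaned <- notch_filter(mix)
  expect_equal(sd(cleaned$data), sd(sin(2 * pi * 10 * t_)), tolerance = 0.02)
  expect_error(notch_filter(tone_rec(10, fs = 80), line_hz = 50),
               class = "tinnconn_input_error")
})

test_that("filters are idempotent in band (double application)", {
  rec <- sim_two_channel(seed = 9, dur = 4, fs = 1000)
  f1 <- bandpass_filter(rec, 0.5, 90)
  f2 <- bandpass_filter(f1, 0.5, 90)
  expect_lt(abs(sd(f2$data) - sd(f1$data)) / sd(f1$data), 0.02)
  n1 <- notch_filter(rec)
  n2 <- notch_filter(n1)
  expect_lt(abs(sd(n2$data) - sd(n1$data)) / sd(n1$data), 0.02)
})

test_that("average re-reference zeroes the instantaneous channel mean", {
  withr::with_seed(10, {
    rec <- eeg_recording(matrix(rnorm(4 * 500, mean = 3), 4), 250,
                         paste0("c", 1:4))
  })
  out <- rereference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # idempotence
  out2 <- rereference(out)
  expect_equal(out2$data, out$data, tolerance = 1e-9)
  # symmetric zero-mean two-channel pair {+v, -v} is already referenced
  v <- sin(2 * pi * seq_len(100) / 20)
  sym <- eeg_recording(rbind(v, -v), 100, c("a", "b"))
  expect_equal(rereference(sym)$data, sym$data, tolerance = 1e-9)
  one <- eeg_recording(matrix(v, 1), 100, "a")
  expect_error(rereference(one), class = "tinnconn_input_error")
  expect_error(rereference(rec, "REST"), class = "tinnconn_config_error")
})

test_that("channel selection picks the auditory montage in order", {
  labels64 <- c(auditory_channels(),
                paste0("X", 1:52))
  withr::with_seed(11, {
    rec <- eeg_recording(matrix(rnorm(64 * 100), 64), 500,
                         sample(labels64))   # scrambled order
  })
  out <- select_auditory_channels(rec)
  expect_identical(out$channel_labels, auditory_channels())
  expect_equal(nrow(out$data), 12)
  expect_equal(out$data[3, ],
               rec$data[match("C5", rec$channel_labels), ])
  # already-selected input is the identity
  expect_equal(select_auditory_channels(out)$data, out$data)
  err <- tryCatch(select_auditory_channels(rec, c("FT7", "XX9")),
                  error = identity)
  expect_s3_class(err, "tinnconn_input_error")
  expect_match(conditionMessage(err), "XX9")
})

test_that("epoch segmentation follows the floor rule and propagates labels", {
  withr::with_seed(12, {
    rec <- eeg_recording(matrix(rnorm(2 * 60500), 2), 100, c("a", "b"),
                         group_label = "left")
  })
  eps <- segment_epochs(rec, 10)          # 605 s at 10 s -> 60 epochs
  expect_length(eps, 60)
  expect_true(all(vapply(eps, function(e) e$label == "left", TRUE)))
  expect_true(all(vapply(eps, function(e) ncol(e$data) == 1000, TRUE)))
  expect_identical(eps[[2]]$data, rec$data[, 1001:2000])
  short <- eeg_recording(matrix(rnorm(2 * 900), 2), 100, c("a", "b"))
  expect_error(segment_epochs(short, 10), class = "tinnconn_input_error")
  expect_error(segment_epochs(rec, 0), class = "tinnconn_input_error")
})

test_that("selection and segmentation commute", {
  withr::with_seed(13, {
    rec <- eeg_recording(matrix(rnorm(4 * 3000), 4), 100,
                         c("FT7", "Z1", "FC5", "Z2"))
  })
  keep <- c("FT7", "FC5")
  a <- segment_epochs(select_auditory_channels(rec, keep), 10)
  b <- lapply(segment_epochs(rec, 10), select_auditory_channels, names = keep)
  expect_length(a, length(b))
  for (i in seq_along(a)) expect_equal(a[[i]]$data, b[[i]]$data)
})

test_that("amplitude rejection drops contaminated epochs", {
  withr::with_seed(14, {
    rec <- eeg_recording(matrix(rnorm(2 * 4000, sd = 10), 2), 100,
                         c("a", "b"))
  })
  rec$data[1, 2500] <- 500   # artifact in epoch 3 (of 4 x 10 s)
  eps <- segment_epochs(rec, 10)
  kept <- reject_epochs(eps, 100)
  expect_length(kept, 3)
  expect_false(3 %in% vapply(kept, `[[`, 0L, "epoch_id"))
  expect_length(reject_epochs(eps, Inf), 4)
})

test_that("preprocess_recording runs the full chain", {
  labels <- c(auditory_channels(), "EXTRA")
  withr::with_seed(15, {
    rec <- eeg_recording(matrix(rnorm(13 * 250 * 25, sd = 5), 13), 250,
                         labels, group_label = "healthy")
  })
  eps <- preprocess_recording(rec, list(epoch_s = 5, reject_uv = Inf))
  expect_length(eps, 5)
  expect_equal(eps[[1]]$channel_labels, auditory_channels())
  expect_equal(eps[[1]]$label, "healthy")
})
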