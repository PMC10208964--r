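# signal conditioning: filtering, downsampling, re-referencing, epoching,
# spike rejection

make_rec <- function(x, fs = 500, events = NULL, ...)
  lfp_recording(matrix(x, nrow = 1), fs, events = events, ...)

subset_trials_export <- function(ep, idx)
  lfp_epochs(ep$data[idx, , , drop = FALSE], ep$fs, ep$t0,
             ep$conditions[idx])

test_that("band-pass attenuates line noise and passes the passband unshifted", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- make_rec(sin(2 * pi * 50 * t), fs)
  # use a wider low edge so the filter settles on a 10 s record
  out <- bandpass_and_notch(rec, band = c(1, 195), transition = 1)
  mid <- 1000:4000
  expect_lt(max(abs(out$data[1, mid])), 10^(-30 / 20))  # >= 30 dB down

  rec10 <- make_rec(sin(2 * pi * 10 * t), fs)
  out10 <- bandpass_and_notch(rec10, band = c(1, 195), transition = 1)
  amp <- max(abs(out10$data[1, mid]))
  expect_lt(abs(20 * log10(amp)), 1)                    # within 1 dB
  # zero-phase contract: cross-correlation peaks at lag 0
  cc <- ccf(out10$data[1, mid], rec10$data[1, mid], lag.max = 10,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("high-pass removes DC offsets", {
  fs <- 500
  rec <- make_rec(rep(100, 10 * fs), fs)
  out <- bandpass_and_notch(rec, band = c(1, 195), transition = 1)
  expect_lt(abs(mean(out$data[1, 1000:4000])), 1)
})

test_that("downsampling keeps lengths, removes aliases, remaps events", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t)
  rec <- make_rec(x, fs, events = data.frame(onset = 1001,
                                             condition = "neutral"))
  out <- downsample_recording(rec, 500)
  expect_equal(ncol(out$data), 5000)
  expect_equal(out$fs, 500)
  # event at sample 1001 (0-based 1000) -> 0-based 500 -> sample 501
  expect_equal(out$events$onset, 501)
  mid <- out$data[1, 1000:4000]
  p100 <- oracle_band_power(mid, 500, c(98, 102))
  p_alias <- oracle_band_power(mid, 500, c(198, 202))  # 300 Hz would fold to 200
  expect_gt(p100, 0.4)                                  # survives
  expect_lt(10 * log10(p_alias / p100), -40)            # removed
  expect_error(downsample_recording(out, 1000), "exceeds")
})

test_that("bipolar re-referencing cancels common signals and gates regions", {
  fs <- 500
  n <- 1000
  common <- rnorm(n)
  priv <- matrix(rnorm(8 * n), 8, n)
  data <- sweep(priv, 2, common, `+`)
  rec <- lfp_recording(data, fs,
                       channel_labels = paste0("A", 1:8),
                       region_labels = c(rep("amygdala", 5), rep("OFC", 3)))
  layout <- list(A = paste0("A", 1:8))
  out <- suppressMessages(bipolar_rereference(rec, layout))
  # 7 adjacent pairs minus the one mixed-region pair (A5-A6)
  expect_equal(nrow(out$data), 6)
  expect_false("A5-A6" %in% out$channel_labels)
  # reference-free: common signal cancels exactly
  rec2 <- lfp_recording(data + matrix(rep(rnorm(n), each = 8), 8, n), fs,
                        channel_labels = paste0("A", 1:8),
                        region_labels = c(rep("amygdala", 5), rep("OFC", 3)))
  out2 <- suppressMessages(bipolar_rereference(rec2, layout))
  # different added common signal, identical bipolar output
  expect_equal(out$data[1, ], priv[1, ] - priv[2, ])
  expect_equal(out2$data[1, ], priv[1, ] - priv[2, ])
  # identical adjacent contacts give exactly zero
  rec3 <- lfp_recording(rbind(common, common), fs,
                        channel_labels = c("B1", "B2"))
  out3 <- bipolar_rereference(rec3, list(B = c("B1", "B2")))
  expect_true(all(out3$data == 0))
  expect_error(bipolar_rereference(rec, list(A = c("A1", "ZZ"))), "unknown")
})

test_that("an 8-contact shaft yields exactly 7 bipolar channels", {
  rec <- lfp_recording(matrix(rnorm(8 * 500), 8, 500), 500,
                       channel_labels = paste0("A", 1:8),
                       region_labels = rep("amygdala", 8))
  out <- bipolar_rereference(rec, list(A = paste0("A", 1:8)))
  expect_equal(nrow(out$data), 7)
  expect_equal(out$channel_labels[1], "A1-A2")
  expect_equal(unique(out$region_labels), "amygdala")
})

test_that("epoching produces the stated geometry and drops edge trials", {
  fs <- 500
  onsets <- seq(500, by = 1300, length.out = 90)
  n <- max(onsets) + 1100
  rec <- lfp_recording(matrix(rnorm(n), 1, n), fs,
                       events = data.frame(
                         onset = onsets,
                         condition = rep(c("positive", "neutral", "negative"), 30)))
  ep <- epoch_recording(rec, 0.5, 2.0)
  expect_equal(dim(ep$data), c(90, 1, 1250))
  expect_equal(ep$t0, -0.5)
  expect_true(all(ep$kept))

  rec$events$onset[1] <- 100     # needs 250 samples of history
  ep2 <- epoch_recording(rec, 0.5, 2.0)
  expect_false(ep2$kept[1])
  expect_equal(ep2$reasons[1], "edge")
  expect_equal(sum(ep2$kept) + sum(!ep2$kept), 90)

  # no filtering inside epoching: constant in, constant out
  rec$data[] <- 3.14
  ep3 <- epoch_recording(rec, 0.5, 2.0)
  expect_true(all(ep3$data[2, 1, ] == 3.14))
})

test_that("spike rejection flags short transients and only those", {
  pd <- small_paradigm(30)
  ep <- simulate_ersp_dataset(pd, seed = 20)
  clean <- reject_spike_trials(ep)
  expect_equal(sum(!clean$kept), 0)   # P(|z|>6) ~ 2e-9 per sample

  sdc <- sd(ep$data[, 1, ])
  ep_sp <- inject_transient(ep, trial = 7, channel = 1, at_s = 0.5,
                            width_s = 0.1, amplitude = 10 * sdc)
  out <- reject_spike_trials(ep_sp)
  expect_false(out$kept[7])
  expect_equal(out$reasons[7], "spike")
  expect_equal(sum(!out$kept), 1)

  # 400 ms transient exceeds the spike width gate: not rejected by this
  # rule (amplitude chosen so the suprathreshold run itself spans > 250 ms)
  ep_long <- inject_transient(ep, trial = 9, channel = 1, at_s = 0.5,
                              width_s = 0.4, amplitude = 30 * sdc)
  out2 <- reject_spike_trials(ep_long)
  expect_true(out2$kept[9])

  expect_error(reject_spike_trials(subset_trials_export(ep, 1:5)),
               "at least")
})
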