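test_that("the full-epoch periodogram has 257 one-sided bins", {
  ep <- tiny_dataset()$epochs[[1]]
  psd <- psd_fft(ep)
  expect_equal(dim(psd$values), c(4, 257))
  expect_equal(psd$freqs[1], 0)
  expect_equal(psd$freqs[257], 64)
  expect_true(all(psd$values >= 0))
  expect_error(psd_fft(ep, channels = "Cz"), "unknown channel")
})

test_that("PSD normalisation is Parseval-consistent", {
  # pure tone: total PSD power equals the time-domain mean square
  ep <- sinusoid_epoch(freq = 10)
  psd <- psd_fft(ep, "F3")
  df <- 128 / 512
  expect_equal(sum(psd$values) * df, mean(ep$signal["F3", ]^2),
               tolerance = 0.01)
  # and on random epochs (property over generated cases)
  set.seed(31)
  cfg <- synth_config(seed = 31)
  for (i in 1:20) {
    ep <- make_epoch(cfg, i, sample(c("like", "dislike"), 1))
    psd <- psd_fft(ep, "AF4")
    expect_equal(sum(psd$values) * df, mean(ep$signal["AF4", ]^2),
                 tolerance = 0.01)
  }
})

test_that("band powers isolate a pure tone and floor degenerate input", {
  psd <- psd_fft(sinusoid_epoch(freq = 10), "F3")
  a <- band_power(psd, "F3", "alpha")
  for (b in c("theta", "beta", "gamma"))
    expect_gt(a, 20 * band_power(psd, "F3", b))
  zp <- psd_fft(zero_epoch(), "F3")
  expect_true(all(zp$values == 0))
  expect_equal(band_power(zp, "F3", "alpha"), 1e-12)
  expect_error(band_power(psd, "F3", c(50, 70)), "Nyquist")
})

test_that("white-noise band powers are flat across frequency", {
  # flat-spectrum oracle: mean band power independent of the band, so
  # per-band averages agree within Monte-Carlo error
  set.seed(17)
  acc <- matrix(0, 500, 4, dimnames = list(NULL, names(eegpref:::EEG_BANDS)))
  for (i in 1:500) {
    sig <- matrix(rnorm(14 * 512), 14, 512,
                  dimnames = list(eegpref:::EPOC_CHANNELS, NULL))
    ep <- structure(list(signal = sig, channel_names = rownames(sig),
                         fs = 128, label = "like", subject_id = 1L,
                         trial_id = 1L), class = "eeg_epoch")
    psd <- psd_fft(ep, "F3")
    for (b in colnames(acc)) acc[i, b] <- band_power(psd, "F3", b)
  }
  m <- colMeans(acc)
  expect_true(all(abs(m / mean(m) - 1) < 0.05))
})

test_that("Morlet average power peaks at the stimulus frequency", {
  v <- morlet_avg_power(sinusoid_epoch(freq = 10), "F3")
  expect_length(v, 61)
  expect_true(all(v >= 0))
  grid <- seq(4, 45, length.out = 61)
  expect_lt(abs(grid[which.max(v)] - 10), 1.5)
  expect_true(all(morlet_avg_power(zero_epoch(), "F3") == 0))
  expect_error(morlet_avg_power(sinusoid_epoch(), "Cz"), "unknown")
})

test_that("Hann spectrogram features match a single-window periodogram", {
  ep <- sinusoid_epoch(freq = 10)   # bin-centred at the 128-point grid
  v <- spectrogram_hann(ep, "F3")
  expect_length(v, 65)
  # single-window oracle: Hann-windowed 128-point periodogram
  w <- as.numeric(signal::hanning(128))
  X <- fft(ep$signal["F3", 1:128] * w)
  p <- Mod(X[1:65])^2 / (128 * sum(w^2))
  p[2:64] <- 2 * p[2:64]
  keep <- p > max(p) * 1e-6   # compare where the tone has support
  expect_true(all(abs(v[keep] / p[keep] - 1) < 0.05))
  expect_true(all(spectrogram_hann(zero_epoch(), "F3") == 0))
  short <- zero_epoch(n = 64)
  expect_error(spectrogram_hann(short, "F3"), "shorter")
})

test_that("assembled feature vectors have the documented composition", {
  ep <- tiny_dataset()$epochs[[1]]
  fv <- assemble_features(ep)
  expect_length(fv, 4 * 257 + 2 * 257 + 4 * 61 + 4 * 65 + 10)
  expect_false(anyDuplicated(names(fv)) > 0)
  fv2 <- assemble_features(tiny_dataset()$epochs[[2]])
  expect_identical(names(fv), names(fv2))
  # identical signals on all four channels: sum block = 4 x average block
  ep_same <- sinusoid_epoch(freq = 9)
  fvs <- assemble_features(ep_same, blocks = "psd_agg")
  sums <- fvs[grep("^psd_sum_", names(fvs))]
  avgs <- fvs[grep("^psd_avg_", names(fvs))]
  expect_equal(unname(sums), unname(4 * avgs))
})

test_that("features are keyed by channel name, not row position", {
  ep <- tiny_dataset()$epochs[[3]]
  perm <- sample(nrow(ep$signal))
  ep2 <- ep
  ep2$signal <- ep$signal[perm, ]
  ep2$channel_names <- ep$channel_names[perm]
  expect_equal(assemble_features(ep), assemble_features(ep2))
})

test_that("feature tables round-trip through the delimited text writer", {
  ds <- tiny_dataset()
  ft <- extract_feature_table(ds, blocks = "indices")
  expect_equal(nrow(ft$matrix), length(ds$epochs))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, f)
  back <- read_feature_table(f)
  expect_identical(back$feature_names, ft$feature_names)
  expect_identical(back$labels, ft$labels)
  expect_equal(back$matrix, ft$matrix, tolerance = 1e-6)
})
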