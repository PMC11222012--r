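sine_rec <- function(freq, fs = 512, dur = 10, nch = 1, phase = 0) {
  t <- (0:(fs * dur - 1)) / fs
  eeg_recording(matrix(rep(sin(2 * pi * freq * t + phase), each = nch),
                       nrow = nch, byrow = FALSE), fs)
}

test_that("resampling preserves duration and spectral content", {
  t <- (0:9999) / 1000
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t)), 1000)
  out <- resample_recording(rec, 512)
  expect_equal(out$fs, 512)
  expect_equal(ncol(out$samples), 5120)
  # spectral peak still at 10 Hz (FFT oracle)
  sp <- Mod(fft(out$samples[1, ]))^2
  half <- 1:2560
  peak_hz <- (which.max(sp[half]) - 1) * 512 / 5120
  expect_equal(peak_hz, 10, tolerance = 0.1)
  # identity when rates match
  expect_identical(resample_recording(out, 512), out)
})

test_that("default bandpass passes 10 Hz, rejects DC and 60 Hz", {
  mid <- 1500:3600
  r10 <- bandpass_recording(sine_rec(10))
  gain10 <- sqrt(mean(r10$samples[1, mid]^2)) / sqrt(0.5)
  expect_equal(gain10, 1, tolerance = 0.05)
  r60 <- bandpass_recording(sine_rec(60))
  expect_lt(sqrt(mean(r60$samples[1, mid]^2)) / sqrt(0.5), 0.01)
  rdc <- bandpass_recording(eeg_recording(matrix(1, 1, 5120), 512))
  expect_lt(max(abs(rdc$samples[1, mid])), 0.02)
  expect_error(bandpass_recording(sine_rec(10), hi = 300), "Nyquist")
  expect_error(bandpass_recording(sine_rec(10), lo = 0), "lo < hi")
})

test_that("filtering is zero-phase for mid-band content", {
  rec <- sine_rec(10)
  out <- bandpass_recording(rec)
  lags <- -20:20
  cc <- vapply(lags, function(l) {
    idx <- 1000:4000
    cor(rec$samples[1, idx], out$samples[1, idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("epoching honors annotations, labels and boundary rules", {
  fs <- 128
  rec <- eeg_recording(matrix(rnorm(2 * 60 * fs), 2), fs)
  ann <- data.frame(onset_s = seq(0, 50, by = 10), duration_s = 10,
                    state = c("normal", "cognitive", "visual", "normal",
                              "cognitive", "visual"))
  eps <- epoch_recording(rec, ann, epoch_s = 10)
  expect_length(eps, 6)
  expect_identical(eps[[3]]$state, "visual")
  expect_identical(dim(eps[[1]]$samples), c(2L, 1280L))
  # per-channel baseline correction
  expect_lt(max(abs(rowMeans(eps[[1]]$samples))), 1e-10)
  # annotation extending past the end is dropped with a message
  ann2 <- rbind(ann[1:5, ], data.frame(onset_s = 52, duration_s = 10,
                                       state = "normal"))
  expect_message(eps2 <- epoch_recording(rec, ann2, epoch_s = 10), "dropping")
  expect_length(eps2, 5)
  # overlap warns, out-of-range onset rejected
  ann3 <- data.frame(onset_s = c(0, 5), duration_s = 10,
                     state = c("normal", "visual"))
  expect_warning(epoch_recording(rec, ann3, epoch_s = 10), "overlap")
  expect_error(epoch_recording(rec, data.frame(onset_s = 70, duration_s = 10,
                                               state = "normal")),
               "outside")
})

test_that("band decomposition assigns tones to their bands", {
  for (method in c("wpt", "fir")) {
    for (probe in list(c(10, "alpha"), c(6, "theta"), c(2, "delta"), c(20, "beta"))) {
      f0 <- as.numeric(probe[1])
      rec <- sine_rec(f0)
      ep <- decompose_bands(eeg_epoch(rec$samples, rec$fs, "normal"),
                            method = method)
      energies <- vapply(ep$bands, function(m) sum(m^2), numeric(1))
      expect_gte(energies[[probe[2]]] / sum(sin(2 * pi * f0 * (0:5119) / 512)^2),
                 0.8)
      expect_identical(names(which.max(energies)), probe[2])
    }
  }
  expect_error(decompose_bands(eeg_epoch(matrix(0, 1, 5120), 512, "normal"),
                               method = "dct"), "arg")
})

test_that("band signals preserve shape, partition energy, and vanish on zeros", {
  set.seed(4)
  ep <- eeg_epoch(matrix(rnorm(2 * 5120), 2), 512, "normal")
  dec <- decompose_bands(ep)
  for (b in names(dec$bands)) expect_identical(dim(dec$bands[[b]]), dim(ep$samples))
  # summed band energy matches the 0.5-30 Hz content of the input
  x <- ep$samples[1, ]
  target <- band_energy_fraction(x, 512, 0.5, 30) * sum(x^2)
  got <- sum(Reduce(`+`, lapply(dec$bands, function(m) m[1, ]))^2)
  expect_equal(got, target, tolerance = 0.1)
  zero <- decompose_bands(eeg_epoch(matrix(0, 1, 5120), 512, "normal"))
  for (b in names(zero$bands)) expect_true(all(zero$bands[[b]] == 0))
})

test_that("wavelet packet transform reconstructs exactly and maps bands disjointly", {
  set.seed(2)
  x <- rnorm(1024)
  terms <- drivernet:::wpt_analyze(rbind(x), 5)
  xr <- drivernet:::wpt_synthesize(terms, 5, 1024)
  expect_equal(drop(xr), x, tolerance = 1e-9)
  at <- drivernet:::wpt_band_assignment(eeg_bands(), 512, 7)
  expect_false(any(duplicated(at$node)))
  # 2-Hz nodes at level 7: delta 2, theta 2, alpha 3 (incl. 12-14), beta 8
  expect_equal(unname(table(at$band)[c("delta", "theta", "alpha", "beta")]),
               c(2L, 2L, 3L, 8L), ignore_attr = TRUE)
})

test_that("EDF files round-trip within 16-bit quantization", {
  set.seed(44)
  rec <- eeg_recording(matrix(rnorm(3 * 256, sd = 40), 3), 128,
                       labels = c("Fz", "Cz", "Pz"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, 128)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$samples, rec$samples,
               tolerance = 2 * max(abs(rec$samples)) / 65535)
  junk <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw("9       not an edf header"), junk)
  expect_error(read_edf(junk), "not an EDF")
})
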