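test_that("PLV is exact for identical and constant-phase-shifted sinusoids", {
  t <- (0:5119) / 512
  x <- sin(2 * pi * 10 * t)
  y <- sin(2 * pi * 10 * t + pi / 3)
  m <- plv_matrix(rbind(x, x, y), band = "alpha")
  expect_equal(m[1, 2], 1, tolerance = 1e-6)
  expect_equal(m[1, 3], 1, tolerance = 1e-6)
  expect_identical(attr(m, "estimator"), "PLV")
  expect_true(all(diag(m) == 0))
})

test_that("PLV ignores signal amplitude", {
  set.seed(8)
  x <- drivernet:::nb_noise(2048, 512, 8, 13)
  y <- drivernet:::nb_noise(2048, 512, 8, 13)
  m1 <- plv_matrix(rbind(x, y))
  m2 <- plv_matrix(rbind(3.7 * x, y))
  expect_equal(m1[1, 2], m2[1, 2], tolerance = 1e-12)
})

test_that("PLV of independent uniform phases follows the Rayleigh baseline", {
  set.seed(13)
  n <- 5120
  vals <- replicate(200, {
    phi <- rbind(runif(n, -pi, pi), runif(n, -pi, pi))
    drivernet:::plv_from_phases(phi)[1, 2]
  })
  expected <- sqrt(pi) / (2 * sqrt(n))
  expect_lt(abs(mean(vals) - expected) / expected, 0.2)
})

test_that("constant channels yield zero PLV entries with a message", {
  set.seed(1)
  x <- rnorm(1024)
  expect_message(m <- plv_matrix(rbind(x, 0 * x)), "constant")
  expect_equal(m[1, 2], 0)
})

test_that("coherence is 1 for linear copies and symmetric by construction", {
  set.seed(3)
  x <- drivernet:::nb_noise(5120, 512, 8, 13)
  m <- coh_matrix(rbind(x, 2 * x), 512, eeg_bands("alpha"))
  expect_gte(m[1, 2], 0.99)
  set.seed(4)
  z <- matrix(rnorm(3 * 5120), 3)
  m2 <- coh_matrix(z, 512, eeg_bands("beta"))
  expect_identical(m2, t(m2))
  expect_error(coh_matrix(rbind(x, x), 512, eeg_bands("alpha"),
                          spectral_params(seg_s = 10, overlap = 0)),
               "at least 2")
})

test_that("coherence of independent noise matches the 1/n_segments bias", {
  set.seed(21)
  p <- spectral_params(seg_s = 1, overlap = 0, taper = "rect")
  vals <- replicate(100, {
    z <- matrix(rnorm(2 * 4096), 2)          # 8 non-overlapping 512-sample segments
    coh_matrix(z, 512, data.frame(band = "broad", lo = 10, hi = 100), p)[1, 2]
  })
  expect_lt(abs(mean(vals) - 1 / 8) / (1 / 8), 0.2)
})

test_that("SL is 1 for identical chaotic signals and ~p_ref for independent noise", {
  h <- henon_pair(2048, coupling = 0, seed = 2)
  p <- sl_params(m = 5, lag = 1, w1 = 16)
  m <- sl_matrix(rbind(h$x, h$x), p)
  expect_gte(m[1, 2], 0.95)
  set.seed(5)
  vals <- replicate(10, sl_matrix(rbind(rnorm(5120), rnorm(5120)),
                                  sl_params())[1, 2])
  expect_lt(abs(mean(vals) - 0.05), 0.015)
})

test_that("SL increases with Henon map coupling", {
  p <- sl_params(m = 5, lag = 1, w1 = 16)
  means <- vapply(c(0, 0.4, 0.8), function(cc) {
    mean(vapply(1:8, function(s) {
      h <- henon_pair(2048, coupling = cc, seed = 400 + s)
      sl_matrix(rbind(h$x, h$y), p)[1, 2]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("SL rejects epochs too short for the embedding with a diagnostic", {
  expect_error(sl_matrix(matrix(rnorm(2 * 500), 2), sl_params()),
               "epoch too short")
  expect_error(sl_params(m = 1), "m >= 2")
})

test_that("optional SL rescaling maps the p_ref floor to zero", {
  set.seed(6)
  x <- matrix(rnorm(2 * 5120), 2)
  raw <- sl_matrix(x, sl_params())
  res <- sl_matrix(x, sl_params(), rescale = TRUE)
  expect_lt(res[1, 2], raw[1, 2])
  expect_gte(min(res), 0)
})

test_that("all estimators stay within [0,1] and symmetric on arbitrary input", {
  set.seed(30)
  p <- sl_params(m = 3, lag = 2, w1 = 8, n_recur = 5)
  for (i in 1:25) {
    kind <- i %% 5
    x <- switch(kind + 1,
      matrix(rnorm(3 * 1200), 3),
      matrix(rnorm(3 * 1200, sd = 100), 3),
      matrix(rep(sin(2 * pi * 7 * (1:1200) / 512), 3), 3, byrow = TRUE) +
        matrix(rnorm(3 * 1200, sd = 0.01), 3),
      matrix(runif(3 * 1200, -1, 1), 3),
      matrix(rt(3 * 1200, df = 3), 3))
    for (m in list(sl_matrix(x, p), plv_matrix(x),
                   coh_matrix(x, 512, data.frame(band = "b", lo = 1, hi = 100),
                              spectral_params(seg_s = 0.5)))) {
      expect_true(all(m >= 0 & m <= 1))
      expect_identical(unclass(m), unclass(t(m)))
      expect_true(all(diag(m) == 0))
    }
  }
})

test_that("mean strength averages positive upper-triangle entries", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.2
  m[1, 3] <- m[3, 1] <- 0.4
  expect_equal(mean_strength(m), 0.3)
  expect_equal(mean_strength(matrix(0, 4, 4)), 0)
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  expect_equal(mean_strength(ones), 1)
})

test_that("connectivity matrices survive the text round-trip", {
  set.seed(9)
  x <- matrix(rnorm(4 * 2048), 4)
  m <- plv_matrix(x, band = "theta")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity(m, path)
  back <- read_connectivity(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-8)
  expect_identical(attr(back, "band"), "theta")
})

test_that("connectivity_epoch computes the full estimator-by-band grid", {
  set.seed(10)
  rec <- generate_epoch(state_coupling_spec("cognitive", nonlinear = TRUE),
                        6, 512, 4, seed = 2)
  ep <- decompose_bands(eeg_epoch(rec$samples, 512, "cognitive"), method = "fir")
  conn <- connectivity_epoch(ep, c("PLV", "COH"))
  expect_named(conn, c("PLV", "COH"))
  expect_named(conn$PLV, drivernet:::band_names())
  expect_error(connectivity_epoch(eeg_epoch(rec$samples, 512, "normal")),
               "decompose_bands")
})
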