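test_that("generated epochs have the contracted shape and are deterministic", {
  spec <- state_coupling_spec("normal")
  r1 <- generate_epoch(spec, n_channels = 8, fs = 512, duration = 10, seed = 7)
  expect_s3_class(r1, "eeg_recording")
  expect_identical(dim(r1$samples), c(8L, 5120L))
  r2 <- generate_epoch(spec, n_channels = 8, fs = 512, duration = 10, seed = 7)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_epoch(spec, n_channels = 8, fs = 512, duration = 10, seed = 8)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("invalid generator inputs are rejected with diagnostics", {
  spec <- state_coupling_spec("normal")
  expect_error(generate_epoch(spec, 8, 512, -1, seed = 1), "duration")
  bad_bands <- data.frame(band = "gamma", lo = 30, hi = 45)
  expect_error(generate_epoch(spec, 8, 512, 2, seed = 1, bands = bad_bands),
               "invalid band")
  expect_error(state_coupling_spec("normal", kappa = c(delta = 1.2, theta = 0,
                                                       alpha = 0, beta = 0)),
               "\\[0, 1\\]")
  expect_error(state_coupling_spec("normal", noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(0, 3), "n_subjects")
  expect_error(cohort_spec(2, 2, fs = 512, duration = 1.0001), "integer sample")
})

test_that("band components are spectrally pure and epochs carry band peaks", {
  set.seed(42)
  bands <- eeg_bands()
  for (bi in seq_len(nrow(bands))) {
    x <- drivernet:::nb_noise(5120, 512, bands$lo[bi], bands$hi[bi])
    expect_gte(band_energy_fraction(x, 512, bands$lo[bi], bands$hi[bi]), 0.8)
    expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-8)
  }
  # a noiseless linear epoch concentrates its energy under 30 Hz
  spec <- state_coupling_spec("normal", noise_sd = 0)
  rec <- generate_epoch(spec, 4, 512, 4, seed = 3)
  for (ch in 1:4)
    expect_gte(band_energy_fraction(rec$samples[ch, ], 512, 0.5, 30), 0.95)
})

test_that("cohort generation yields the labeled grid and regenerates identically", {
  cs <- cohort_spec(2, 3, n_channels = 6, fs = 256, duration = 2, seed = 9)
  cohort <- generate_cohort(cs)
  expect_length(cohort, 18)
  states <- vapply(cohort, `[[`, character(1), "state")
  expect_equal(unname(table(states)[drivernet:::driving_states()]),
               rep(6L, 3), ignore_attr = TRUE)
  cohort2 <- generate_cohort(cs)
  expect_identical(lapply(cohort, `[[`, "samples"),
                   lapply(cohort2, `[[`, "samples"))
  # distinct epochs differ
  expect_false(identical(cohort[[1]]$samples, cohort[[2]]$samples))
})

test_that("zero theta coupling reproduces the independent-phase PLV baseline", {
  # Monte-Carlo oracle: PLV between independent theta-band signals
  set.seed(11)
  n <- 2560; fs <- 512
  oracle <- replicate(60, {
    a <- drivernet:::nb_noise(n, fs, 4, 8)
    b <- drivernet:::nb_noise(n, fs, 4, 8)
    plv_matrix(rbind(a, b), band = "theta")[1, 2]
  })
  spec <- state_coupling_spec("normal",
                              kappa = c(delta = 0.3, theta = 0, alpha = 0.3, beta = 0.3))
  vals <- vapply(1:20, function(s) {
    rec <- generate_epoch(spec, 4, fs, n / fs, seed = 100 + s)
    ep <- decompose_bands(eeg_epoch(rec$samples, fs, "normal"), method = "fir")
    m <- plv_matrix(ep$bands$theta, band = "theta")
    mean(m[1:2, 1:2][upper.tri(diag(2))])
  }, numeric(1))
  # coupled-pair mean should sit at the independent baseline, not above it
  tol <- 3 * sd(oracle) / sqrt(20) + 3 * sd(vals) / sqrt(20)
  expect_lt(abs(mean(vals) - mean(oracle)), max(tol, 0.02))
})

test_that("stronger theta coupling raises cohort theta-band PLV strength", {
  mk <- function(kth) state_coupling_spec("normal",
    kappa = c(delta = 0.2, theta = kth, alpha = 0.2, beta = 0.2))
  strength <- function(spec, seed) {
    rec <- generate_epoch(spec, 8, 512, 5, seed = seed)
    ep <- decompose_bands(eeg_epoch(rec$samples, 512, "normal"), method = "fir")
    mean_strength(plv_matrix(ep$bands$theta, band = "theta"))
  }
  lo <- vapply(1:8, function(s) strength(mk(0.1), s), numeric(1))
  hi <- vapply(1:8, function(s) strength(mk(0.6), s), numeric(1))
  expect_gt(mean(hi), mean(lo) + 0.05)
})

test_that("cohorts round-trip through the TSV manifest format", {
  cs <- cohort_spec(1, 2, n_channels = 4, fs = 256, duration = 1, seed = 5)
  cohort <- generate_cohort(cs)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, cspec = cs)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "cohort_spec.json")))
  back <- read_cohort(dir)
  expect_length(back, length(cohort))
  expect_equal(back[[3]]$samples, cohort[[3]]$samples, tolerance = 1e-6)
  expect_identical(vapply(back, `[[`, character(1), "state"),
                   vapply(cohort, `[[`, character(1), "state"))
})

test_that("per-epoch seeds are stable and distinct", {
  s1 <- drivernet:::epoch_seed(42, 1, "normal", 1)
  expect_identical(s1, drivernet:::epoch_seed(42, 1, "normal", 1))
  grid <- expand.grid(subj = 1:4, state = drivernet:::driving_states(),
                      ep = 1:5, stringsAsFactors = FALSE)
  seeds <- mapply(drivernet:::epoch_seed, 42, grid$subj, grid$state, grid$ep)
  expect_equal(length(unique(seeds)), nrow(grid))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
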