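# Seeded generator of EEG-like cohorts with band-specific, state-specific
# cross-channel coupling. Per band, channels in the coupled set share a
# narrowband stochastic oscillator mixed in with weight kappa against an
# independent narrowband component with weight (1 - kappa), so kappa acts as
# a graded synchronization dial for PLV/COH; an optional unidirectionally
# coupled Henon-map overlay adds the generalized-synchronization structure
# that SL is sensitive to.

#' Narrowband Gaussian noise via spectral synthesis
#'
#' Draws complex Gaussian Fourier coefficients on the bins whose center
#' frequency lies in `[lo, hi)` and inverts, yielding a stationary Gaussian
#' signal whose spectral support is exactly the requested band, normalized to
#' unit RMS.
#'
#' @noRd
nb_noise <- function(n, fs, lo, hi) {
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:(floor(n / 2))                   # positive-frequency bins, no DC/Nyquist
  sel <- half[freqs[half] >= lo & freqs[half] < hi]
  if (length(sel) == 0) stop("band [", lo, ",", hi, ") holds no frequency bin at n=", n)
  coef <- complex(real = rep(0, n), imaginary = rep(0, n))
  coef[sel] <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel)))
  coef[n + 2 - sel] <- Conj(coef[sel])       # Hermitian symmetry -> real signal
  x <- Re(fft(coef, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x / r
  x
}

#' State-specific coupling specification
#'
#' Describes how epochs of one driving state are generated: per-band coupling
#' strengths, the set of mutually coupled channels, oscillator amplitudes,
#' additive-noise level, and whether a nonlinear (Henon-map) coupling
#' component is superimposed on coupled channel pairs.
#'
#' @param state One of `"normal"`, `"cognitive"`, `"visual"`.
#' @param kappa Named numeric vector of coupling strengths in `[0, 1]` for
#'   `delta`, `theta`, `alpha`, `beta`.
#' @param coupled_channels Integer vector of channel indices sharing the
#'   band oscillators; `NULL` means the first half of the montage.
#' @param nonlinear Logical; superimpose unidirectionally coupled Henon-map
#'   trajectories on consecutive coupled channel pairs.
#' @param noise_sd Standard deviation of the additive white noise (signal
#'   units, >= 0).
#' @param amplitude Named numeric vector of per-band oscillator amplitudes.
#' @param henon_amp RMS amplitude of the Henon overlay relative to the band
#'   oscillators (only used when `nonlinear = TRUE`).
#' @return An object of class `state_coupling_spec`.
#' @export
state_coupling_spec <- function(state,
                                kappa = c(delta = 0.3, theta = 0.3, alpha = 0.3, beta = 0.3),
                                coupled_channels = NULL,
                                nonlinear = FALSE,
                                noise_sd = 0.5,
                                amplitude = c(delta = 1.0, theta = 0.9, alpha = 1.0, beta = 0.7),
                                henon_amp = 0.6) {
  state <- match.arg(state, driving_states())
  if (!all(band_names() %in% names(kappa)))
    stop("kappa must be named with all of: ", paste(band_names(), collapse = ", "))
  kappa <- kappa[band_names()]
  if (any(kappa < 0 | kappa > 1)) stop("kappa values must lie in [0, 1]")
  if (!all(band_names() %in% names(amplitude)))
    stop("amplitude must be named with all of: ", paste(band_names(), collapse = ", "))
  amplitude <- amplitude[band_names()]
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(state = state, kappa = kappa, coupled_channels = coupled_channels,
         nonlinear = isTRUE(nonlinear), noise_sd = noise_sd,
         amplitude = amplitude, henon_amp = henon_amp),
    class = "state_coupling_spec"
  )
}

#' Default per-state coupling specifications
#'
#' Encodes the qualitative state signature the analysis assumes: theta- and
#' beta-band coupling elevated under distraction, alpha coupling slightly
#' depressed; visual distraction carries the strongest theta elevation,
#' cognitive distraction the strongest beta elevation plus a nonlinear
#' (Henon) coupling component. Absolute levels are synthetic conventions of
#' this package, not measured values.
#'
#' @param noise_sd Additive-noise standard deviation passed to every state.
#' @return Named list of three [state_coupling_spec()] objects.
#' @export
default_state_specs <- function(noise_sd = 0.5) {
  list(
    normal = state_coupling_spec(
      "normal",
      kappa = c(delta = 0.25, theta = 0.20, alpha = 0.40, beta = 0.20),
      noise_sd = noise_sd
    ),
    cognitive = state_coupling_spec(
      "cognitive",
      kappa = c(delta = 0.30, theta = 0.40, alpha = 0.34, beta = 0.50),
      nonlinear = TRUE, noise_sd = noise_sd
    ),
    visual = state_coupling_spec(
      "visual",
      kappa = c(delta = 0.28, theta = 0.55, alpha = 0.32, beta = 0.35),
      noise_sd = noise_sd
    )
  )
}

#' Cohort specification
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param epochs_per_state Epochs generated per subject and state (>= 1).
#' @param n_channels Channel count (default 63, a full 10-10 montage minus
#'   reference).
#' @param fs Sampling rate in Hz (default 512).
#' @param duration Epoch duration in seconds (default 10); `duration * fs`
#'   must be an integer.
#' @param seed Master seed; per-epoch seeds are derived deterministically.
#' @param state_specs Named list of [state_coupling_spec()] objects for
#'   `normal`, `cognitive`, `visual`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, epochs_per_state, n_channels = 63,
                        fs = 512, duration = 10, seed = 1,
                        state_specs = default_state_specs()) {
  stopifnot(n_subjects >= 1, epochs_per_state >= 1, n_channels >= 2, fs > 0)
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9) stop("duration * fs must be an integer sample count")
  if (!all(driving_states() %in% names(state_specs)))
    stop("state_specs must contain: ", paste(driving_states(), collapse = ", "))
  structure(
    list(n_subjects = as.integer(n_subjects),
         epochs_per_state = as.integer(epochs_per_state),
         n_channels = as.integer(n_channels), fs = fs, duration = duration,
         seed = as.integer(seed), state_specs = state_specs[driving_states()]),
    class = "cohort_spec"
  )
}

# Stable per-epoch seed derived from (master seed, subject, state, epoch);
# arithmetic kept below 2^53 so the modular reduction is exact in doubles.
epoch_seed <- function(master, subject, state, epoch) {
  sidx <- match(state, driving_states())
  v <- (as.numeric(master) %% 2147483647) * 1000003 +
    as.numeric(subject) * 10007 + sidx * 101 + as.numeric(epoch)
  as.integer(v %% 2147483629)
}

#' Generate one synthetic EEG epoch
#'
#' Pure function of `(spec, seed)`: per band, a shared unit-RMS narrowband
#' oscillator is mixed into every coupled channel with weight `kappa[band]`
#' against an independent narrowband component with weight `1 - kappa[band]`;
#' uncoupled channels receive only independent components. White Gaussian
#' noise of standard deviation `noise_sd` is added, and, if the spec's
#' nonlinear flag is set, coupled Henon-map trajectories are superimposed on
#' consecutive coupled channel pairs.
#'
#' @param spec A [state_coupling_spec()].
#' @param n_channels Number of channels.
#' @param fs Sampling rate (Hz).
#' @param duration Epoch duration in seconds (> 0).
#' @param seed Integer seed.
#' @param bands Band definitions as from [eeg_bands()].
#' @return An [eeg_recording()] of shape `n_channels x (fs * duration)`.
#' @examples
#' rec <- generate_epoch(state_coupling_spec("normal"), n_channels = 8,
#'                       fs = 512, duration = 2, seed = 7)
#' @export
generate_epoch <- function(spec, n_channels, fs, duration, seed,
                           bands = eeg_bands()) {
  if (!inherits(spec, "state_coupling_spec")) stop("spec must be a state_coupling_spec")
  if (duration <= 0) stop("duration must be positive")
  check_band_defs(bands)
  if (!all(bands$band %in% band_names()))
    stop("invalid band name(s): ", paste(setdiff(bands$band, band_names()), collapse = ", "))
  n <- round(fs * duration)
  coupled <- spec$coupled_channels
  if (is.null(coupled)) coupled <- seq_len(ceiling(n_channels / 2))
  if (any(coupled < 1 | coupled > n_channels))
    stop("coupled_channels reference channels outside 1..", n_channels)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  X <- matrix(0, n_channels, n)
  for (bi in seq_len(nrow(bands))) {
    b <- bands$band[bi]
    shared <- nb_noise(n, fs, bands$lo[bi], bands$hi[bi])
    k <- spec$kappa[[b]]
    a <- spec$amplitude[[b]]
    for (ch in seq_len(n_channels)) {
      indep <- nb_noise(n, fs, bands$lo[bi], bands$hi[bi])
      w <- if (ch %in% coupled) k else 0
      X[ch, ] <- X[ch, ] + a * (w * shared + (1 - w) * indep)
    }
  }
  if (spec$nonlinear && length(coupled) >= 2) {
    npair <- floor(length(coupled) / 2)
    c_map <- mean(spec$kappa)               # coupling constant mapped from kappa
    for (p in seq_len(npair)) {
      hseed <- as.integer((seed + 104729 * p) %% 2147483647)
      h <- henon_pair(n, coupling = c_map, seed = hseed)
      i <- coupled[2 * p - 1]; j <- coupled[2 * p]
      X[i, ] <- X[i, ] + spec$henon_amp * (h$x - mean(h$x)) / sd(h$x)
      X[j, ] <- X[j, ] + spec$henon_amp * (h$y - mean(h$y)) / sd(h$y)
    }
  }
  if (spec$noise_sd > 0)
    X <- X + matrix(rnorm(n_channels * n, sd = spec$noise_sd), n_channels, n)
  eeg_recording(X, fs)
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_subjects * 3 states * epochs_per_state` labeled epochs with
#' per-epoch seeds derived deterministically from the master seed, so
#' regeneration from the same [cohort_spec()] is bit-identical.
#'
#' @param cspec A [cohort_spec()].
#' @return List of [eeg_epoch()] objects.
#' @export
generate_cohort <- function(cspec) {
  if (!inherits(cspec, "cohort_spec")) stop("cspec must be a cohort_spec")
  out <- vector("list", cspec$n_subjects * 3L * cspec$epochs_per_state)
  i <- 0L
  for (subj in seq_len(cspec$n_subjects)) {
    for (state in driving_states()) {
      sspec <- cspec$state_specs[[state]]
      for (ep in seq_len(cspec$epochs_per_state)) {
        sd_i <- epoch_seed(cspec$seed, subj, state, ep)
        rec <- generate_epoch(sspec, cspec$n_channels, cspec$fs,
                              cspec$duration, sd_i)
        i <- i + 1L
        out[[i]] <- eeg_epoch(rec$samples, rec$fs, state, subject = subj,
                              epoch = ep, labels = rec$labels)
      }
    }
  }
  out
}

#' Write / read a cohort as plain-text matrices plus a TSV manifest
#'
#' Each epoch is stored as one tab-delimited numeric matrix (channels x
#' samples); `manifest.tsv` records subject, state, epoch, file and sampling
#' rate, and the generating [cohort_spec()] (when given) is serialized as
#' JSON alongside.
#'
#' @param cohort List of [eeg_epoch()] objects.
#' @param dir Output directory (created if needed).
#' @param cspec Optional [cohort_spec()] to serialize with the data.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, cspec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(subject = character(), state = character(),
                    epoch = integer(), path = character(), fs = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(cohort)) {
    ep <- cohort[[i]]
    f <- sprintf("epoch_%04d.tsv", i)
    write.table(format(ep$samples, digits = 8, trim = TRUE),
                file.path(dir, f), sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    man <- rbind(man, data.frame(subject = as.character(ep$subject),
                                 state = ep$state, epoch = ep$epoch,
                                 path = f, fs = ep$fs, stringsAsFactors = FALSE))
  }
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(cspec)) {
    ser <- cspec
    ser$state_specs <- lapply(ser$state_specs, unclass)
    jsonlite::write_json(unclass(ser), file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- read.table(file.path(dir, "manifest.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    m <- as.matrix(read.table(file.path(dir, man$path[i]), sep = "\t"))
    dimnames(m) <- NULL
    eeg_epoch(m, man$fs[i], man$state[i], subject = man$subject[i],
              epoch = man$epoch[i])
  })
}
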