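# Pairwise synchronization estimators. All three return a symmetric
# channels x channels matrix with zero diagonal and entries in [0, 1],
# tagged with the estimator name and frequency band.

#' Connectivity matrix container
#'
#' @param values Symmetric numeric matrix with entries in `[0, 1]`.
#' @param estimator One of `"SL"`, `"PLV"`, `"COH"`.
#' @param band Band name.
#' @param labels Optional channel labels.
#' @return A matrix of class `connectivity_matrix` with attributes
#'   `estimator` and `band`.
#' @export
connectivity_matrix <- function(values, estimator, band = NA_character_,
                                labels = NULL) {
  estimator <- match.arg(estimator, c("SL", "PLV", "COH"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("values must be square")
  if (max(abs(values - t(values))) > 1e-12) stop("values must be symmetric")
  if (any(values < -1e-12 | values > 1 + 1e-12)) stop("entries must lie in [0, 1]")
  values <- pmin(pmax((values + t(values)) / 2, 0), 1)
  diag(values) <- 0
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  structure(values, estimator = estimator, band = band,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s / %s, %d x %d, mean strength %.4f\n",
              attr(x, "estimator"), attr(x, "band"), nrow(x), ncol(x),
              mean_strength(x)))
  invisible(x)
}

#' Synchronization likelihood parameters
#'
#' Defaults follow the canonical generalized-synchronization formulation:
#' embedding dimension `m = 10`, lag `l = 10` samples, Theiler window
#' `w1 = 2 l (m - 1)`, outer window `w2 = w1 + round(n_recur / p_ref)` so
#' that about `n_recur` recurrences per side fall inside the window at
#' reference probability `p_ref = 0.05`. `stride` subsamples the reference
#' time points (the likelihood is averaged over them).
#'
#' @param m Embedding dimension (>= 2).
#' @param lag Embedding lag in samples (>= 1).
#' @param w1 Theiler exclusion window in samples.
#' @param w2 Outer window in samples (> `w1`).
#' @param p_ref Reference recurrence probability in (0, 1).
#' @param n_recur Target recurrences per window side (sets the default `w2`).
#' @param stride Reference-point stride in samples.
#' @return An object of class `sl_params`.
#' @export
sl_params <- function(m = 10, lag = 10, w1 = 2 * lag * (m - 1),
                      p_ref = 0.05, n_recur = 10,
                      w2 = w1 + round(n_recur / p_ref), stride = 8) {
  stopifnot(m >= 2, lag >= 1, w1 >= 0, w2 > w1, p_ref > 0, p_ref < 1, stride >= 1)
  structure(list(m = as.integer(m), lag = as.integer(lag), w1 = as.integer(w1),
                 w2 = as.integer(w2), p_ref = p_ref, stride = as.integer(stride)),
            class = "sl_params")
}

#' Synchronization likelihood matrix
#'
#' Embedding-based nonlinear synchronization between every channel pair:
#' per-time-point critical distances are set by exact rank selection so the
#' within-window recurrence fraction equals `p_ref`, and the likelihood that
#' recurrences coincide across channels is averaged over reference times.
#' Independent signals score about `p_ref`; identical signals score 1. An
#' optional rescaling `(SL - p_ref) / (1 - p_ref)` maps that floor to 0
#' (default off; raw values are reported).
#'
#' @param x Channels-by-samples numeric matrix (one frequency band).
#' @param params An [sl_params()] object.
#' @param band Band name tag.
#' @param rescale Subtract the `p_ref` floor and renormalize (default FALSE).
#' @return A [connectivity_matrix()] tagged `"SL"`.
#' @export
sl_matrix <- function(x, params = sl_params(), band = NA_character_,
                      rescale = FALSE) {
  x <- as_signal_matrix(x)
  v <- sl_matrix_cpp(x, params$m, params$lag, params$w1, params$w2,
                     params$p_ref, params$stride)
  if (rescale) {
    v <- (v - params$p_ref) / (1 - params$p_ref)
    v[v < 0] <- 0
    diag(v) <- 0
  }
  connectivity_matrix(v, "SL", band)
}

# Analytic signal (FFT method): positive frequencies doubled, negative
# zeroed, DC/Nyquist kept.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# PLV from a channels x time matrix of instantaneous phases.
plv_from_phases <- function(phi) {
  Z <- exp(1i * phi)
  Mod(Z %*% Conj(t(Z))) / ncol(phi)
}

#' Phase locking value matrix
#'
#' Instantaneous phases are taken from the analytic signal of each (already
#' band-limited) channel; the PLV of a pair is the magnitude of the
#' time-averaged unit phasor of their phase difference. Amplitude-blind by
#' construction. All-zero (or constant) channels have undefined phase; their
#' entries are set to 0 with a message.
#'
#' @param x Channels-by-samples numeric matrix (one frequency band).
#' @param band Band name tag.
#' @return A [connectivity_matrix()] tagged `"PLV"`.
#' @export
plv_matrix <- function(x, band = NA_character_) {
  x <- as_signal_matrix(x)
  dead <- apply(x, 1, function(r) all(abs(r - r[1]) < .Machine$double.eps * 100))
  phi <- t(apply(x, 1, function(r) Arg(analytic_signal(r))))
  v <- plv_from_phases(phi)
  if (any(dead)) {
    message("PLV undefined for constant channel(s): ",
            paste(which(dead), collapse = ", "), "; entries set to 0")
    v[dead, ] <- 0
    v[, dead] <- 0
  }
  v <- pmin(v, 1)
  diag(v) <- 0
  connectivity_matrix(v, "PLV", band)
}

#' Welch spectral-estimation parameters
#'
#' @param seg_s Segment length in seconds (default 2, i.e. 0.5 Hz resolution
#'   at 512 Hz).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @param taper Taper applied per segment: `"hann"` or `"rect"`.
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(seg_s = 2, overlap = 0.5, taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  stopifnot(seg_s > 0, overlap >= 0, overlap < 1)
  structure(list(seg_s = seg_s, overlap = overlap, taper = taper),
            class = "spectral_params")
}

#' Band-averaged magnitude-squared coherence matrix
#'
#' Averaged modified periodograms (Welch): per-segment tapered FFTs give
#' segment cross- and auto-spectra; the magnitude-squared coherence
#' `|S_xy|^2 / (S_xx S_yy)` is formed from the segment averages and then
#' averaged over the frequency bins whose center lies in `[lo, hi)`. With a
#' single segment the estimate is identically 1, so at least 2 segments are
#' required. Channels with zero power in the band get 0 entries.
#'
#' @param x Channels-by-samples numeric matrix (one frequency band).
#' @param fs Sampling rate (Hz).
#' @param band_def One-row data.frame with `band`, `lo`, `hi` (as from
#'   [eeg_bands()]).
#' @param params A [spectral_params()] object.
#' @return A [connectivity_matrix()] tagged `"COH"`.
#' @export
coh_matrix <- function(x, fs, band_def, params = spectral_params()) {
  x <- as_signal_matrix(x)
  nch <- nrow(x)
  n <- ncol(x)
  seg <- round(params$seg_s * fs)
  if (seg > n) stop("segment length exceeds epoch length")
  step <- max(1, round(seg * (1 - params$overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  if (length(starts) < 2)
    stop("coherence requires at least 2 averaging segments ",
         "(single-segment coherence is identically 1)")
  win <- if (params$taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  } else rep(1, seg)
  freqs <- (0:(seg - 1)) * fs / seg
  bins <- which(freqs >= band_def$lo & freqs < band_def$hi & freqs <= fs / 2)
  if (length(bins) == 0) stop("no frequency bin inside band at this resolution")

  # accumulate cross-spectral matrices per in-band bin
  S <- array(0 + 0i, dim = c(nch, nch, length(bins)))
  for (s0 in starts) {
    Fseg <- mvfft(t(x[, s0:(s0 + seg - 1), drop = FALSE]) * win)  # seg x nch
    for (bi in seq_along(bins)) {
      v <- Fseg[bins[bi], ]
      S[, , bi] <- S[, , bi] + outer(v, Conj(v))
    }
  }
  msc <- matrix(0, nch, nch)
  for (bi in seq_along(bins)) {
    Sb <- S[, , bi]
    p <- Re(diag(Sb))
    denom <- outer(p, p)
    k2 <- matrix(0, nch, nch)
    pos <- denom > 0
    k2[pos] <- (Mod(Sb)^2)[pos] / denom[pos]
    msc <- msc + k2
  }
  msc <- msc / length(bins)
  msc <- pmin(msc, 1)
  diag(msc) <- 0
  connectivity_matrix((msc + t(msc)) / 2, "COH", band_def$band)
}

#' Mean connection strength
#'
#' Mean of the strictly positive off-diagonal upper-triangle entries of a
#' connectivity matrix (0 if none are positive).
#'
#' @param mat A [connectivity_matrix()] or plain symmetric matrix.
#' @return Scalar strength `V`.
#' @export
mean_strength <- function(mat) {
  v <- mat[upper.tri(mat)]
  v <- v[v > 0]
  if (length(v) == 0) return(0)
  mean(v)
}

#' Per-band connectivity matrices of one epoch
#'
#' Computes the requested estimators for every decomposed band of an epoch.
#'
#' @param epoch An [eeg_epoch()] with `$bands` filled (see
#'   [decompose_bands()]).
#' @param estimators Subset of `c("SL", "PLV", "COH")`.
#' @param sl An [sl_params()] object.
#' @param spectral A [spectral_params()] object.
#' @param bands Band definitions matching the epoch's decomposition.
#' @return Nested list: `result[[estimator]][[band]]` is a
#'   [connectivity_matrix()].
#' @export
connectivity_epoch <- function(epoch, estimators = c("SL", "PLV", "COH"),
                               sl = sl_params(), spectral = spectral_params(),
                               bands = eeg_bands()) {
  if (is.null(epoch$bands)) stop("epoch has no band decomposition; run decompose_bands() first")
  estimators <- match.arg(estimators, c("SL", "PLV", "COH"), several.ok = TRUE)
  out <- list()
  for (est in estimators) {
    out[[est]] <- list()
    for (bi in seq_len(nrow(bands))) {
      b <- bands$band[bi]
      xb <- epoch$bands[[b]]
      if (is.null(xb)) stop("epoch lacks band signal for ", b)
      out[[est]][[b]] <- switch(est,
        SL = sl_matrix(xb, sl, band = b),
        PLV = plv_matrix(xb, band = b),
        COH = coh_matrix(xb, epoch$fs, bands[bi, , drop = FALSE], spectral))
    }
  }
  out
}

as_signal_matrix <- function(x) {
  if (inherits(x, "eeg_recording")) x <- x$samples
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x))) stop("signal matrix must be finite numeric")
  x
}

#' Write / read a connectivity matrix as delimited text with a JSON sidecar
#'
#' @param mat A [connectivity_matrix()].
#' @param path Output path for the square tab-delimited matrix; the sidecar
#'   is written to `paste0(path, ".json")`.
#' @return `path` (write) or the validated [connectivity_matrix()] (read).
#' @export
write_connectivity <- function(mat, path) {
  write.table(format(unclass(mat), digits = 10, trim = TRUE), path,
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(estimator = attr(mat, "estimator"), band = attr(mat, "band"),
         n = nrow(mat)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  v <- as.matrix(read.table(path, sep = "\t"))
  dimnames(v) <- NULL
  connectivity_matrix(v, meta$estimator, meta$band)
}
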