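#' Multichannel EEG recording container
#'
#' A lightweight container for a channels-by-samples signal matrix with its
#' sampling rate and channel labels (10-10 names or plain indices).
#'
#' @param samples Numeric matrix, channels in rows, time samples in columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of channel labels; defaults to
#'   `ch01, ch02, ...`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, labels = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(samples)))
  if (length(labels) != nrow(samples))
    stop("label count (", length(labels), ") must equal channel count (", nrow(samples), ")")
  structure(
    list(samples = samples, fs = fs, labels = as.character(labels)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
    nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

n_channels <- function(rec) nrow(rec$samples)
n_samples <- function(rec) ncol(rec$samples)

#' Labeled EEG epoch
#'
#' A fixed-length recording segment carrying a driving-state label, subject
#' and epoch identifiers, and (once decomposed) per-band signal matrices.
#'
#' @param samples Channels-by-samples numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param state One of `"normal"`, `"cognitive"`, `"visual"`.
#' @param subject Subject identifier (integer or character).
#' @param epoch Epoch index within (subject, state).
#' @param labels Optional channel labels.
#' @param bands Optional named list of band signal matrices (same shape as
#'   `samples`), as filled by [decompose_bands()].
#' @return An object of class `eeg_epoch` (inherits `eeg_recording`).
#' @export
eeg_epoch <- function(samples, fs, state, subject = 1L, epoch = 1L,
                      labels = NULL, bands = NULL) {
  state <- match.arg(state, driving_states())
  rec <- eeg_recording(samples, fs, labels)
  rec$state <- state
  rec$subject <- subject
  rec$epoch <- epoch
  rec$bands <- bands
  class(rec) <- c("eeg_epoch", "eeg_recording")
  rec
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf(
    "<eeg_epoch> subject %s, state %s, epoch %s: %d channels x %d samples @ %g Hz%s\n",
    x$subject, x$state, x$epoch, nrow(x$samples), ncol(x$samples), x$fs,
    if (is.null(x$bands)) "" else sprintf(" [%s]", paste(names(x$bands), collapse = ","))
  ))
  invisible(x)
}
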