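#' Canonical EEG frequency bands
#'
#' Returns the four-band partition used throughout the pipeline: delta
#' (0.5--4 Hz), theta (4--8 Hz), alpha (8--13 Hz), beta (13--30 Hz).
#' Band edges are treated as half-open intervals `[lo, hi)` so the shared
#' boundaries at 4, 8 and 13 Hz belong to the upper band.
#'
#' @param names Optional character vector selecting a subset of bands.
#' @return A data.frame with columns `band`, `lo`, `hi` (Hz).
#' @examples
#' eeg_bands()
#' eeg_bands("theta")
#' @export
eeg_bands <- function(names = NULL) {
  defs <- data.frame(
    band = c("delta", "theta", "alpha", "beta"),
    lo   = c(0.5, 4, 8, 13),
    hi   = c(4, 8, 13, 30),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) return(defs)
  unknown <- setdiff(names, defs$band)
  if (length(unknown) > 0)
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  defs[match(names, defs$band), , drop = FALSE]
}

band_names <- function() c("delta", "theta", "alpha", "beta")

driving_states <- function() c("normal", "cognitive", "visual")

check_band_defs <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("band", "lo", "hi") %in% names(bands)))
  if (any(bands$lo <= 0) || any(bands$lo >= bands$hi))
    stop("band edges must satisfy 0 < lo < hi")
  invisible(bands)
}
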