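#' Construct an EEG recording object
#'
#' A recording couples a channels x samples signal matrix (in microvolts)
#' with its sampling rate and the flash-event table that generated / annotates
#' it. Event rows carry a 0-based `sample` index of the flash onset.
#'
#' @param signal Numeric matrix, channels x samples; rownames are channel
#'   labels.
#' @param rate Sampling rate in Hz.
#' @param events Tibble of flash events with at least `onset_s`, `trial`,
#'   `sequence`, `flash`, `letters`, `stim_class`, `is_target` and `sample`.
#' @param condition Paradigm label carried along for bookkeeping.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, rate, events, condition = NA_character_) {
  stopifnot(is.matrix(signal), !is.null(rownames(signal)), rate > 0)
  if (!is.null(events$sample)) {
    bad <- events$sample < 0 | events$sample >= ncol(signal)
    if (any(bad)) stop("event sample index outside signal")
  }
  structure(
    list(signal = signal, rate = rate, channels = rownames(signal),
         events = events, condition = condition),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(x$signal), ncol(x$signal), x$rate, ncol(x$signal) / x$rate,
    nrow(x$events)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eeg_recording <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channels, times = ncol(x$signal)),
    time_s = rep((seq_len(ncol(x$signal)) - 1) / x$rate, each = nrow(x$signal)),
    amplitude = as.vector(x$signal)
  )
}
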