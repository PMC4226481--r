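#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filters every channel with zero-phase (forward--backward)
#' Butterworth filtering. The band-pass is applied as a high-pass / low-pass
#' cascade of order-`order` filters: at EEG rates the lower edge (0.1 Hz) is
#' so close to DC that a directly-designed band-pass of this order is
#' numerically unstable in double precision, while the cascade is
#' well-conditioned and has the same passband.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz (defaults 0.1 and 30).
#' @param order Filter order of each cascade stage (default 5).
#' @return The filtered [eeg_recording()]; rate and events unchanged.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 30, order = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$rate / 2)) {
    stop("invalid band: need 0 < low < high < rate/2")
  }
  nyq <- rec$rate / 2
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  sig <- t(apply(rec$signal, 1, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  dimnames(sig) <- dimnames(rec$signal)
  rec$signal <- sig
  rec
}

#' Anti-aliased decimation to a lower rate
#'
#' Downsamples a recording by an integer factor: a zero-phase Chebyshev
#' type-I low-pass (default order 8, 0.05 dB passband ripple, cutoff at 0.8
#' times the new Nyquist frequency) is applied per channel before taking
#' every `factor`-th sample. Event marker sample indices are rescaled to the
#' new rate.
#'
#' @param rec An [eeg_recording()].
#' @param new_rate Target rate in Hz; must divide the current rate.
#' @param order Chebyshev filter order (default 8).
#' @param ripple Passband ripple in dB (default 0.05).
#' @return The decimated [eeg_recording()].
#' @export
resample_recording <- function(rec, new_rate = 100, order = 8,
                               ripple = 0.05) {
  stopifnot(inherits(rec, "eeg_recording"))
  q <- rec$rate / new_rate
  if (q != round(q) || q < 1) {
    stop("new rate must divide the current rate (non-integer ratio)")
  }
  q <- as.integer(q)
  if (q == 1L) return(rec)
  lp <- signal::cheby1(order, ripple, 0.8 / q, type = "low")
  keep <- seq(1L, ncol(rec$signal), by = q)
  sig <- t(apply(rec$signal, 1, function(x) {
    signal::filtfilt(lp, x)[keep]
  }))
  dimnames(sig) <- list(rownames(rec$signal), NULL)
  rec$signal <- sig
  rec$rate <- new_rate
  if (!is.null(rec$events$sample)) {
    rec$events$sample <- as.integer(round(rec$events$sample / q))
  }
  rec
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per flash event from the recording, over a half-open
#' window (default \[-200, 800) ms relative to flash onset; the t = 0 sample
#' belongs to the post-stimulus side). At 100 Hz this yields 100 samples per
#' epoch. Target-to-target-interval metadata is attached to target epochs.
#'
#' @param rec An [eeg_recording()] whose events carry `sample` indices.
#' @param window Epoch window in ms, length 2 (default `c(-200, 800)`).
#' @return An object of class `epoch_set`: a list with `data` (array epochs
#'   x channels x time, microvolts), `time_ms`, `channels`, and `metadata`
#'   (tibble: `epoch`, `trial`, `sequence`, `flash`, `stim_class`,
#'   `is_target`, `tti`).
#' @export
extract_epochs <- function(rec, window = c(-200, 800)) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2,
            window[1] < window[2])
  ev <- rec$events
  stopifnot(!is.null(ev$sample))
  rate <- rec$rate
  k0 <- round(window[1] / 1000 * rate)
  k1 <- round(window[2] / 1000 * rate) - 1L    # half-open right edge
  offs <- k0:k1
  time_ms <- offs / rate * 1000
  n <- ncol(rec$signal)
  first <- ev$sample + k0
  last <- ev$sample + k1
  bad <- which(first < 0L | last >= n)
  if (length(bad)) {
    stop(sprintf(
      "event %d (trial %d, sequence %d, flash %d) too close to recording edge",
      bad[1] - 1L, ev$trial[bad[1]], ev$sequence[bad[1]], ev$flash[bad[1]]))
  }
  # gather all epochs in one indexing pass: columns ordered (time, event)
  idx <- outer(offs, ev$sample, `+`) + 1L
  block <- rec$signal[, as.vector(idx), drop = FALSE]
  dat <- aperm(array(block, dim = c(nrow(rec$signal), length(offs),
                                    nrow(ev))),
               c(3, 1, 2))
  dimnames(dat) <- list(NULL, rownames(rec$signal), NULL)
  tti <- target_to_target_intervals(ev)
  meta <- tibble::tibble(
    epoch = seq_len(nrow(ev)),
    trial = ev$trial, sequence = ev$sequence, flash = ev$flash,
    stim_class = ev$stim_class, is_target = ev$is_target,
    tti = NA_integer_
  )
  meta$tti[tti$event + 1L] <- tti$tti
  structure(
    list(data = dat, time_ms = time_ms, channels = rownames(rec$signal),
         metadata = meta, condition = rec$condition),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples (%g..%g ms), %d targets\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    min(x$time_ms), max(x$time_ms), sum(x$metadata$is_target)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    time_ms = rep(x$time_ms, each = d[1] * d[2]),
    amplitude = as.vector(x$data),
    is_target = rep(x$metadata$is_target, times = d[2] * d[3])
  )
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean amplitude over the
#' pre-stimulus baseline window (default \[-200, 0) ms) from the whole
#' epoch.
#'
#' @param epochs An `epoch_set`.
#' @param window Baseline window in ms (default `c(-200, 0)`), half-open on
#'   the right; must lie within the epoch window.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$time_ms >= window[1] & epochs$time_ms < window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
  epochs$data <- sweep(epochs$data, c(1, 2), base, `-`)
  epochs
}

# subset an epoch_set by a logical/integer epoch index
subset_epochs <- function(epochs, idx) {
  if (is.logical(idx)) idx <- which(idx)
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$metadata <- epochs$metadata[idx, , drop = FALSE]
  epochs$metadata$epoch <- seq_len(nrow(epochs$metadata))
  epochs
}
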