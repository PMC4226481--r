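# shared fixture builders; everything is generated in code at test time

# epoch_set built directly from an array (epochs x channels x time)
make_epoch_set <- function(data, labels, time_ms = NULL,
                           channels = NULL, stim_class = "highlight",
                           tti = NULL) {
  d <- dim(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  if (is.null(time_ms)) time_ms <- seq(-200, 790, length.out = d[3])
  dimnames(data) <- list(NULL, channels, NULL)
  meta <- tibble::tibble(
    epoch = seq_len(d[1]),
    trial = 0L, sequence = 0L, flash = seq_len(d[1]) - 1L,
    stim_class = rep(stim_class, length.out = d[1]),
    is_target = as.logical(labels),
    tti = if (is.null(tti)) NA_integer_ else tti
  )
  structure(
    list(data = data, time_ms = time_ms, channels = channels,
         metadata = meta, condition = NA_character_),
    class = "epoch_set"
  )
}

# single-channel recording around a constant rate, no events unless given
make_recording <- function(x, rate, events = NULL, channel = "Cz") {
  if (is.null(events)) {
    events <- tibble::tibble(
      onset_s = numeric(), trial = integer(), sequence = integer(),
      flash = integer(), letters = list(), stim_class = character(),
      is_target = logical(), sample = integer())
  }
  sig <- matrix(x, nrow = 1, dimnames = list(channel, NULL))
  eeg_recording(sig, rate, events)
}

# independent loop implementation of the analytic shrinkage formulas
shrinkage_oracle <- function(x) {
  n <- nrow(x); p <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  s <- matrix(0, p, p)
  var_s <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      w <- xc[, i] * xc[, j]
      s[i, j] <- n / (n - 1) * mean(w)
      var_s[i, j] <- n / (n - 1)^3 * sum((w - mean(w))^2)
    }
  }
  nu <- mean(diag(s))
  tgt <- diag(nu, p)
  denom <- sum((s - tgt)^2)
  gamma <- if (denom <= 0) 1 else min(max(sum(var_s) / denom, 0), 1)
  list(sigma = (1 - gamma) * s + gamma * tgt, gamma = gamma, nu = nu, S = s)
}

# brute-force 36-way evidence enumeration for letter decoding
decode_oracle <- function(scores, events, n_sequences, matrix) {
  symbols <- matrix$symbol[order(matrix$row, matrix$col)]
  out <- lapply(sort(unique(events$trial)), function(tr) {
    ev_sum <- numeric(length(symbols))
    for (si in seq_along(symbols)) {
      for (i in seq_len(nrow(events))) {
        if (events$trial[i] == tr && events$sequence[i] < n_sequences &&
            symbols[si] %in% events$letters[[i]]) {
          ev_sum[si] <- ev_sum[si] + scores[i]
        }
      }
    }
    symbols[which.max(ev_sum)]
  })
  unlist(out)
}

# cheap sim config for end-to-end structure tests (fewer samples to filter)
fast_timing <- function(nseq = 3) {
  speller_timing(sequences_per_trial = nseq)
}
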