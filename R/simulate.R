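#' 1/f^alpha noise
#'
#' Generates a Gaussian noise vector whose power spectrum follows
#' 1/f^alpha, by spectrally shaping white noise in the frequency domain.
#' The output is standardized to unit standard deviation (DC removed).
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (0 = white noise).
#' @return Numeric vector of length `n`, sd 1.
#' @export
pink_noise <- function(n, alpha = 1) {
  stopifnot(n >= 2)
  as.numeric(pink_noise_matrix(n, 1, alpha))
}

# n x k matrix of independent unit-sd 1/f^alpha noise columns; one FFT pair
# for all columns via mvfft. Synthesized at the next 2-3-5-smooth length and
# truncated: R's mixed-radix FFT is O(n * p) for a large prime factor p, so
# arbitrary lengths can be catastrophically slow.
pink_noise_matrix <- function(n, k, alpha = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  white <- matrix(rnorm(m * k), nrow = m, ncol = k)
  out <- pink_shape(white, alpha)[seq_len(n), , drop = FALSE]
  out <- sweep(out, 2, colMeans(out))
  sweep(out, 2, apply(out, 2, sd), `/`)
}

pink_shape <- function(white, alpha) {
  n <- nrow(white)
  spec <- stats::mvfft(white)
  # frequency bin indices; DC gets weight 0, others f^(-alpha/2)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)          # two-sided spectrum symmetry
  w <- c(0, f[-1]^(-alpha / 2))
  Re(stats::mvfft(spec * w, inverse = TRUE)) / n
}

#' Simulate a multichannel EEG recording for a schedule
#'
#' Forward model: the signal is a superposition, over flash events and ERP
#' components, of `amplitude x polarity x half-sine kernel x Gaussian spatial
#' weight`, on top of 1/f^alpha background noise (independent per channel
#' plus a common-mode share). Target flashes evoke a P300 whose amplitude is
#' attenuated at short target-to-target intervals; face flashes evoke an
#' N170 (stronger for targets); target face flashes evoke an N400f that is
#' stronger for the user's own face.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param schedule A [build_schedule()] result.
#' @param config A [sim_config()].
#' @param amplitude_scale Scalar multiplier on all component amplitudes
#'   (used for session-to-session effects; default 1).
#' @param duration_s Recording length in seconds; defaults to the schedule's
#'   last onset plus 1.5 s. Must cover the schedule.
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(schedule, config = sim_config(),
                               amplitude_scale = 1, duration_s = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rate <- config$sample_rate
  events <- tibble::as_tibble(schedule)
  need_s <- max(events$onset_s) + 1.5
  if (is.null(duration_s)) duration_s <- need_s
  if (duration_s < need_s) {
    stop("schedule longer than requested duration")
  }
  n <- ceiling(duration_s * rate)
  mont <- config$montage
  nchan <- nrow(mont)

  # background: per-channel 1/f noise + common-mode term
  if (config$noise_sigma > 0) {
    noise <- pink_noise_matrix(n, nchan + 1L, config$noise_alpha)
    sig <- config$noise_sigma * t(noise[, seq_len(nchan), drop = FALSE])
    if (config$common_mode > 0) {
      common <- config$common_mode * config$noise_sigma * noise[, nchan + 1L]
      sig <- sweep(sig, 2, common, `+`)
    }
  } else {
    sig <- matrix(0, nrow = nchan, ncol = n)
  }
  dimnames(sig) <- list(mont$channel, NULL)

  # event-locked components
  events$sample <- round(events$onset_s * rate)   # 0-based
  tti <- target_to_target_intervals(schedule)
  events$.tti <- NA_integer_
  events$.tti[tti$event + 1L] <- tti$tti
  comps <- config$components
  amps <- config$amplitudes
  for (k in seq_len(nrow(comps))) {
    cmp <- comps[k, ]
    # kernel sampled on the recording grid relative to flash onset
    kt <- seq(floor(cmp$start_ms / 1000 * rate),
              ceiling(cmp$end_ms / 1000 * rate))
    kern <- erp_kernel(cmp$start_ms, cmp$end_ms, kt / rate * 1000)
    pk <- mont[mont$channel == cmp$peak_channel, ]
    d2 <- (mont$x - pk$x)^2 + (mont$y - pk$y)^2
    wch <- exp(-d2 / (2 * cmp$spread^2))
    a <- component_amplitude(cmp$component, events$stim_class,
                             events$is_target, amps)
    if (cmp$component == "P300") a <- a * tti_scale(events$.tti, config)
    a <- a * amplitude_scale * cmp$polarity
    hit <- which(a != 0)
    if (length(hit) == 0L) next
    # accumulate the component's time course once, then one spatial outer add
    series <- numeric(n)
    for (e in hit) {
      idx <- events$sample[e] + kt + 1L       # to 1-based columns
      ok <- idx >= 1L & idx <= n
      series[idx[ok]] <- series[idx[ok]] + a[e] * kern[ok]
    }
    touched <- which(series != 0)
    sig[, touched] <- sig[, touched] + wch %o% series[touched]
  }
  events$.tti <- NULL
  eeg_recording(sig, rate, events, condition = schedule_condition(schedule))
}

study_sentences <- list(train = "BRAIN_COMPUTER_INTERFACE",
                        test = "KOREAUNIVERSITY")

#' Generate a full simulated study for one subject
#'
#' Six runs: for each paradigm (RC, RASP, RASP-F) a training run
#' (copy-spelling "BRAIN_COMPUTER_INTERFACE", 24 trials) and a test run
#' ("KOREAUNIVERSITY", 15 trials) with independent noise and a shared
#' montage. Test-run component amplitudes are scaled by
#' `config$session_effect` to emulate recording the phases on different
#' days.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param config A [sim_config()].
#' @param timing A [speller_timing()].
#' @param conditions Paradigms to generate (default all three).
#' @return A nested list `study[[condition]][[phase]]` of [eeg_recording()]
#'   objects, `phase` in `c("train", "test")`.
#' @export
generate_study <- function(config = sim_config(), timing = speller_timing(),
                           conditions = speller_conditions) {
  conditions <- match.arg(conditions, speller_conditions, several.ok = TRUE)
  out <- lapply(conditions, function(cond) {
    lapply(stats::setNames(nm = c("train", "test")), function(phase) {
      sched <- build_schedule(cond, study_sentences[[phase]], timing)
      scale <- if (phase == "test") config$session_effect else 1
      simulate_recording(sched, config, amplitude_scale = scale)
    })
  })
  names(out) <- conditions
  out
}

#' Write / read a simulation configuration as JSON
#'
#' Serializes the full [sim_config()] (montage, rates, noise model,
#' amplitudes, TTI attenuation, session effect, component table) so a
#' generated dataset can carry its provenance.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns the restored `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(
    montage = tibble::as_tibble(obj$montage),
    sample_rate = obj$sample_rate,
    noise_sigma = obj$noise_sigma,
    noise_alpha = obj$noise_alpha,
    common_mode = obj$common_mode,
    amplitudes = as.list(obj$amplitudes),
    tti_attenuation = obj$tti_attenuation,
    session_effect = obj$session_effect,
    components = tibble::as_tibble(obj$components)
  )
}
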