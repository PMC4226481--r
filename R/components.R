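#' Default ERP component table
#'
#' The three stimulus-locked components the forward model generates, with the
#' canonical analysis windows and peak electrodes: P300 (positive, 280--370
#' ms, Cz), N170 (negative, 130--200 ms, PO7, face stimuli), and N400f
#' (negative, 400--550 ms, Cz, face-familiarity response). `spread` is the
#' standard deviation (head-radius units) of the Gaussian spatial profile
#' around the peak electrode.
#'
#' @return A tibble with columns `component`, `start_ms`, `end_ms`,
#'   `polarity`, `peak_channel`, `spread`.
#' @export
erp_components <- function() {
  tibble::tibble(
    component = c("P300", "N170", "N400f"),
    start_ms = c(280, 130, 400),
    end_ms = c(370, 200, 550),
    polarity = c(1, -1, -1),
    peak_channel = c("Cz", "PO7", "Cz"),
    spread = c(0.70, 0.45, 0.60)
  )
}

#' Half-sine ERP kernel
#'
#' Unit-peak waveform of a component over a time axis: a half-sine bump
#' supported exactly on `[start_ms, end_ms]`, peaking at 1 at the window
#' midpoint and 0 outside.
#'
#' @param start_ms,end_ms Component window in ms post-stimulus.
#' @param time_ms Numeric time axis in ms.
#' @return Numeric vector of the same length as `time_ms`.
#' @examples
#' erp_kernel(280, 370, seq(-200, 790, by = 10))
#' @export
erp_kernel <- function(start_ms, end_ms, time_ms) {
  stopifnot(end_ms > start_ms)
  inside <- time_ms >= start_ms & time_ms <= end_ms
  out <- numeric(length(time_ms))
  out[inside] <- sin(pi * (time_ms[inside] - start_ms) / (end_ms - start_ms))
  out
}

#' Simulation configuration
#'
#' All free parameters of the forward model. Amplitudes are in microvolts
#' and enter with the component's polarity; they encode the assumed class
#' structure: every target flash evokes a P300 (scaled by the
#' target-to-target-interval attenuation), every face-class flash evokes an
#' N170 (larger when the flash contains the target), and target face flashes
#' evoke an N400f that is larger for the user's own face than for other
#' faces.
#'
#' @param montage Electrode table, see [electrode_positions()].
#' @param sample_rate Recording rate in Hz (default 500).
#' @param noise_sigma Per-channel background noise standard deviation in
#'   microvolts (default 6).
#' @param noise_alpha Spectral exponent of the 1/f^alpha background
#'   (default 1).
#' @param common_mode Fraction of `noise_sigma` added as a common-mode noise
#'   term shared across channels (default 0.3), giving spatially correlated
#'   background activity.
#' @param amplitudes Named list: `p300_target`, `n170_face`,
#'   `n170_target_bonus`, `n400f_self_target`, `n400f_nonself_target`.
#' @param tti_attenuation Multiplicative P300 scale for target-to-target
#'   intervals 0, 1, 2 and >= 3; nondecreasing, 1 at >= 3. A trial's first
#'   target flash (no within-trial TTI) gets the full scale.
#' @param session_effect Scalar applied to all amplitudes of test-phase runs
#'   in [generate_study()] (default 0.95), emulating session-to-session
#'   transfer loss.
#' @param components Component table, see [erp_components()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(montage = electrode_positions(),
                       sample_rate = 500,
                       noise_sigma = 6,
                       noise_alpha = 1,
                       common_mode = 0.3,
                       amplitudes = list(
                         p300_target = 5,
                         n170_face = 3,
                         n170_target_bonus = 1,
                         n400f_self_target = 4,
                         n400f_nonself_target = 2
                       ),
                       tti_attenuation = c(`0` = 0.4, `1` = 0.6, `2` = 0.8,
                                           `3+` = 1.0),
                       session_effect = 0.95,
                       components = erp_components()) {
  stopifnot(nrow(montage) == 29L, sample_rate > 0, noise_sigma >= 0,
            length(tti_attenuation) == 4L,
            all(tti_attenuation > 0), all(tti_attenuation <= 1),
            !is.unsorted(tti_attenuation),
            tti_attenuation[[4]] == 1)
  stopifnot(all(vapply(amplitudes, function(a) a >= 0, TRUE)))
  structure(
    list(montage = montage, sample_rate = sample_rate,
         noise_sigma = noise_sigma, noise_alpha = noise_alpha,
         common_mode = common_mode, amplitudes = amplitudes,
         tti_attenuation = unname(tti_attenuation),
         session_effect = session_effect, components = components),
    class = "sim_config"
  )
}

tti_scale <- function(tti, config) {
  att <- config$tti_attenuation
  idx <- pmin(ifelse(is.na(tti), 3L, tti), 3L) + 1L
  att[idx]
}

# amplitude of one component for one flash event (without TTI scaling)
component_amplitude <- function(component, stim_class, is_target, amplitudes) {
  face <- stim_class %in% c("self_face", "non_self_face")
  switch(component,
    P300 = ifelse(is_target, amplitudes$p300_target, 0),
    N170 = ifelse(face,
                  amplitudes$n170_face +
                    is_target * amplitudes$n170_target_bonus, 0),
    N400f = ifelse(is_target & stim_class == "self_face",
                   amplitudes$n400f_self_target,
                   ifelse(is_target & stim_class == "non_self_face",
                          amplitudes$n400f_nonself_target, 0)),
    stop("unknown component: ", component)
  )
}
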