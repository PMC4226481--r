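#' The 29-channel 10--20 montage
#'
#' The recording montage: 29 Ag/AgCl scalp electrodes of the international
#' 10--20 system (F3, F4, Fz, FC1, FC2, FC5, FC6, C3, C4, Cz, T7, T8, CP1,
#' CP2, CP5, CP6, P3, P4, Pz, P7, P8, PO3, PO4, POz, PO7, PO8, O1, Oz, O2)
#' with schematic top-view 2-D coordinates in head-radius units (x: left
#' negative / right positive; y: posterior negative / anterior positive).
#' The coordinates are used only for the spatial spread of simulated
#' components and for plotting.
#'
#' @return A tibble with columns `channel`, `x`, `y` (29 rows).
#' @export
electrode_positions <- function() {
  path <- system.file("extdata", "montage_1020_29.tsv", package = "erpspell",
                      mustWork = TRUE)
  tibble::as_tibble(read.delim(path, colClasses = c(channel = "character")))
}
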