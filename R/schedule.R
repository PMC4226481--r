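#' Speller timing parameters
#'
#' Flash/ISI timing of the speller. Each flash lasts `flash_duration` seconds
#' and is followed by an inter-stimulus interval of `isi` seconds, so the
#' stimulus-onset asynchrony is `flash_duration + isi` (default 0.185 s).
#' Every trial (one letter to spell) starts with a countdown and consists of
#' `sequences_per_trial` sequences of 12 flashes run back to back, without a
#' prolonged inter-sequence interval.
#'
#' @param flash_duration Flash duration in seconds (default 0.135).
#' @param isi Inter-stimulus interval in seconds (default 0.050).
#' @param countdown Pre-trial countdown in seconds (default 2).
#' @param sequences_per_trial Number of 12-flash sequences per trial
#'   (default 10).
#' @return A list of class `speller_timing`.
#' @export
speller_timing <- function(flash_duration = 0.135, isi = 0.050,
                           countdown = 2, sequences_per_trial = 10L) {
  stopifnot(flash_duration > 0, isi > 0, countdown > 0,
            sequences_per_trial >= 1)
  structure(
    list(flash_duration = flash_duration, isi = isi, countdown = countdown,
         sequences_per_trial = as.integer(sequences_per_trial)),
    class = "speller_timing"
  )
}

soa <- function(timing) timing$flash_duration + timing$isi

trial_duration <- function(timing) {
  timing$countdown + timing$sequences_per_trial * 12 * soa(timing)
}

#' Selection duration for a given number of sequences
#'
#' Time spent on one letter selection when the first `n_sequences` sequences
#' are used: the countdown plus `n_sequences` x 12 flashes at one
#' stimulus-onset asynchrony each.
#'
#' @param timing A [speller_timing()] object.
#' @param n_sequences Number of sequences used for the selection.
#' @return Duration in seconds (vectorized over `n_sequences`).
#' @export
selection_duration <- function(timing, n_sequences) {
  stopifnot(all(n_sequences >= 1))
  timing$countdown + n_sequences * 12 * soa(timing)
}

speller_conditions <- c("RC", "RASP", "RASP_F")

#' Draw one 12-flash stimulus sequence
#'
#' Generates the 12 flash sets of one sequence for a given paradigm. For
#' `RC`, the sets are the 6 physical rows and 6 physical columns of the
#' matrix in uniformly random order, all of stimulus class `highlight`. For
#' `RASP` and `RASP_F`, a fresh uniformly random virtual 6 x 6 arrangement of
#' the 36 symbols is drawn and its 6 virtual rows and 6 virtual columns are
#' flashed in uniformly random interleaved order; under `RASP_F` virtual rows
#' carry the user's own face (`self_face`) and virtual columns other faces
#' (`non_self_face`). In every case each symbol is flashed exactly twice.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param condition One of `"RC"`, `"RASP"`, `"RASP_F"`.
#' @param matrix Letter matrix, see [letter_matrix()].
#' @return A tibble with 12 rows and columns `flash` (0-based position in the
#'   sequence), `letters` (list column, 6 symbols each), `stim_class`.
#' @export
schedule_sequence <- function(condition, matrix = letter_matrix()) {
  condition <- match.arg(condition, speller_conditions)
  assert_letter_matrix(matrix)
  if (condition == "RC") {
    rows <- lapply(0:5, function(r) matrix$symbol[matrix$row == r])
    cols <- lapply(0:5, function(c) matrix$symbol[matrix$col == c])
    sets <- c(rows, cols)
    classes <- rep("highlight", 12)
  } else {
    virt <- base::matrix(sample(matrix$symbol), nrow = 6, ncol = 6)
    rows <- lapply(1:6, function(r) virt[r, ])
    cols <- lapply(1:6, function(c) virt[, c])
    sets <- c(rows, cols)
    classes <- if (condition == "RASP_F") {
      c(rep("self_face", 6), rep("non_self_face", 6))
    } else {
      rep("highlight", 12)
    }
  }
  ord <- sample(12L)
  tibble::tibble(
    flash = 0:11,
    letters = sets[ord],
    stim_class = classes[ord]
  )
}

#' Build a full stimulus schedule
#'
#' Lays out the flash events for copy-spelling `targets` under a paradigm:
#' per target letter, a countdown followed by `sequences_per_trial` sequences
#' of 12 flashes with onsets spaced by one stimulus-onset asynchrony.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams schedule_sequence
#' @param targets The sentence to spell: a character vector of symbols, or a
#'   single string that is split into characters.
#' @param timing A [speller_timing()] object.
#' @return A tibble of class `speller_schedule` with one row per flash event:
#'   `onset_s`, `trial` (0-based; one trial = one letter), `sequence`
#'   (0-based within trial), `flash` (0-based within sequence), `letters`
#'   (list column of 6 symbols), `stim_class`, `is_target`, `target` (the
#'   trial's target symbol). Attributes: `condition`, `timing`, `matrix`,
#'   `targets`.
#' @export
build_schedule <- function(condition, targets, timing = speller_timing(),
                           matrix = letter_matrix()) {
  condition <- match.arg(condition, speller_conditions)
  assert_letter_matrix(matrix)
  if (length(targets) == 1L && nchar(targets) > 1L) {
    targets <- strsplit(targets, "")[[1]]
  }
  if (!all(targets %in% matrix$symbol)) {
    stop("target symbol(s) not in matrix: ",
         paste(unique(setdiff(targets, matrix$symbol)), collapse = ", "))
  }
  step <- soa(timing)
  nseq <- timing$sequences_per_trial
  trials <- purrr::map(seq_along(targets), function(i) {
    tgt <- targets[[i]]
    seqs <- purrr::map(seq_len(nseq), function(s) {
      sq <- schedule_sequence(condition, matrix)
      sq$sequence <- s - 1L
      sq
    })
    tr <- dplyr::bind_rows(seqs)
    tr$trial <- i - 1L
    tr$target <- tgt
    k <- seq_len(nrow(tr)) - 1L
    tr$onset_s <- (i - 1L) * trial_duration(timing) + timing$countdown +
      k * step
    tr$is_target <- purrr::map_lgl(tr$letters, function(ls) tgt %in% ls)
    tr
  })
  events <- dplyr::bind_rows(trials)
  events <- events[, c("onset_s", "trial", "sequence", "flash", "letters",
                       "stim_class", "is_target", "target")]
  structure(
    events,
    class = c("speller_schedule", class(tibble::tibble()))  ,
    condition = condition,
    timing = timing,
    matrix = matrix,
    targets = targets
  )
}

schedule_condition <- function(schedule) attr(schedule, "condition")
schedule_timing <- function(schedule) attr(schedule, "timing")
schedule_matrix <- function(schedule) attr(schedule, "matrix")

#' Target-to-target intervals
#'
#' For every target flash, counts the non-target flashes since the previous
#' target flash within the same trial. The first target flash of a trial has
#' no predecessor and gets `NA`. A TTI of 0 is a "double-flashed target":
#' the target letter contained in two consecutive flashes.
#'
#' @param schedule A [build_schedule()] result (or any tibble with columns
#'   `trial`, `is_target` in event order).
#' @return A tibble with one row per target flash: `trial`, `sequence`,
#'   `flash`, `event` (0-based index into the schedule's events) and `tti`
#'   (integer, `NA` for each trial's first target flash).
#' @export
target_to_target_intervals <- function(schedule) {
  ev <- tibble::as_tibble(schedule)
  ev$event <- seq_len(nrow(ev)) - 1L
  ev |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(.pos = dplyr::row_number()) |>
    dplyr::filter(.data$is_target) |>
    dplyr::mutate(tti = .data$.pos - dplyr::lag(.data$.pos) - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("trial", "sequence", "flash", "event", "tti")
}

#' Write / read a flash-event log
#'
#' The event log is a TSV with columns `onset_s`, `trial`, `sequence`,
#' `flash`, `letters` (the 6 symbols concatenated), `stim_class`,
#' `is_target`. `read_event_log()` restores `letters` as a list column.
#'
#' @param schedule A schedule tibble (see [build_schedule()]).
#' @param path File path.
#' @return `write_event_log()` returns `path` invisibly; `read_event_log()`
#'   returns a tibble of flash events.
#' @export
write_event_log <- function(schedule, path) {
  out <- tibble::as_tibble(schedule)[
    , c("onset_s", "trial", "sequence", "flash", "letters", "stim_class",
        "is_target")]
  out$letters <- vapply(out$letters, paste0, "", collapse = "")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  raw <- read.delim(path, colClasses = c(letters = "character"))
  out <- tibble::as_tibble(raw)
  out$letters <- strsplit(out$letters, "")
  out$is_target <- as.logical(out$is_target)
  out
}
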