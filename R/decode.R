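#' Decode spelled letters by evidence accumulation
#'
#' For each trial, the evidence for a symbol is the sum of classifier scores
#' over all flashes, within the first `n_sequences` sequences, whose letter
#' set contains that symbol; the decoded symbol is the argmax. Ties break to
#' the symbol at the smallest (row, col) position in row-major order. The
#' same rule serves RC, RASP and RASP-F schedules.
#'
#' @param scores Numeric vector, one classifier score per flash event, in
#'   schedule order.
#' @param schedule A [build_schedule()] result (or event tibble with
#'   `trial`, `sequence`, `letters`, `target`).
#' @param n_sequences Number of sequences (from the start of each trial) to
#'   accumulate.
#' @param matrix Letter matrix defining the symbol set and the tie-break
#'   order; defaults to the schedule's matrix.
#' @return A tibble with one row per trial: `trial`, `target`, `decoded`,
#'   `correct`.
#' @export
decode_characters <- function(scores, schedule, n_sequences = NULL,
                              matrix = NULL) {
  ev <- tibble::as_tibble(schedule)
  if (length(scores) != nrow(ev)) {
    stop(sprintf("got %d scores for %d flash events",
                 length(scores), nrow(ev)))
  }
  if (is.null(matrix)) matrix <- schedule_matrix(schedule)
  if (is.null(matrix)) matrix <- letter_matrix()
  # row-major tie-break: order symbols by (row, col)
  symbols <- matrix$symbol[order(matrix$row, matrix$col)]
  if (is.null(n_sequences)) n_sequences <- max(ev$sequence) + 1L
  stopifnot(n_sequences >= 1)
  ev$score <- scores
  use <- ev[ev$sequence < n_sequences, ]
  use |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      target = .data$target[1],
      decoded = {
        ltr <- unlist(.data$letters)
        sc <- rep(.data$score, each = 6L)
        ev_sum <- vapply(split(sc, factor(ltr, levels = symbols)), sum, 0)
        symbols[which.max(ev_sum)]   # which.max: first max wins the tie
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(correct = .data$decoded == .data$target)
}

#' Accuracy as a function of the number of sequences
#'
#' Decodes each trial using the first `n` sequences, for `n` from 1 to the
#' number available, and reports the fraction of correctly decoded trials.
#'
#' @inheritParams decode_characters
#' @param n_max Largest number of sequences to evaluate (default: all).
#' @return A tibble with columns `n_sequences`, `n_trials`, `accuracy`.
#' @export
accuracy_vs_sequences <- function(scores, schedule, n_max = NULL,
                                  matrix = NULL) {
  ev <- tibble::as_tibble(schedule)
  if (is.null(n_max)) n_max <- max(ev$sequence) + 1L
  purrr::map_dfr(seq_len(n_max), function(n) {
    dec <- decode_characters(scores, schedule, n, matrix = matrix)
    tibble::tibble(n_sequences = n, n_trials = nrow(dec),
                   accuracy = mean(dec$correct))
  })
}

#' Bits per selection of an N-choice speller
#'
#' The symmetric-channel information per selection:
#' \deqn{B = \log_2 N + P \log_2 P + (1-P) \log_2 \frac{1-P}{N-1},}
#' with \eqn{0 \log_2 0 \equiv 0}, clamped at 0 for accuracies at or below
#' chance (\eqn{P \le 1/N}).
#'
#' @param p Selection accuracy in `[0, 1]` (vectorized).
#' @param n_choices Number of equiprobable choices N (default 36).
#' @return Bits per selection.
#' @export
bits_per_selection <- function(p, n_choices = 36) {
  if (n_choices < 2) stop("need at least 2 choices")
  if (any(p < 0 | p > 1)) stop("accuracy must be in [0, 1]")
  xlx <- function(q) ifelse(q > 0, q * log2(q), 0)
  b <- log2(n_choices) + xlx(p) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_choices - 1)), 0)
  # B(1/N) = 0 analytically; clamp chance-or-worse accuracies to exactly 0
  ifelse(p <= 1 / n_choices, 0, pmax(b, 0))
}

#' Information transfer rate
#'
#' Wolpaw information transfer rate in bits per minute: bits per selection
#' (see [bits_per_selection()]) times selections per minute
#' (`60 / selection_duration_s`).
#'
#' @inheritParams bits_per_selection
#' @param selection_duration_s Duration of one selection in seconds (see
#'   [selection_duration()]).
#' @return Bits per minute (vectorized over `p` and
#'   `selection_duration_s`).
#' @export
information_transfer_rate <- function(p, n_choices = 36,
                                      selection_duration_s) {
  stopifnot(all(selection_duration_s > 0))
  bits_per_selection(p, n_choices) * 60 / selection_duration_s
}

#' Chronological k-fold cross-validation of per-flash classification
#'
#' Splits epochs, in recording order, into `k` temporally contiguous folds
#' of near-equal size (earlier folds take the remainders). Each fold is
#' tested once with an RLDA classifier trained on the other folds; per-flash
#' binary accuracy is evaluated at the score > 0 boundary. A stratum
#' restricts the epochs to one stimulus class before splitting (used to
#' compare self-face against non-self-face flashes).
#'
#' @param features A `speller_features` tibble in recording order.
#' @param k Number of folds (default 8).
#' @param stratum `"all"`, `"self_face"` or `"non_self_face"`.
#' @return A list of class `speller_cv`: `folds` (tibble `fold`, `n`,
#'   `accuracy`), `mean_accuracy`, `stratum`, `k`.
#' @export
chronological_cross_validation <- function(features, k = 8,
                                           stratum = c("all", "self_face",
                                                       "non_self_face")) {
  stratum <- match.arg(stratum)
  if (stratum != "all") {
    features <- features[features$.stim_class == stratum, , drop = FALSE]
  }
  n <- nrow(features)
  labels <- features$.is_target
  if (sum(labels) < k || sum(!labels) < k) {
    stop("need at least k epochs per class")
  }
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1) + 1L)
  x <- feature_matrix(features)
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    test_ix <- starts[f]:stops[f]
    train_lab <- labels[-test_ix]
    if (length(unique(train_lab)) < 2L) {
      stop("training folds contain a single class")
    }
    model <- train_rlda(x[-test_ix, , drop = FALSE], train_lab)
    sc <- rlda_score(model, x[test_ix, , drop = FALSE])
    tibble::tibble(fold = f, n = length(test_ix),
                   accuracy = mean((sc > 0) == labels[test_ix]))
  })
  structure(
    list(folds = folds, mean_accuracy = mean(folds$accuracy),
         stratum = stratum, k = k),
    class = "speller_cv"
  )
}

#' @export
print.speller_cv <- function(x, ...) {
  cat(sprintf("<speller_cv> %d-fold chronological, stratum = %s, mean accuracy = %.3f\n",
              x$k, x$stratum, x$mean_accuracy))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.speller_cv <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.speller_cv <- function(x, ...) {
  tibble::tibble(k = x$k, stratum = x$stratum,
                 mean_accuracy = x$mean_accuracy)
}
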