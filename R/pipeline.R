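#' Run the full offline speller pipeline for one simulated subject
#'
#' End-to-end analysis mirroring the offline study design, per paradigm:
#' simulate a training run (copy-spelling the training sentence) and a test
#' run (on a different simulated "day": amplitudes scaled by the session
#' effect); decimate to 100 Hz, band-pass 0.1--30 Hz, epoch \[-200, 800) ms
#' and baseline-correct; select 8 discriminative intervals on the training
#' run via the signed-r2 heuristic and extract 232-dimensional interval-mean
#' features; train shrinkage-regularized LDA on the training run; score the
#' test run, decode letters by evidence accumulation and compute the
#' accuracy-vs-sequences and ITR curves; run 8-fold chronological
#' cross-validation of per-flash accuracy on the test run (for RASP-F also
#' per stimulus-class stratum).
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param config A [sim_config()].
#' @param timing A [speller_timing()].
#' @param conditions Paradigms to run (default all three).
#' @param analysis_rate Analysis sampling rate in Hz (default 100).
#' @param band Band-pass edges in Hz (default `c(0.1, 30)`).
#' @param n_intervals Number of discriminative intervals (default 8).
#' @param cv_folds Folds for chronological cross-validation (default 8).
#' @param train_sentence,test_sentence Sentences to copy-spell.
#' @return A list of class `speller_study` with tibbles `accuracy`
#'   (condition, n_sequences, n_trials, accuracy, duration_s, itr),
#'   `cv` (condition, stratum, fold accuracies summarized), `decisions`
#'   (per condition and n_sequences: trial, target, decoded, correct),
#'   `target_flashes` (condition, tti, score, correct), and per-condition
#'   `models` / `intervals`.
#' @export
run_speller_study <- function(config = sim_config(),
                              timing = speller_timing(),
                              conditions = speller_conditions,
                              analysis_rate = 100,
                              band = c(0.1, 30),
                              n_intervals = 8,
                              cv_folds = 8,
                              train_sentence = study_sentences$train,
                              test_sentence = study_sentences$test) {
  conditions <- match.arg(conditions, speller_conditions, several.ok = TRUE)
  res <- lapply(conditions, function(cond) {
    run_condition(cond, config, timing, analysis_rate, band, n_intervals,
                  cv_folds, train_sentence, test_sentence)
  })
  names(res) <- conditions
  structure(
    list(
      accuracy = purrr::map_dfr(res, "accuracy"),
      cv = purrr::map_dfr(res, "cv"),
      decisions = purrr::map_dfr(res, "decisions"),
      target_flashes = purrr::map_dfr(res, "target_flashes"),
      models = purrr::map(res, "model"),
      intervals = purrr::map(res, "intervals"),
      timing = timing
    ),
    class = "speller_study"
  )
}

# one paradigm: simulate both phases, train on train, evaluate on test
run_condition <- function(cond, config, timing, analysis_rate, band,
                          n_intervals, cv_folds, train_sentence,
                          test_sentence) {
  prep <- function(sentence, amplitude_scale) {
    sched <- build_schedule(cond, sentence, timing)
    rec <- simulate_recording(sched, config,
                              amplitude_scale = amplitude_scale)
    rec <- resample_recording(rec, analysis_rate)
    rec <- bandpass_filter(rec, band[1], band[2])
    ep <- baseline_correct(extract_epochs(rec))
    list(schedule = sched, epochs = ep)
  }
  train <- prep(train_sentence, 1)
  test <- prep(test_sentence, config$session_effect)

  map <- signed_r_squared_map(train$epochs)
  intervals <- select_discriminative_intervals(map, n = n_intervals)
  ft_train <- interval_mean_features(train$epochs, intervals)
  model <- train_rlda(ft_train, intervals = intervals)
  ft_test <- interval_mean_features(test$epochs, intervals)
  scores <- rlda_score(model, ft_test)

  acc <- accuracy_vs_sequences(scores, test$schedule)
  acc$duration_s <- selection_duration(timing, acc$n_sequences)
  acc$itr <- information_transfer_rate(acc$accuracy, 36, acc$duration_s)
  acc <- dplyr::mutate(acc, condition = cond, .before = 1)

  decisions <- purrr::map_dfr(seq_len(timing$sequences_per_trial),
    function(n) {
      dec <- decode_characters(scores, test$schedule, n)
      dplyr::mutate(dec, condition = cond, n_sequences = n, .before = 1)
    })

  strata <- if (cond == "RASP_F") c("all", "self_face", "non_self_face")
            else "all"
  cv <- purrr::map_dfr(strata, function(st) {
    r <- chronological_cross_validation(ft_test, k = cv_folds, stratum = st)
    tibble::tibble(condition = cond, stratum = st,
                   mean_accuracy = r$mean_accuracy,
                   fold_accuracies = list(r$folds$accuracy))
  })

  tf <- ft_test[ft_test$.is_target, c(".tti", ".trial")]
  target_flashes <- tibble::tibble(
    condition = cond, trial = tf$.trial, tti = tf$.tti,
    score = scores[ft_test$.is_target],
    correct = scores[ft_test$.is_target] > 0
  )

  list(accuracy = acc, cv = cv, decisions = decisions,
       target_flashes = target_flashes, model = model,
       intervals = intervals)
}

#' @export
print.speller_study <- function(x, ...) {
  cat("<speller_study>\n")
  s1 <- dplyr::filter(x$accuracy, .data$n_sequences == 1)
  for (i in seq_len(nrow(s1))) {
    cat(sprintf("  %-7s P(1) = %.3f, ITR(1) = %.1f bits/min\n",
                s1$condition[i], s1$accuracy[i], s1$itr[i]))
  }
  invisible(x)
}

#' Simulate and analyze a cohort of subjects
#'
#' Repeats [run_speller_study()] for `n_subjects` independent simulated
#' subjects (independent noise and schedules, shared configuration) and
#' row-binds the result tibbles with a `subject` column.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams run_speller_study
#' @param n_subjects Number of simulated subjects.
#' @param ... Passed on to [run_speller_study()].
#' @return A list of class `speller_cohort` with tibbles `accuracy`, `cv`,
#'   `decisions`, `target_flashes` (each with a leading `subject` column).
#' @export
simulate_subjects <- function(n_subjects, config = sim_config(),
                              timing = speller_timing(), ...) {
  runs <- purrr::map(seq_len(n_subjects), function(s) {
    st <- run_speller_study(config = config, timing = timing, ...)
    list(
      accuracy = dplyr::mutate(st$accuracy, subject = s, .before = 1),
      cv = dplyr::mutate(st$cv, subject = s, .before = 1),
      decisions = dplyr::mutate(st$decisions, subject = s, .before = 1),
      target_flashes = dplyr::mutate(st$target_flashes, subject = s,
                                     .before = 1)
    )
  })
  structure(
    list(
      accuracy = purrr::map_dfr(runs, "accuracy"),
      cv = purrr::map_dfr(runs, "cv"),
      decisions = purrr::map_dfr(runs, "decisions"),
      target_flashes = purrr::map_dfr(runs, "target_flashes"),
      timing = timing
    ),
    class = "speller_cohort"
  )
}

#' @export
print.speller_cohort <- function(x, ...) {
  ns <- length(unique(x$accuracy$subject))
  cat(sprintf("<speller_cohort> %d subjects\n", ns))
  s1 <- x$accuracy |>
    dplyr::filter(.data$n_sequences == 1) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     mean_itr = mean(.data$itr), .groups = "drop")
  for (i in seq_len(nrow(s1))) {
    cat(sprintf("  %-7s mean P(1) = %.3f, mean ITR(1) = %.1f bits/min\n",
                s1$condition[i], s1$mean_accuracy[i], s1$mean_itr[i]))
  }
  invisible(x)
}
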