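test_that("component windows match the canonical table", {
  w <- component_windows()
  expect_equal(w$channel[w$component == "N170"], "PO7")
  expect_equal(unlist(w[w$component == "P300", c("start_ms", "end_ms")],
                      use.names = FALSE), c(280, 370))
  expect_equal(unlist(w[w$component == "N400f", c("start_ms", "end_ms")],
                      use.names = FALSE), c(400, 550))
})

test_that("component window means average the named channel and window", {
  tms <- seq(-200, 790, by = 10)
  d <- array(3, dim = c(4, 2, length(tms)))
  ep <- make_epoch_set(d, c(TRUE, TRUE, FALSE, FALSE), tms,
                       channels = c("Cz", "PO7"))
  out <- component_window_mean(ep, "P300")
  expect_equal(out$amplitude, rep(3, 4))
  expect_error(component_window_mean(
    make_epoch_set(d, c(TRUE, TRUE, FALSE, FALSE), tms), "P300"),
    "not in montage")
})

test_that("a noiseless self-face target epoch hits the closed-form N400f mean", {
  cfg <- sim_config(noise_sigma = 0)
  ev <- tibble::tibble(
    onset_s = 1, trial = 0L, sequence = 0L, flash = 0L,
    letters = list(c("A", "B", "C", "D", "E", "F")),
    stim_class = "self_face", is_target = TRUE, target = "A")
  rec <- simulate_recording(ev, cfg, duration_s = 3)
  ep <- extract_epochs(rec)
  out <- component_window_mean(ep, "N400f")
  win <- ep$time_ms >= 400 & ep$time_ms <= 550
  expected <- -cfg$amplitudes$n400f_self_target *
    mean(erp_kernel(400, 550, ep$time_ms[win]))
  expect_equal(out$amplitude, expected, tolerance = 1e-10)
})

test_that("the exact sign test matches binomial tail arithmetic", {
  a <- 1:15; b <- a - 1                       # 15 of 15 concordant pairs
  st <- paired_sign_test(a, b)
  expect_equal(st$p_value, 2 * 0.5^15)        # = 6.1035e-5
  expect_equal(st$statistic, 15L)
  # 8 of 15 positive is nowhere near significant
  b2 <- c(rep(0, 8), rep(2, 7)); a2 <- rep(1, 15)
  expect_gt(paired_sign_test(a2, b2)$p_value, 0.5)
  # symmetry under swapping the members of each pair
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(paired_sign_test(x, y)$p_value,
               paired_sign_test(y, x)$p_value)
  expect_error(paired_sign_test(x, x), "tied")
})

test_that("Bonferroni adjustment scales and caps p values", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  p <- c(0.001, 0.04, 0.2)
  expect_equal(order(bonferroni_adjust(p, 5)), order(p))
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "family size")
})

test_that("pooled two-sample t test matches the textbook value", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.6742346141747673, tolerance = 1e-10)
  expect_equal(tt$p_value, 0.021311641128756713, tolerance = 1e-10)
  expect_equal(tt$df, 4)
  same <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  neg <- two_sample_t(-c(1, 2, 3), -c(4, 5, 6))
  expect_equal(neg$statistic, -tt$statistic)
  expect_equal(neg$p_value, tt$p_value)
})

test_that("repeated-measures ANOVA has the study's df structure", {
  set.seed(4)
  d <- expand.grid(subject = 1:15, speller = c("RC", "RASP", "RASP_F"),
                   sequences = 1:10)
  d$value <- rnorm(nrow(d))
  tab <- repeated_measures_anova_2way(d, "value", "subject", "speller",
                                      "sequences")
  expect_equal(tab$df1, c(2, 9, 18))
  expect_equal(tab$df2, c(28, 126, 252))
})

test_that("subject-constant data yields zero F throughout", {
  d <- expand.grid(subject = 1:6, speller = c("a", "b"), sequences = 1:3)
  d$value <- as.numeric(d$subject)            # varies only between subjects
  tab <- repeated_measures_anova_2way(d, "value", "subject", "speller",
                                      "sequences")
  expect_equal(tab$statistic, c(0, 0, 0))
})

test_that("ANOVA F values agree with aov's within-subject decomposition", {
  set.seed(5)
  d <- expand.grid(subject = factor(1:6), A = factor(c("x", "y", "z")),
                   B = factor(1:4))
  d$value <- rnorm(nrow(d))
  tab <- repeated_measures_anova_2way(d, "value", "subject", "A", "B")
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = d)
  s <- summary(fit)
  f_aov <- c(s[["Error: subject:A"]][[1]]["A", "F value"],
             s[["Error: subject:B"]][[1]]["B", "F value"],
             s[["Error: subject:A:B"]][[1]]["A:B", "F value"])
  expect_equal(tab$statistic, unname(f_aov), tolerance = 1e-8)
  # adding a per-subject constant is absorbed by the subject stratum
  d2 <- d
  d2$value <- d$value + 100 * as.numeric(d$subject)
  tab2 <- repeated_measures_anova_2way(d2, "value", "subject", "A", "B")
  expect_equal(tab2$statistic, tab$statistic, tolerance = 1e-6)
  expect_error(repeated_measures_anova_2way(d[-1, ], "value", "subject",
                                            "A", "B"),
               "complete and balanced")
})

test_that("TTI profiles bin target flashes and flag empty bins", {
  d <- tibble::tibble(tti = c(0, 0, 1, 3, 7, 9, NA),
                      correct = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  prof <- tti_accuracy_profile(d)
  expect_equal(levels(prof$tti_bin), c("0", "1", "2", "3", "4", ">=5"))
  expect_equal(prof$n, c(2L, 1L, 0L, 1L, 0L, 2L))
  expect_equal(prof$accuracy, c(0.5, 1, NA, 1, NA, 0.5))
  all_ok <- tti_accuracy_profile(tibble::tibble(tti = c(0, 2, 8),
                                                correct = TRUE))
  expect_true(all(all_ok$accuracy[!is.na(all_ok$accuracy)] == 1))
})

test_that("error topography counts offsets around the centered target", {
  m <- letter_matrix()
  # all correct: everything lands in the center cell
  e1 <- adjacency_error_map(c("A", "Z", "5"), c("A", "Z", "5"), m)
  expect_equal(sum(e1), 3)
  expect_equal(e1["0", "0"], 3L)
  # one error one column to the right of the target
  e2 <- adjacency_error_map(c("B"), c("A"), m)
  expect_equal(e2["0", "1"], 1L)
  expect_equal(sum(e2), 1)
  # conservation on random decode results
  set.seed(6)
  dec <- sample(m$symbol, 50, replace = TRUE)
  tru <- sample(m$symbol, 50, replace = TRUE)
  expect_equal(sum(adjacency_error_map(dec, tru, m)), 50)
})
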