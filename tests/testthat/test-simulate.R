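test_that("erp kernel is a unit half-sine on its window", {
  tms <- seq(-200, 790, by = 10)
  k <- erp_kernel(280, 370, tms)
  expect_true(all(k[tms < 280 | tms > 370] == 0))
  expect_gt(min(k[tms > 280 & tms < 370]), 0)
  expect_equal(erp_kernel(280, 370, 325), 1)       # midpoint peak
  expect_equal(erp_kernel(280, 370, 279), 0)       # compact support
})

test_that("noiseless single target flash reproduces amplitude x kernel x spatial weight", {
  cfg <- sim_config(noise_sigma = 0,
                    amplitudes = list(p300_target = 5, n170_face = 0,
                                      n170_target_bonus = 0,
                                      n400f_self_target = 0,
                                      n400f_nonself_target = 0),
                    tti_attenuation = c(1, 1, 1, 1))
  # one isolated target flash, so no neighboring response overlaps the epoch
  sch <- tibble::tibble(
    onset_s = 1, trial = 0L, sequence = 0L, flash = 0L,
    letters = list(c("A", "B", "C", "D", "E", "F")),
    stim_class = "highlight", is_target = TRUE, target = "A")
  rec <- simulate_recording(sch, cfg, duration_s = 3)
  ep <- extract_epochs(rec)
  tgt <- 1L
  mont <- cfg$montage
  pk <- mont[mont$channel == "Cz", ]
  comp <- erp_components()[erp_components()$component == "P300", ]
  for (ch in c("Cz", "PO7", "F3")) {
    d2 <- (mont$x[mont$channel == ch] - pk$x)^2 +
      (mont$y[mont$channel == ch] - pk$y)^2
    w <- exp(-d2 / (2 * comp$spread^2))
    expected <- 5 * w * erp_kernel(280, 370, ep$time_ms)
    expect_equal(ep$data[tgt, ch, ], expected, tolerance = 1e-12)
  }
})

test_that("simulation is deterministic given the seed", {
  set.seed(9); sch <- build_schedule("RASP_F", "A", fast_timing(1))
  set.seed(10); r1 <- simulate_recording(sch)
  set.seed(10); r2 <- simulate_recording(sch)
  expect_identical(r1$signal, r2$signal)
})

test_that("the forward model is linear in flash events (noiseless)", {
  cfg <- sim_config(noise_sigma = 0)
  base <- tibble::tibble(
    trial = 0L, sequence = 0L, flash = 0L,
    letters = list(c("A", "B", "C", "D", "E", "F")),
    stim_class = "self_face", is_target = TRUE, target = "A")
  ev1 <- base; ev1$onset_s <- 1.0
  ev2 <- base; ev2$onset_s <- 2.0
  both <- dplyr::bind_rows(ev1, ev2)
  both$flash <- 0:1
  dur <- 4
  r1 <- simulate_recording(ev1, cfg, duration_s = dur)
  r12 <- simulate_recording(both, cfg, duration_s = dur)
  # second flash follows the first at TTI 0, so match its attenuation
  p300 <- cfg$amplitudes$p300_target
  att <- cfg$tti_attenuation[1]
  # recompute flash 2 alone with the attenuated P300 it gets in the pair
  cfg_att <- sim_config(noise_sigma = 0,
                        amplitudes = modifyList(cfg$amplitudes,
                                                list(p300_target = p300 * att)),
                        tti_attenuation = c(1, 1, 1, 1))
  r2_att <- simulate_recording(ev2, cfg_att, duration_s = dur)
  expect_equal(r12$signal, r1$signal + r2_att$signal, tolerance = 1e-12)
})

test_that("mean target-minus-nontarget window amplitude recovers the P300", {
  # 10 trials x 10 sequences: 200 target and 1000 non-target flashes
  cfg <- sim_config(tti_attenuation = c(1, 1, 1, 1))
  set.seed(31)
  sch <- build_schedule("RC", "ABCDEFGHIJ")
  rec <- simulate_recording(sch, cfg)
  ep <- extract_epochs(rec)
  win <- ep$time_ms >= 280 & ep$time_ms <= 370
  cz <- rowMeans(ep$data[, "Cz", win])
  y <- ep$metadata$is_target
  expect_equal(sum(y), 200L); expect_equal(sum(!y), 1000L)
  diff_obs <- mean(cz[y]) - mean(cz[!y])
  expected <- cfg$amplitudes$p300_target *
    mean(erp_kernel(280, 370, ep$time_ms[win]))
  se <- sqrt(var(cz[y]) / sum(y) + var(cz[!y]) / sum(!y))
  expect_lt(abs(diff_obs - expected), 3 * se)
})

test_that("background noise follows the configured 1/f spectrum", {
  set.seed(8)
  x <- pink_noise(30000, alpha = 1)        # 60 s at 500 Hz
  pg <- stats::spec.pgram(stats::ts(x, frequency = 500), taper = 0,
                          plot = FALSE, detrend = FALSE)
  keep <- pg$freq >= 1 & pg$freq <= 30
  fit <- stats::lm(log(pg$spec[keep]) ~ log(pg$freq[keep]))
  alpha_hat <- -unname(coef(fit)[2])
  expect_lt(abs(alpha_hat - 1), 0.3)
})

test_that("grand-average target contrast peaks at Cz in the P300 window", {
  set.seed(55)
  # default amplitudes; noise reduced so the channel argmax reflects the
  # component topography rather than residual background at this trial count
  cfg <- sim_config(noise_sigma = 1)
  sch <- build_schedule("RC", "STIMULATING", fast_timing(8))
  rec <- simulate_recording(sch, cfg)
  rec <- bandpass_filter(resample_recording(rec, 100))
  ep <- baseline_correct(extract_epochs(rec))
  win <- ep$time_ms >= 280 & ep$time_ms <= 370
  y <- ep$metadata$is_target
  diff_by_ch <- rowMeans(ep$data[y, , win], dims = 2) |> colMeans() -
    (rowMeans(ep$data[!y, , win], dims = 2) |> colMeans())
  expect_equal(ep$channels[which.max(diff_by_ch)], "Cz")
})

test_that("generate_study produces the six study runs with correct structure", {
  set.seed(202)
  study <- generate_study(sim_config(), fast_timing(2))
  expect_named(study, c("RC", "RASP", "RASP_F"))
  for (cond in names(study)) {
    expect_equal(max(study[[cond]]$train$events$trial) + 1L, 24L)
    expect_equal(max(study[[cond]]$test$events$trial) + 1L, 15L)
    classes <- unique(c(study[[cond]]$train$events$stim_class,
                        study[[cond]]$test$events$stim_class))
    if (cond == "RASP_F") {
      expect_setequal(classes, c("self_face", "non_self_face"))
    } else {
      expect_equal(classes, "highlight")
    }
  }
})

test_that("simulation configs round-trip through JSON", {
  cfg <- sim_config(noise_sigma = 4.5, session_effect = 0.9)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$noise_sigma, 4.5)
  expect_equal(back$session_effect, 0.9)
  expect_equal(back$amplitudes, cfg$amplitudes)
  expect_equal(back$tti_attenuation, cfg$tti_attenuation)
  expect_equal(as.data.frame(back$montage), as.data.frame(cfg$montage))
  expect_equal(as.data.frame(back$components),
               as.data.frame(cfg$components))
})
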