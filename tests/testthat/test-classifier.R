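test_that("shrinkage covariance reproduces the frozen fixture", {
  # independent direct evaluation of the analytic-shrinkage formulas on this
  # matrix gives gamma = 1, nu = 5/9, sigma = nu * I (regression fixture)
  x <- matrix(c(1, 2, 0,
                0, 1, 1,
                2, 0, 1,
                1, 1, 0), nrow = 4, byrow = TRUE)
  sc <- shrinkage_covariance(x)
  expect_equal(sc$gamma, 1)
  expect_equal(sc$nu, 5 / 9)
  expect_equal(sc$sigma, diag(5 / 9, 3))
  s_expected <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 1) / 3, 3, 3)
  expect_equal(sc$S, s_expected)
})

test_that("shrinkage covariance agrees with an independent loop oracle", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(c(15, 40, 80), 1)
    p <- sample(3:6, 1)
    base <- matrix(rnorm(n * p), n, p)
    x <- base + rnorm(n)          # common factor induces strong covariance
    sc <- shrinkage_covariance(x)
    or <- shrinkage_oracle(x)
    expect_equal(sc$gamma, or$gamma, tolerance = 1e-10)
    expect_equal(sc$sigma, or$sigma, tolerance = 1e-10)
    # some cases should exercise an interior intensity
    expect_true(sc$gamma >= 0 && sc$gamma <= 1)
    # trace-preserving target
    expect_equal(sum(diag(sc$sigma)), sum(diag(sc$S)), tolerance = 1e-8)
  }
})

test_that("degenerate input (S = nu I) yields gamma 1 and the target", {
  x <- matrix(c(1, 0, 0, 1, -1, 0, 0, -1), ncol = 2, byrow = TRUE)
  sc <- shrinkage_covariance(x)
  expect_equal(sc$gamma, 1)
  expect_equal(sc$sigma, diag(sc$nu, 2))
  expect_error(shrinkage_covariance(matrix(1, 1, 3)), "n >= 2")
})

test_that("shrinkage intensity falls as sample size grows", {
  set.seed(123)
  p <- 50
  # true covariance must differ from the spherical target, else gamma ~ 1
  # at every n; a common factor plus heteroscedastic scales provides that
  scales <- seq(0.5, 3, length.out = p)
  draw <- function(n) {
    x <- matrix(rnorm(n * p), n, p) %*% diag(scales) + 2 * rnorm(n)
    shrinkage_covariance(x)$gamma
  }
  mean_gamma <- vapply(c(20, 200, 2000),
                       function(n) mean(replicate(3, draw(n))), 0)
  expect_true(all(diff(mean_gamma) < 0))
})

test_that("RLDA separates a one-informative-feature problem", {
  set.seed(17)
  n <- 60
  lab <- rep(c(TRUE, FALSE), n / 2)
  x <- matrix(rnorm(n * 4, sd = 0.05), n, 4)
  x[, 1] <- x[, 1] + ifelse(lab, 1, -1)
  colnames(x) <- paste0("f", 1:4)
  m <- train_rlda(x, lab)
  sc <- rlda_score(m, x)
  expect_equal(mean((sc > 0) == lab), 1)           # 100% training accuracy
  expect_true(abs(m$w[1]) > 5 * max(abs(m$w[-1]))) # weight on feature 1
})

test_that("identical class means give zero weights and zero scores", {
  x <- rbind(diag(3), diag(3))
  lab <- rep(c(TRUE, FALSE), each = 3)
  m <- train_rlda(x, lab)
  expect_equal(unname(m$w), rep(0, 3))
  expect_equal(rlda_score(m, x), rep(0, 6))
  expect_error(train_rlda(x, rep(TRUE, 6)), "both classes")
})

test_that("RLDA weights match a direct solve oracle on a fixed dataset", {
  set.seed(33)
  x <- matrix(rnorm(8 * 3), 8, 3)
  lab <- rep(c(TRUE, FALSE), each = 4)
  x[lab, 1] <- x[lab, 1] + 1
  m <- train_rlda(x, lab)
  # oracle: class-center the data, loop-evaluated shrinkage, direct solve
  mu_t <- colMeans(x[lab, ]); mu_nt <- colMeans(x[!lab, ])
  xc <- x
  xc[lab, ] <- sweep(x[lab, ], 2, mu_t)
  xc[!lab, ] <- sweep(x[!lab, ], 2, mu_nt)
  or <- shrinkage_oracle(xc)
  w_or <- solve(or$sigma) %*% (mu_t - mu_nt)
  expect_equal(unname(m$w), as.numeric(w_or), tolerance = 1e-8)
  expect_equal(m$b, -sum(m$w * (mu_t + mu_nt)) / 2)
})

test_that("scores follow the linear form and its algebra", {
  set.seed(44)
  x <- matrix(rnorm(40 * 5), 40, 5)
  lab <- rep(c(TRUE, FALSE), 20)
  x[lab, ] <- x[lab, ] + 0.5
  m <- train_rlda(x, lab)
  gap <- sum(m$w * (m$mu_target - m$mu_nontarget))
  expect_equal(rlda_score(m, rbind(m$mu_target)), gap / 2)
  expect_equal(rlda_score(m, rbind((m$mu_target + m$mu_nontarget) / 2)), 0,
               tolerance = 1e-12)
  # batch scoring equals per-row scoring
  batch <- rlda_score(m, x)
  rows <- vapply(seq_len(nrow(x)), function(i) rlda_score(m, x[i, , drop = FALSE]), 0)
  expect_equal(batch, rows)
  expect_error(rlda_score(m, x[, 1:3]), "dimension mismatch")
})

test_that("scaling all inputs leaves decisions unchanged", {
  set.seed(55)
  x <- matrix(rnorm(60 * 4), 60, 4)
  lab <- rep(c(TRUE, FALSE), 30)
  x[lab, 2] <- x[lab, 2] + 1
  m1 <- train_rlda(x, lab)
  m2 <- train_rlda(3.7 * x, lab)
  s1 <- rlda_score(m1, x)
  s2 <- rlda_score(m2, 3.7 * x)
  # scores scale by a positive factor: same signs, same ranking
  expect_equal(sign(s1), sign(s2))
  expect_equal(order(s1), order(s2))
  expect_gt(stats::cor(s1, s2), 0.999999)
})

test_that("training works at the speller's natural 1:5 class imbalance", {
  set.seed(66)
  n_t <- 40; n_nt <- 200
  x <- rbind(matrix(rnorm(n_t * 6, mean = 0.8), n_t, 6),
             matrix(rnorm(n_nt * 6), n_nt, 6))
  lab <- rep(c(TRUE, FALSE), c(n_t, n_nt))
  m <- train_rlda(x, lab)
  sc <- rlda_score(m, x)
  expect_gt(mean(sc[lab]), mean(sc[!lab]))   # sign convention holds
  expect_gt(mean((sc > 0) == lab), 0.8)
})

test_that("models serialize to JSON and back", {
  set.seed(77)
  x <- matrix(rnorm(20 * 3), 20, 3)
  colnames(x) <- c("Cz_1", "Cz_2", "Pz_1")
  lab <- rep(c(TRUE, FALSE), 10)
  iv <- tibble::tibble(start_ms = c(100, 300), end_ms = c(200, 400))
  m <- train_rlda(x, lab, intervals = iv)
  path <- withr::local_tempfile(fileext = ".json")
  write_rlda(m, path)
  back <- read_rlda(path)
  expect_equal(back$w, m$w)
  expect_equal(back$b, m$b)
  expect_equal(back$gamma, m$gamma)
  expect_equal(back$intervals, m$intervals)
  expect_equal(rlda_score(back, x), rlda_score(m, x))
})
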