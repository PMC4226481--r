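#' Canonical ERP component analysis windows
#'
#' The per-component measurement windows and electrodes used for amplitude
#' statistics: N170 at PO7 over 130--200 ms, P300 at Cz over 280--370 ms,
#' N400f at Cz over 400--550 ms.
#'
#' @return A tibble with columns `component`, `channel`, `start_ms`,
#'   `end_ms`.
#' @export
component_windows <- function() {
  tibble::tibble(
    component = c("N170", "P300", "N400f"),
    channel = c("PO7", "Cz", "Cz"),
    start_ms = c(130, 280, 400),
    end_ms = c(200, 370, 550)
  )
}

#' Per-epoch mean amplitude in a component window
#'
#' Averages each epoch's amplitude at the component's electrode over its
#' measurement window (closed interval, in ms post-stimulus).
#'
#' @param epochs An `epoch_set`.
#' @param component One of `"N170"`, `"P300"`, `"N400f"`, or a one-row
#'   tibble with `channel`, `start_ms`, `end_ms`.
#' @return A tibble: the epoch metadata plus columns `component` and
#'   `amplitude` (microvolts).
#' @export
component_window_mean <- function(epochs, component = "P300") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(component)) {
    wins <- component_windows()
    win <- wins[wins$component == component, ]
    if (nrow(win) != 1L) stop("unknown component: ", component)
  } else {
    win <- component
    if (is.null(win$component)) win$component <- "custom"
  }
  ci <- match(win$channel, epochs$channels)
  if (is.na(ci)) stop("channel not in montage: ", win$channel)
  sel <- epochs$time_ms >= win$start_ms & epochs$time_ms <= win$end_ms
  if (!any(sel)) stop("component window contains no samples")
  vals <- rowMeans(epochs$data[, ci, sel, drop = FALSE], dims = 1)
  out <- epochs$metadata
  out$component <- win$component
  out$amplitude <- as.numeric(vals)
  out
}

#' Exact paired sign test
#'
#' Two-sided exact binomial sign test on paired samples: ties (`a == b`) are
#' dropped and the number of pairs with `a > b` among the remaining is
#' tested against Binomial(m, 1/2).
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return A tibble with `statistic` (number of positive pairs), `n`
#'   (non-tied pairs), `p_value`.
#' @export
paired_sign_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) stop("all pairs are tied")
  k <- sum(d > 0)
  m <- length(d)
  p <- stats::binom.test(k, m, p = 0.5, alternative = "two.sided")$p.value
  tibble::tibble(statistic = k, n = m, p_value = p)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` tests.
#'
#' @param p Numeric vector of p values.
#' @param m Family size; must be at least `length(p)` (default
#'   `length(p)`).
#' @return Adjusted p values in the same order.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size m must be >= number of p values")
  pmin(1, m * p)
}

#' Pooled-variance two-sample t test
#'
#' Classic two-sample t test with pooled variance and the null hypothesis of
#' equal means. Degenerate input (zero pooled variance with equal means)
#' yields `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors, each with at least 2 observations.
#' @return A tibble with `statistic` (t), `df`, `p_value`, `estimate`
#'   (mean of `a` minus mean of `b`).
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  est <- mean(a) - mean(b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (sp2 == 0) {
    if (est == 0) {
      return(tibble::tibble(statistic = 0, df = df, p_value = 1,
                            estimate = 0))
    }
    stop("zero pooled variance with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, estimate = est)
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA on a complete balanced design.
#' Each effect is tested against its own effect-by-subject interaction:
#' with `a` and `b` factor levels and `s` subjects the degrees of freedom
#' are `(a-1, (a-1)(s-1))`, `(b-1, (b-1)(s-1))` and
#' `((a-1)(b-1), (a-1)(b-1)(s-1))`. No sphericity correction is applied.
#'
#' @param data A data frame in long format.
#' @param value,subject,factor1,factor2 Column names (strings) of the
#'   dependent variable, the subject identifier and the two within-subject
#'   factors.
#' @return A tibble of class `anova_table` with one row per effect
#'   (`factor1`, `factor2`, `factor1:factor2`): `effect`, `df1`, `df2`,
#'   `ss`, `ms`, `statistic` (F), `p_value`.
#' @export
repeated_measures_anova_2way <- function(data, value = "value",
                                         subject = "subject",
                                         factor1 = "factor1",
                                         factor2 = "factor2") {
  df <- data.frame(
    y = data[[value]],
    s = factor(data[[subject]]),
    A = factor(data[[factor1]]),
    B = factor(data[[factor2]])
  )
  if (anyNA(df)) stop("missing values in the design")
  cnt <- table(df$s, df$A, df$B)
  if (any(cnt != 1)) stop("design must be complete and balanced (one observation per cell)")
  ns <- nlevels(df$s); na <- nlevels(df$A); nb <- nlevels(df$B)
  g <- mean(df$y)
  m_s <- tapply(df$y, df$s, mean)
  m_a <- tapply(df$y, df$A, mean)
  m_b <- tapply(df$y, df$B, mean)
  m_sa <- tapply(df$y, list(df$s, df$A), mean)
  m_sb <- tapply(df$y, list(df$s, df$B), mean)
  m_ab <- tapply(df$y, list(df$A, df$B), mean)
  y_arr <- tapply(df$y, list(df$s, df$A, df$B), mean)

  ss_a <- ns * nb * sum((m_a - g)^2)
  ss_b <- ns * na * sum((m_b - g)^2)
  ss_sa <- nb * sum((m_sa - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + g)^2)
  ss_sb <- na * sum((m_sb - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + g)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + g)^2)
  resid <- y_arr
  for (i in seq_len(ns)) for (j in seq_len(na)) for (k in seq_len(nb)) {
    resid[i, j, k] <- y_arr[i, j, k] - m_sa[i, j] - m_sb[i, k] -
      m_ab[j, k] + m_s[i] + m_a[j] + m_b[k] - g
  }
  ss_sab <- sum(resid^2)

  eff <- tibble::tibble(
    effect = c(factor1, factor2, paste0(factor1, ":", factor2)),
    df1 = c(na - 1, nb - 1, (na - 1) * (nb - 1)),
    df2 = c((na - 1) * (ns - 1), (nb - 1) * (ns - 1),
            (na - 1) * (nb - 1) * (ns - 1)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_err = c(ss_sa, ss_sb, ss_sab)
  )
  eff$ms <- eff$ss / eff$df1
  # zero effect SS is F = 0 even when the error SS is also degenerate
  eff$statistic <- ifelse(eff$ss <= 0, 0, eff$ms / (eff$ss_err / eff$df2))
  eff$p_value <- stats::pf(eff$statistic, eff$df1, eff$df2,
                           lower.tail = FALSE)
  out <- eff[, c("effect", "df1", "df2", "ss", "ms", "statistic", "p_value")]
  class(out) <- c("anova_table", class(out))
  out
}

#' Accuracy profile over target-to-target intervals
#'
#' Bins target-flash outcomes by the number of non-target flashes preceding
#' the target (TTI bins 0, 1, 2, 3, 4 and >= 5) and reports the fraction of
#' correct outcomes per bin. Empty bins are kept with `NA` accuracy (not 0).
#'
#' @param data A data frame with one row per target flash.
#' @param tti,correct Column names (strings) holding the integer TTI and
#'   the logical outcome.
#' @return A tibble with columns `tti_bin` (ordered factor `"0"` ...
#'   `"4"`, `">=5"`), `n`, `accuracy`.
#' @export
tti_accuracy_profile <- function(data, tti = "tti", correct = "correct") {
  tt <- data[[tti]]
  ok <- data[[correct]]
  keep <- !is.na(tt)
  tt <- tt[keep]; ok <- ok[keep]
  lv <- c(as.character(0:4), ">=5")
  bin <- factor(ifelse(tt >= 5, ">=5", as.character(tt)), levels = lv)
  tibble::tibble(
    tti_bin = factor(lv, levels = lv),
    n = as.integer(table(bin)),
    accuracy = as.numeric(tapply(ok, bin, mean))
  )
}

#' Target-centered error topography
#'
#' Builds the 11 x 11 count matrix of decision offsets: for every trial the
#' cell at (decoded row - target row, decoded col - target col), with the
#' target centered at (0, 0). The center cell counts correct selections and
#' the matrix total equals the number of trials.
#'
#' @param decoded,truth Character vectors of decoded and true symbols,
#'   aligned.
#' @param matrix Letter matrix giving symbol positions (default
#'   [letter_matrix()]).
#' @return An 11 x 11 integer matrix of class `error_topography` with
#'   dimnames `-5 ... 5` (rows = row offset, cols = column offset).
#' @export
adjacency_error_map <- function(decoded, truth, matrix = letter_matrix()) {
  stopifnot(length(decoded) == length(truth))
  pd <- symbol_positions(matrix, decoded)
  pt <- symbol_positions(matrix, truth)
  dr <- pd$row - pt$row
  dc <- pd$col - pt$col
  out <- base::matrix(0L, 11, 11, dimnames = list(-5:5, -5:5))
  for (i in seq_along(dr)) {
    out[dr[i] + 6L, dc[i] + 6L] <- out[dr[i] + 6L, dc[i] + 6L] + 1L
  }
  class(out) <- c("error_topography", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.error_topography <- function(x, ...) {
  tibble::tibble(
    d_row = rep(-5:5, times = 11),
    d_col = rep(-5:5, each = 11),
    n = as.integer(unclass(x))
  )
}
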