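#' Signed r-squared discriminability map
#'
#' For every (channel, time) point, computes the signed squared point-biserial
#' correlation between single-epoch amplitude and the binary target /
#' non-target label:
#' \deqn{r = \frac{\sqrt{N_1 N_2}}{N_1 + N_2}\,\frac{\mu_1 - \mu_2}{\sigma},
#' \qquad \mathrm{sgn}\,r^2 = \mathrm{sign}(\mu_1 - \mu_2)\, r^2,}
#' where class 1 is target, \eqn{\mu_1,\mu_2} are the class means, and
#' \eqn{\sigma} is the population (divide-by-N) standard deviation over all
#' epochs. With this convention the value equals the signed squared Pearson
#' correlation between amplitude and the 0/1 class indicator. Points with
#' \eqn{\sigma = 0} are defined as 0.
#'
#' @param epochs An `epoch_set` (see [extract_epochs()]) with both classes
#'   present.
#' @return A channels x time matrix of class `srsq_map` with attribute
#'   `time_ms`.
#' @export
signed_r_squared_map <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  y <- epochs$metadata$is_target
  n1 <- sum(y); n2 <- sum(!y)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  n <- n1 + n2
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, nrow = d[1])        # columns = (channel, time)
  shape <- function(v) matrix(v, nrow = d[2], ncol = d[3])
  mu1 <- shape(colMeans(flat[y, , drop = FALSE]))
  mu2 <- shape(colMeans(flat[!y, , drop = FALSE]))
  mu <- shape(colMeans(flat))
  ex2 <- shape(colMeans(flat^2))
  sigma <- sqrt(pmax(ex2 - mu^2, 0))
  r <- sqrt(n1 * n2) / n * (mu1 - mu2) / sigma
  r[sigma == 0] <- 0
  out <- sign(mu1 - mu2) * r^2
  structure(out, class = "srsq_map", time_ms = epochs$time_ms,
            dimnames = list(epochs$channels, NULL))
}

#' @exportS3Method generics::tidy
tidy.srsq_map <- function(x, ...) {
  tibble::tibble(
    channel = rep(rownames(x), times = ncol(x)),
    time_ms = rep(attr(x, "time_ms"), each = nrow(x)),
    srsq = as.vector(unclass(x))
  )
}

#' Select discriminative intervals from an r-squared map
#'
#' Greedy peak-growing heuristic over the channel-summed discriminability
#' score \eqn{s(t) = \sum_c r^2(c, t)} within the search window: repeatedly
#' pick the unmasked maximum \eqn{t^*}, grow a contiguous interval while
#' \eqn{s(t) \ge 0.5\, s(t^*)}, and mask it. If the remaining score is
#' everywhere zero, the remaining intervals tile the unoccupied parts of the
#' window left-to-right with equal widths (for an all-zero map: `n`
#' equal-width intervals tiling the window). Deterministic given the map.
#'
#' @param map An `srsq_map` (see [signed_r_squared_map()]).
#' @param n Number of intervals (default 8).
#' @param window Search window in ms, half-open `(window[1], window[2]]`
#'   (default `c(100, 600)`).
#' @return A tibble with `n` rows and columns `start_ms`, `end_ms`;
#'   intervals are half-open `(start_ms, end_ms]`, pairwise disjoint, sorted
#'   by start.
#' @export
select_discriminative_intervals <- function(map, n = 8,
                                            window = c(100, 600)) {
  stopifnot(inherits(map, "srsq_map"), n >= 1)
  tms <- attr(map, "time_ms")
  if (window[1] < min(tms) - 1e-9 || window[2] > max(tms) + 1e-9) {
    stop("search window outside the map's time axis")
  }
  dt <- stats::median(diff(tms))
  in_win <- which(tms > window[1] & tms <= window[2])
  if (length(in_win) < n) stop("search window too small for ", n, " intervals")
  s <- colSums(abs(unclass(map)))[in_win]
  t_in <- tms[in_win]
  masked <- rep(FALSE, length(in_win))
  picked <- list()
  for (i in seq_len(n)) {
    avail <- which(!masked)
    if (length(avail) == 0L || max(s[avail]) == 0) break
    star <- avail[which.max(s[avail])]
    thr <- 0.5 * s[star]
    a <- star
    while (a > 1 && !masked[a - 1] && s[a - 1] >= thr) a <- a - 1
    b <- star
    while (b < length(s) && !masked[b + 1] && s[b + 1] >= thr) b <- b + 1
    masked[a:b] <- TRUE
    picked[[length(picked) + 1L]] <- c(t_in[a] - dt, t_in[b])
  }
  m <- n - length(picked)
  if (m > 0 && any(!masked)) {
    # tile unoccupied runs of the window left-to-right, widths equal in ms
    runs <- split(which(!masked), cumsum(c(1, diff(which(!masked)) != 1)))
    spans <- purrr::map(runs, function(ix) c(t_in[ix[1]] - dt, t_in[ix[length(ix)]]))
    lens <- vapply(spans, function(sp) sp[2] - sp[1], 0)
    # allocate interval counts proportional to span length (largest remainder)
    raw <- lens / sum(lens) * m
    cnt <- floor(raw)
    rem <- m - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    for (j in seq_along(spans)) {
      if (cnt[j] == 0) next
      bks <- seq(spans[[j]][1], spans[[j]][2], length.out = cnt[j] + 1)
      for (q in seq_len(cnt[j])) {
        picked[[length(picked) + 1L]] <- c(bks[q], bks[q + 1])
      }
    }
  }
  # the greedy pass can swallow the whole window in fewer than n intervals;
  # split the widest picked intervals at a sample boundary until n remain
  while (length(picked) < n) {
    widths <- vapply(picked, function(iv) iv[2] - iv[1], 0)
    widths[widths < 2 * dt - 1e-9] <- -Inf   # needs >= 2 samples to split
    j <- which.max(widths)
    if (!is.finite(widths[j])) stop("search window too fragmented to split")
    iv <- picked[[j]]
    mid <- iv[1] + dt * floor((iv[2] - iv[1]) / (2 * dt))
    picked[[j]] <- c(iv[1], mid)
    picked[[length(picked) + 1L]] <- c(mid, iv[2])
  }
  out <- tibble::tibble(
    start_ms = vapply(picked, `[`, 0, 1),
    end_ms = vapply(picked, `[`, 0, 2)
  )
  dplyr::arrange(out, .data$start_ms)
}

#' Interval-mean spatiotemporal features
#'
#' For every epoch, channel and interval, the mean amplitude of that channel
#' over the interval's samples (sample times `t` with
#' `start_ms < t <= end_ms`). With 29 channels and 8 intervals this yields
#' the 232-dimensional feature vector. Columns are ordered channel-major
#' (all intervals of channel 1, then channel 2, ...).
#'
#' @param epochs An `epoch_set`.
#' @param intervals A tibble of intervals from
#'   [select_discriminative_intervals()].
#' @return A tibble of class `speller_features`: metadata columns `.epoch`,
#'   `.trial`, `.sequence`, `.flash`, `.stim_class`, `.is_target`, `.tti`
#'   followed by one numeric column per (channel, interval) pair named
#'   `<channel>_<k>`.
#' @export
interval_mean_features <- function(epochs, intervals) {
  stopifnot(inherits(epochs, "epoch_set"),
            all(c("start_ms", "end_ms") %in% names(intervals)))
  tms <- epochs$time_ms
  sel <- purrr::map(seq_len(nrow(intervals)), function(k) {
    ix <- which(tms > intervals$start_ms[k] & tms <= intervals$end_ms[k])
    if (length(ix) == 0L) {
      stop(sprintf("interval (%g, %g] ms contains no samples",
                   intervals$start_ms[k], intervals$end_ms[k]))
    }
    ix
  })
  nch <- length(epochs$channels)
  nk <- nrow(intervals)
  feat <- matrix(0, nrow = dim(epochs$data)[1], ncol = nch * nk)
  cn <- character(nch * nk)
  col <- 0L
  for (ci in seq_len(nch)) {
    for (k in seq_len(nk)) {
      col <- col + 1L
      sl <- epochs$data[, ci, sel[[k]], drop = FALSE]
      feat[, col] <- rowMeans(sl, dims = 1)
      cn[col] <- paste0(epochs$channels[ci], "_", k)
    }
  }
  colnames(feat) <- cn
  meta <- epochs$metadata
  out <- tibble::tibble(
    .epoch = meta$epoch, .trial = meta$trial, .sequence = meta$sequence,
    .flash = meta$flash, .stim_class = meta$stim_class,
    .is_target = meta$is_target, .tti = meta$tti
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(feat))
  class(out) <- c("speller_features", class(out))
  attr(out, "feature_names") <- cn
  attr(out, "intervals") <- intervals
  out
}

feature_names <- function(features) {
  fn <- attr(features, "feature_names")
  if (is.null(fn)) fn <- setdiff(names(features),
                                 grep("^\\.", names(features), value = TRUE))
  fn
}

# numeric matrix of the feature columns
feature_matrix <- function(features) {
  as.matrix(features[, feature_names(features), drop = FALSE])
}
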