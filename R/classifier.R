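#' Analytic shrinkage covariance estimate
#'
#' Schafer--Strimmer analytic shrinkage of the empirical covariance toward a
#' scaled identity: \eqn{\hat\Sigma = (1-\gamma) S + \gamma \nu I}, with
#' \eqn{S} the unbiased (divide-by-(n-1)) empirical covariance, \eqn{\nu}
#' the mean of its diagonal, and the closed-form intensity
#' \deqn{\gamma^* = \mathrm{clamp}\Big(
#'   \frac{\sum_{ij} \widehat{\mathrm{Var}}(s_{ij})}
#'        {\sum_{ij} (s_{ij} - t_{ij})^2}, 0, 1\Big),}
#' where \eqn{T = \nu I} and \eqn{\widehat{\mathrm{Var}}(s_{ij})} is the
#' standard unbiased estimate of the sampling variance of the covariance
#' entries. The target preserves the trace, so
#' \eqn{\mathrm{tr}(\hat\Sigma) = \mathrm{tr}(S)}. If the denominator is 0
#' (S already equals \eqn{\nu I}), \eqn{\gamma} is defined as 1.
#'
#' @param x Numeric data matrix, n x p (rows = observations). Column means
#'   are removed internally.
#' @return A list of class `shrinkage_cov` with elements `sigma` (p x p),
#'   `gamma`, `nu`, and `S`.
#' @export
shrinkage_covariance <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 observations (n >= 2)")
  xc <- scale(x, center = TRUE, scale = FALSE)
  wbar <- crossprod(xc) / n                 # mean of w_kij
  s <- n / (n - 1) * wbar
  nu <- mean(diag(s))
  # Var-hat(s_ij) = n/(n-1)^3 * sum_k (w_kij - wbar_ij)^2
  sum_w2 <- crossprod(xc^2)
  var_s <- n / (n - 1)^3 * (sum_w2 - n * wbar^2)
  tgt <- diag(nu, p)
  denom <- sum((s - tgt)^2)
  gamma <- if (denom <= 0) 1 else min(max(sum(var_s) / denom, 0), 1)
  sigma <- (1 - gamma) * s + gamma * tgt
  structure(list(sigma = sigma, gamma = gamma, nu = nu, S = s),
            class = "shrinkage_cov")
}

#' @export
print.shrinkage_cov <- function(x, ...) {
  cat(sprintf("<shrinkage_cov> p = %d, gamma = %.4f, nu = %.4g\n",
              nrow(x$sigma), x$gamma, x$nu))
  invisible(x)
}

#' Train a shrinkage-regularized LDA classifier
#'
#' Binary linear discriminant analysis with analytic shrinkage of the pooled
#' within-class covariance: \eqn{w = \hat\Sigma^{-1}(\mu_t - \mu_{nt})},
#' \eqn{b = -w^\top(\mu_t + \mu_{nt})/2}. Positive scores indicate the
#' target class; the midpoint bias makes `score(mu_t) = -score(mu_nt)`.
#'
#' @param features A `speller_features` tibble (labels taken from
#'   `.is_target`) or a numeric matrix.
#' @param labels Logical/0-1 vector; required when `features` is a matrix.
#' @param intervals Optional interval table stored with the model (so test
#'   data reuses the training-phase intervals).
#' @return An object of class `rlda`: list with `w`, `b`, `gamma`, `nu`,
#'   `mu_target`, `mu_nontarget`, `feature_names`, `intervals`.
#' @export
train_rlda <- function(features, labels = NULL, intervals = NULL) {
  if (is.data.frame(features)) {
    if (is.null(labels)) labels <- features$.is_target
    if (is.null(intervals)) intervals <- attr(features, "intervals")
    x <- feature_matrix(features)
  } else {
    x <- as.matrix(features)
  }
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(x), !anyNA(labels))
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  mu_t <- colMeans(x[labels, , drop = FALSE])
  mu_nt <- colMeans(x[!labels, , drop = FALSE])
  xc <- x
  xc[labels, ] <- sweep(x[labels, , drop = FALSE], 2, mu_t)
  xc[!labels, ] <- sweep(x[!labels, , drop = FALSE], 2, mu_nt)
  cov <- shrinkage_covariance(xc)
  w <- tryCatch(
    solve(cov$sigma, mu_t - mu_nt),
    error = function(e) stop("covariance matrix is singular: ",
                             conditionMessage(e))
  )
  b <- -sum(w * (mu_t + mu_nt)) / 2
  structure(
    list(w = w, b = b, gamma = cov$gamma, nu = cov$nu,
         mu_target = mu_t, mu_nontarget = mu_nt,
         feature_names = colnames(x), intervals = intervals,
         n_target = n1, n_nontarget = n2),
    class = "rlda"
  )
}

#' Score epochs with an RLDA model
#'
#' Linear score \eqn{w^\top x + b}; higher values are more target-like.
#'
#' @param model An [train_rlda()] model.
#' @param features A `speller_features` tibble or numeric matrix with the
#'   model's feature columns.
#' @return Numeric score vector, one per row.
#' @export
rlda_score <- function(model, features) {
  stopifnot(inherits(model, "rlda"))
  x <- if (is.data.frame(features)) feature_matrix(features)
       else as.matrix(features)
  if (ncol(x) != length(model$w)) {
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 length(model$w), ncol(x)))
  }
  if (!is.null(colnames(x)) && !is.null(model$feature_names) &&
      !identical(colnames(x), model$feature_names)) {
    x <- x[, model$feature_names, drop = FALSE]
  }
  as.numeric(x %*% model$w + model$b)
}

#' @export
predict.rlda <- function(object, newdata, ...) {
  rlda_score(object, newdata)
}

#' @export
print.rlda <- function(x, ...) {
  cat(sprintf(
    "<rlda> %d features, gamma = %.4f (n = %d target / %d non-target)\n",
    length(x$w), x$gamma, x$n_target, x$n_nontarget))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rlda <- function(x, ...) {
  tibble::tibble(term = x$feature_names %||% paste0("x", seq_along(x$w)),
                 estimate = unname(x$w))
}

#' @exportS3Method generics::glance
glance.rlda <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, nu = x$nu, n_features = length(x$w),
                 n_target = x$n_target, n_nontarget = x$n_nontarget)
}

#' Serialize / restore an RLDA model as JSON
#'
#' @param model An `rlda` model.
#' @param path File path.
#' @return `write_rlda()` returns `path` invisibly; `read_rlda()` the model.
#' @export
write_rlda <- function(model, path) {
  stopifnot(inherits(model, "rlda"))
  obj <- unclass(model)
  obj$intervals <- if (!is.null(obj$intervals)) {
    as.list(obj$intervals)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rlda
#' @export
read_rlda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$intervals)) {
    obj$intervals <- tibble::as_tibble(obj$intervals)
  }
  names(obj$w) <- obj$feature_names
  names(obj$mu_target) <- obj$feature_names
  names(obj$mu_nontarget) <- obj$feature_names
  structure(obj, class = "rlda")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
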