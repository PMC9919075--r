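#' Column-wise autoscaling
#'
#' Centers each column and optionally scales to unit variance (n-1 sd) or by
#' the square root of the sd (Pareto). Constant columns cannot be
#' unit-variance scaled; they are flagged and left centered only.
#'
#' @param X numeric matrix.
#' @param center center columns (default TRUE).
#' @param scale `"unit_variance"`, `"pareto"` or `"none"`.
#' @return list with `X` (scaled matrix), `means`, `sds` (the divisors
#'   actually applied), `constant_cols` (indices left unscaled), `center`
#'   and `scale`.
#' @export
autoscale <- function(X, center = TRUE,
                      scale = c("unit_variance", "pareto", "none")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  m <- if (center) colMeans(X) else rep(0, ncol(X))
  s <- apply(X, 2, stats::sd)
  constant <- which(s == 0)
  div <- switch(scale,
                unit_variance = ifelse(s == 0, 1, s),
                pareto = ifelse(s == 0, 1, sqrt(s)),
                none = rep(1, ncol(X)))
  Xs <- sweep(sweep(X, 2, m, "-"), 2, div, "/")
  list(X = Xs, means = m, sds = div, constant_cols = constant,
       center = center, scale = scale)
}

#' Fit a single-response PLS regression by NIPALS
#'
#' Extracts `A` latent components maximizing covariance between the scaled
#' predictor matrix and the scaled response. Per component `a`: the weight
#' vector `w_a` is proportional to `X_a' y_a` (unit norm, sign fixed so its
#' largest-magnitude element is positive), scores `t_a = X_a w_a`, loadings
#' `p_a = X_a' t_a / t_a' t_a`, `q_a = y_a' t_a / t_a' t_a`, followed by
#' deflation of both blocks. Regression coefficients on the scaled data are
#' `b = W (P'W)^{-1} q`; raw-scale coefficients and intercept are also
#' returned.
#'
#' @param X samples x peaks matrix (or `peak_matrix`).
#' @param y response vector (one endpoint).
#' @param A number of components, `<= min(p, n - 1)`.
#' @param scale predictor/response scaling, as in [autoscale()]
#'   (default unit variance, the usual chemometric choice).
#' @return object of class `pls_model`: weights `W`, loadings `P`, scores
#'   `T`, y-loadings `q`, coefficients `b` (scaled) and `b_raw` plus
#'   `intercept`, per-component `R2X` and cumulative `R2Y`, `vip`, fitted
#'   values, and the scaling parameters.
#' @export
fit_pls <- function(X, y, A = 2, scale = "unit_variance") {
  if (inherits(X, "peak_matrix")) X <- X$areas
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("response has zero variance", call. = FALSE)
  if (A > min(p, n - 1)) {
    stop(sprintf("A = %d exceeds min(p, n - 1) = %d", A, min(p, n - 1)),
         call. = FALSE)
  }
  sx <- autoscale(X, scale = scale)
  sy <- autoscale(matrix(y, ncol = 1), scale = scale)
  Xs <- sx$X; ys <- drop(sy$X)
  ss_y <- sum(ys^2); ss_x <- sum(Xs^2)

  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  R2X <- R2Y <- numeric(A)
  Xa <- Xs; ya <- ys
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) {
      stop(sprintf("component %d: no covariance left to extract (reduce A)", a),
           call. = FALSE)
    }
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w   # reproducible sign
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    pp <- drop(crossprod(Xa, t)) / tt
    qq <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pp)
    ya <- ya - qq * t
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- t; q[a] <- qq
    R2X[a] <- tt * sum(pp^2) / ss_x
    R2Y[a] <- 1 - sum(ya^2) / ss_y        # cumulative
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  b_raw <- b * sy$sds[1] / sx$sds
  intercept <- sy$means[1] - sum(b_raw * sx$means)
  fitted <- drop(X %*% b_raw) + intercept
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", seq_len(A)))
  model <- structure(
    list(n_components = A, W = W, P = P, T = Tm, q = q,
         b = stats::setNames(b, colnames(X)),
         b_raw = stats::setNames(b_raw, colnames(X)),
         intercept = intercept, fitted = fitted,
         R2X = R2X, R2Y = R2Y,
         x_means = sx$means, x_sds = sx$sds,
         y_mean = sy$means[1], y_sd = sy$sds[1],
         scale = sx$scale, Q2 = NULL),
    class = "pls_model"
  )
  model$vip <- vip(model)
  model
}

#' Predict from a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata samples x peaks matrix on the raw scale.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return predicted response vector.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$n_components,
                              ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == nrow(object$W), ncomp >= 1,
            ncomp <= object$n_components)
  idx <- seq_len(ncomp)
  b <- drop(object$W[, idx, drop = FALSE] %*%
              solve(crossprod(object$P[, idx, drop = FALSE],
                              object$W[, idx, drop = FALSE]),
                    object$q[idx]))
  b_raw <- b * object$y_sd / object$x_sds
  intercept <- object$y_mean - sum(b_raw * object$x_means)
  drop(newdata %*% b_raw) + intercept
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )` with
#' `SSY_a = q_a^2 t_a' t_a`, the response variance captured by component
#' `a`. VIPs satisfy `sum_j VIP_j^2 = p`; VIP > 1 is the conventional
#' importance cut.
#'
#' @param model a fitted `pls_model`.
#' @return named numeric vector of VIP scores, one per predictor.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"), model$n_components >= 1)
  W <- model$W
  ssy <- model$q^2 * colSums(model$T^2)
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  v <- sqrt(nrow(W) * drop(wn2 %*% ssy) / sum(ssy))
  stats::setNames(v, rownames(W))
}

#' Leave-one-out Q2 of a PLS model
#'
#' For each left-out sample the model (including the scaling) is refit on
#' the remaining samples and the held-out response predicted with 1..A
#' components; `Q2(a) = 1 - PRESS(a) / SS` with `SS = sum((y - mean(y))^2)`.
#' A fold whose refit fails contributes the fold-training mean as its
#' prediction, with a warning.
#'
#' @inheritParams fit_pls
#' @return numeric vector `Q2[1..A]` (cumulative, per component count).
#' @export
loo_q2 <- function(X, y, A = 2, scale = "unit_variance") {
  if (inherits(X, "peak_matrix")) X <- X$areas
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4) stop("leave-one-out Q2 needs n >= 4", call. = FALSE)
  if (A > min(ncol(X), n - 2)) {
    stop("A too large for leave-one-out refits", call. = FALSE)
  }
  press <- numeric(A)
  for (i in seq_len(n)) {
    fold <- tryCatch(
      fit_pls(X[-i, , drop = FALSE], y[-i], A = A, scale = scale),
      error = function(e) NULL
    )
    if (is.null(fold)) {
      warning(sprintf("fold %d failed; using fold-train mean", i),
              call. = FALSE)
      press <- press + (y[i] - mean(y[-i]))^2
    } else {
      for (a in seq_len(A)) {
        pred <- predict(fold, X[i, , drop = FALSE], ncomp = a)
        press[a] <- press[a] + (y[i] - pred)^2
      }
    }
  }
  ss <- sum((y - mean(y))^2)
  1 - press / ss
}

#' Choose the number of PLS components
#'
#' Deterministic component-count rules on the leave-one-out Q2 curve:
#' `"max_q2"` picks the count maximizing Q2; `"q2_gain"` adds components
#' while the Q2 increment exceeds a threshold (default 0.0975, the
#' conventional cross-validation gain rule); `"fixed"` returns `fixed_A`.
#' The result is never below 1.
#'
#' @inheritParams fit_pls
#' @param rule `"max_q2"`, `"q2_gain"` or `"fixed"`.
#' @param threshold Q2 gain threshold for `"q2_gain"`.
#' @param A_max maximal component count examined.
#' @param fixed_A the count returned under `"fixed"`.
#' @return list with `A` (chosen count) and `q2` (the Q2 curve examined;
#'   NULL for `"fixed"`).
#' @export
select_components <- function(X, y, rule = c("max_q2", "q2_gain", "fixed"),
                              threshold = 0.0975, A_max = NULL,
                              fixed_A = 2, scale = "unit_variance") {
  rule <- match.arg(rule)
  if (rule == "fixed") return(list(A = max(1L, as.integer(fixed_A)), q2 = NULL))
  if (inherits(X, "peak_matrix")) X <- X$areas
  if (is.null(A_max)) A_max <- min(ncol(X), nrow(X) - 2, 5)
  q2 <- loo_q2(X, y, A = A_max, scale = scale)
  list(A = q2_rule(q2, rule, threshold), q2 = q2)
}

#' Apply a component-count rule to a Q2 curve
#'
#' @param q2 cross-validated Q2 per component count.
#' @param rule `"max_q2"` or `"q2_gain"` (see [select_components()]).
#' @param threshold gain threshold for `"q2_gain"`.
#' @return integer component count (>= 1).
#' @export
q2_rule <- function(q2, rule = c("max_q2", "q2_gain"), threshold = 0.0975) {
  rule <- match.arg(rule)
  A <- if (rule == "max_q2") {
    which.max(q2)
  } else {
    a <- 1L
    while (a < length(q2) && (q2[a + 1] - q2[a]) > threshold) a <- a + 1L
    a
  }
  max(1L, as.integer(A))
}

#' Fit one PLS model per activity endpoint
#'
#' Convenience wrapper producing the model list the screening stage
#' consumes. Each endpoint is fit as a single-response model on the
#' normalized peak matrix; endpoints tagged `lower_is_active` (IC50) are
#' negated before fitting so that activity always loads positive, making
#' coefficient signs comparable across endpoints. Samples missing an
#' endpoint are dropped from that endpoint's fit.
#'
#' @param X a normalized `peak_matrix` (or samples x peaks matrix).
#' @param activity an `activity_table`.
#' @param A components per model (an integer, or `"auto"` for the Q2-gain
#'   rule).
#' @param orient_active negate `lower_is_active` endpoints (default TRUE).
#' @param compute_q2 attach the leave-one-out Q2 curve to each model.
#' @inheritParams fit_pls
#' @return named list of `pls_model` objects, one per endpoint.
#' @export
fit_endpoint_models <- function(X, activity, A = 2, scale = "unit_variance",
                                orient_active = TRUE, compute_q2 = FALSE) {
  M <- if (inherits(X, "peak_matrix")) X$areas else as.matrix(X)
  stopifnot(inherits(activity, "activity_table"))
  out <- list()
  for (e in colnames(activity$values)) {
    yv <- activity$values[, e]
    keep <- !is.na(yv)
    ids <- rownames(activity$values)[keep]
    rows <- if (!is.null(rownames(M))) ids else which(keep)
    y <- yv[keep]
    if (orient_active && activity$direction[[e]] == "lower_is_active") {
      y <- -y
    }
    Ae <- if (identical(A, "auto")) {
      select_components(M[rows, , drop = FALSE], y, rule = "q2_gain",
                        scale = scale)$A
    } else A
    m <- fit_pls(M[rows, , drop = FALSE], y, A = Ae, scale = scale)
    m$endpoint <- e
    if (compute_q2) {
      m$Q2 <- loo_q2(M[rows, , drop = FALSE], y, A = Ae, scale = scale)
    }
    out[[e]] <- m
  }
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model%s: %d predictors, A = %d, R2Y = %.3f%s\n",
              if (!is.null(x$endpoint)) sprintf(" [%s]", x$endpoint) else "",
              nrow(x$W), x$n_components, x$R2Y[x$n_components],
              if (!is.null(x$Q2))
                sprintf(", Q2 = %.3f", x$Q2[length(x$Q2)]) else ""))
  invisible(x)
}
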