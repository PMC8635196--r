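# Two-class PLS-DA written from first principles: PLS1 latent-variable
# regression (NIPALS with X- and y-deflation) on a 1/0 dummy response, an
# LDA-derived decision threshold on the training predictions, canonical
# scores, regression coefficients and VIP variable importance.

# NIPALS PLS1 on a centred/scaled X and centred y. With a single response
# the inner NIPALS iteration is exact (no convergence loop is needed): each
# component's weight vector is proportional to X'y of the deflated data.
.pls1_nipals <- function(X, y, n_lv, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  tt <- numeric(n_lv)
  Xd <- X
  yd <- y
  a_done <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    t <- Xd %*% w
    t2 <- sum(t^2)
    if (t2 < tol) break
    W[, a] <- w
    P[, a] <- crossprod(Xd, t) / t2
    q[a] <- sum(yd * t) / t2
    tt[a] <- t2
    Xd <- Xd - t %*% t(P[, a])
    yd <- yd - t * q[a]
    a_done <- a
  }
  if (a_done == 0L) {
    abort("degenerate fit: X carries no covariance with the response")
  }
  idx <- seq_len(a_done)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       q = q[idx], tt = tt[idx], n_lv = a_done)
}

# Regression coefficients (scaled X space) of the first `a` components.
.pls1_coef <- function(fit, a = fit$n_lv) {
  Wa <- fit$W[, seq_len(a), drop = FALSE]
  Pa <- fit$P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), fit$q[seq_len(a)]))
}

# Coerce a two-class label vector to the 1/0 dummy coding; the first factor
# level (or first unique value) is class 1, coded 1.
.dummy_response <- function(y, classes = NULL) {
  if (is.null(classes)) {
    classes <- if (is.factor(y)) levels(droplevels(y)) else unique(as.character(y))
  }
  y <- as.character(y)
  if (length(classes) != 2) abort("exactly two classes are required")
  if (!all(y %in% classes)) abort("labels outside the declared classes")
  y01 <- ifelse(y == classes[1], 1, 0)
  if (all(y01 == 1) || all(y01 == 0)) {
    abort("both classes must be present (zero-variance dummy response)")
  }
  list(y01 = y01, classes = classes)
}

#' LDA-derived decision threshold on predicted responses
#'
#' One-dimensional linear discriminant boundary between the two classes'
#' predicted responses. With class means `m1` (class 1, coded 1) and `m2`,
#' pooled within-class variance `s2` and priors `pi1`, `pi2` (the training
#' class frequencies, or equal if requested), the threshold is
#' `(m1 + m2) / 2 + s2 * log(pi2 / pi1) / (m1 - m2)`: the crossing point of
#' the two equal-variance Gaussian class densities weighted by the priors.
#' With equal class sizes it reduces to the midpoint of the class means.
#'
#' @param yhat Numeric vector of predicted responses on the training set.
#' @param labels Two-class label vector aligned with `yhat` (first
#'   level/value = class 1) or a 1/0 numeric dummy vector.
#' @param equal_priors If `TRUE` use equal priors instead of the training
#'   class frequencies.
#' @return The scalar threshold: predict class 1 when `yhat > threshold`.
#' @examples
#' lda_threshold(c(0.9, 0.7, 0.3, 0.1), c(1, 1, 0, 0)) # 0.5
#' @export
lda_threshold <- function(yhat, labels, equal_priors = FALSE) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    y01 <- labels
  } else {
    y01 <- .dummy_response(labels)$y01
  }
  stopifnot(length(yhat) == length(y01))
  m1 <- mean(yhat[y01 == 1])
  m2 <- mean(yhat[y01 == 0])
  if (m1 == m2) {
    abort("degenerate separation: the class means of yhat coincide")
  }
  n1 <- sum(y01 == 1)
  n2 <- sum(y01 == 0)
  s2 <- (sum((yhat[y01 == 1] - m1)^2) + sum((yhat[y01 == 0] - m2)^2)) /
    (n1 + n2 - 2)
  if (equal_priors) {
    pi1 <- 0.5
    pi2 <- 0.5
  } else {
    pi1 <- n1 / (n1 + n2)
    pi2 <- n2 / (n1 + n2)
  }
  (m1 + m2) / 2 + s2 * log(pi2 / pi1) / (m1 - m2)
}

#' Fit a two-class PLS-DA model
#'
#' Autoscales the predictors (training rows only), codes the classes as a
#' 1/0 dummy response (first level = class 1, coded 1), fits a PLS1 model by
#' NIPALS with X- and y-deflation, and derives the decision threshold by
#' one-dimensional LDA on the training predictions ([lda_threshold()]).
#' Regression coefficients are reported in the autoscaled space so their
#' signs and sizes are comparable across elements.
#'
#' @param x Wide analysis tibble (`sample_id` plus element columns) or a
#'   numeric matrix of predictors.
#' @param y Two-class label vector (factor, character or logical); the first
#'   level is class 1.
#' @param n_lv Number of latent variables (>= 1 and at most
#'   `min(n - 1, p)`).
#' @param scale If `TRUE` (default) autoscale `x`; set `FALSE` only if `x`
#'   is already scaled.
#' @param equal_priors Passed to [lda_threshold()].
#' @return An object of class `plsda`.
#' @export
fit_plsda <- function(x, y, n_lv = 2, scale = TRUE, equal_priors = FALSE) {
  X <- .as_feature_matrix(x)
  dr <- .dummy_response(y)
  stopifnot(nrow(X) == length(dr$y01))
  max_rank <- min(nrow(X) - 1L, ncol(X))
  if (n_lv < 1 || n_lv > max_rank) {
    abort(sprintf("n_lv must be in [1, %d] for %d samples x %d predictors",
                  max_rank, nrow(X), ncol(X)))
  }
  scaling <- NULL
  if (scale) {
    scaling <- fit_autoscale(X)
    Xs <- apply_autoscale(X, scaling)
  } else {
    Xs <- X
  }
  y_mean <- mean(dr$y01)
  fit <- .pls1_nipals(Xs, dr$y01 - y_mean, n_lv)
  b <- .pls1_coef(fit)
  yhat <- drop(Xs %*% b) + y_mean
  threshold <- lda_threshold(yhat, dr$y01, equal_priors = equal_priors)
  structure(
    list(
      elements = colnames(X), classes = dr$classes, n_lv = fit$n_lv,
      weights = fit$W, x_loadings = fit$P, y_loadings = fit$q,
      t_sumsq = fit$tt, coefficients = b, scaling = scaling,
      y_mean = y_mean, threshold = threshold, yhat_train = yhat,
      labels_train = dr$y01, equal_priors = equal_priors
    ),
    class = "plsda"
  )
}

#' Predict from a PLS-DA model
#'
#' @param object A fitted `plsda` model.
#' @param newdata Wide tibble or matrix holding the model's element columns.
#' @param type `"response"` for the predicted dummy response,
#'   `"score"` for the canonical-variate score (response re-centred at the
#'   threshold), `"class"` for hard labels: class 1 iff the response is
#'   strictly greater than the threshold (a tie goes to class 2).
#' @param ... Unused.
#' @return Numeric vector (`response`/`score`) or factor (`class`).
#' @export
predict.plsda <- function(object, newdata,
                          type = c("response", "score", "class"), ...) {
  type <- match.arg(type)
  X <- .as_feature_matrix(newdata)
  if (!is.null(object$scaling)) {
    Xs <- apply_autoscale(X, object$scaling)
  } else {
    missing <- setdiff(object$elements, colnames(X))
    if (length(missing) > 0) {
      abort(paste0("newdata lacks element(s): ",
                   paste(missing, collapse = ", ")))
    }
    Xs <- X[, object$elements, drop = FALSE]
  }
  yhat <- drop(Xs %*% object$coefficients) + object$y_mean
  switch(type,
    response = yhat,
    score = yhat - object$threshold,
    class = factor(ifelse(yhat > object$threshold,
                          object$classes[1], object$classes[2]),
                   levels = object$classes)
  )
}

#' Classify samples with a fitted PLS-DA model
#'
#' Hard class assignment: class 1 when the predicted response strictly
#' exceeds the LDA threshold, class 2 otherwise (including an exact tie).
#'
#' @inheritParams predict.plsda
#' @return Factor of predicted class labels.
#' @export
classify <- function(object, newdata) {
  stopifnot(inherits(object, "plsda"))
  predict(object, newdata, type = "class")
}

#' Canonical-variate scores
#'
#' The single canonical variate of a two-class PLS-DA model: the predicted
#' response re-centred at the decision threshold, so class-1 samples tend to
#' positive scores and class-2 samples to negative ones, and `score > 0` is
#' exactly the class-1 prediction rule.
#'
#' @inheritParams predict.plsda
#' @return Numeric vector of scores.
#' @export
canonical_scores <- function(object, newdata) {
  stopifnot(inherits(object, "plsda"))
  predict(object, newdata, type = "score")
}

#' VIP (variable importance in projection) scores
#'
#' `VIP_j = sqrt(p * sum_a ssy_a * w_ja^2 / sum_a ssy_a)` with unit-norm
#' weight vectors `w_a` and `ssy_a` the response variance explained by
#' component `a`; consequently the mean of the squared VIPs over the `p`
#' variables is exactly 1.
#'
#' @param object A fitted `plsda` model.
#' @return Named numeric vector of VIP scores (one per element).
#' @export
vip <- function(object) {
  stopifnot(inherits(object, "plsda"))
  ssy <- object$y_loadings^2 * object$t_sumsq
  if (sum(ssy) <= 0) abort("model explains no response variance")
  p <- length(object$elements)
  w2 <- object$weights^2
  scores <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  setNames(scores, object$elements)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf(
    "<plsda> %s vs %s: %d latent variable(s), %d element(s), threshold %.4f\n",
    x$classes[1], x$classes[2], x$n_lv, length(x$elements), x$threshold
  ))
  invisible(x)
}

#' Tidy a PLS-DA model
#'
#' @param x A fitted `plsda` model.
#' @param ... Unused.
#' @return A tibble with one row per element: autoscaled-space regression
#'   `coefficient` and `vip` score.
#' @export
tidy.plsda <- function(x, ...) {
  tibble::tibble(
    term = x$elements,
    coefficient = unname(x$coefficients),
    vip = unname(vip(x))
  )
}

#' One-row summary of a PLS-DA model
#'
#' @param x A fitted `plsda` model.
#' @param ... Unused.
#' @return A one-row tibble: classes, number of latent variables, threshold,
#'   training accuracy (%).
#' @export
glance.plsda <- function(x, ...) {
  pred_class1 <- x$yhat_train > x$threshold
  acc <- 100 * mean(pred_class1 == (x$labels_train == 1))
  tibble::tibble(
    class1 = x$classes[1], class2 = x$classes[2],
    n_lv = x$n_lv, threshold = x$threshold,
    train_accuracy = acc
  )
}
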