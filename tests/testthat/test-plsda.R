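test_that("PLS1 with one predictor reduces to simple regression", {
  set.seed(1)
  x <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "e"))
  y <- factor(rep(c("A", "B"), 6))
  m <- fit_plsda(x, y, n_lv = 1)
  y01 <- ifelse(y == "A", 1, 0)
  xs <- drop(scale(x))
  b_uni <- sum(xs * (y01 - mean(y01))) / sum(xs^2)
  expect_equal(unname(m$coefficients), b_uni, tolerance = 1e-12)
  expect_equal(unname(vip(m)), 1)   # p = 1 normalisation
})

test_that("full-rank PLS1 equals the least-squares solution", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(8:15, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("e", seq_len(p))))
    y <- factor(rep_len(c("A", "B"), n))
    m <- fit_plsda(X, y, n_lv = p)
    y01 <- ifelse(y == "A", 1, 0)
    Xs <- scale(X)
    expect_equal(unname(m$coefficients),
                 unname(oracle_ols(Xs, y01 - mean(y01))),
                 tolerance = 1e-8)
    # training predictions reproduce the OLS fitted values
    fit_ols <- drop(Xs %*% oracle_ols(Xs, y01 - mean(y01))) + mean(y01)
    expect_equal(unname(predict(m, X)), fit_ols, tolerance = 1e-8)
  }
})

test_that("orthonormal predictors give b = X'y up to centering", {
  # columns of an orthogonal matrix, centred by construction
  Q <- qr.Q(qr(cbind(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, -1, -1, 1))))
  colnames(Q) <- c("a", "b", "c")
  y01 <- c(1, 1, 0, 0)
  yc <- y01 - mean(y01)
  m <- fit_plsda(Q, factor(c("A", "A", "B", "B")), n_lv = 3, scale = FALSE)
  expect_equal(unname(m$coefficients), unname(drop(crossprod(Q, yc))),
               tolerance = 1e-10)
})

test_that("prediction honours centering and determinism", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("A", "B"), c(12, 8)))
  m <- fit_plsda(X, y, n_lv = 2)
  # row at the training mean profile predicts the class-1 proportion
  mu <- matrix(colMeans(X), 1, 3, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(predict(m, mu)), 12 / 20, tolerance = 1e-12)
  # duplicated rows get identical predictions
  two <- X[c(5, 5), ]
  expect_equal(predict(m, two)[1], predict(m, two)[2])
  # element-set mismatch is an error
  expect_error(predict(m, X[, 1:2, drop = FALSE]), "lacks")
})

test_that("the LDA threshold is the prior-weighted density crossing", {
  # equal class sizes: exact midpoint of the class means
  yhat <- c(0.9, 0.7, 0.3, 0.1)
  y01 <- c(1, 1, 0, 0)
  expect_equal(lda_threshold(yhat, y01), 0.5)
  # symmetric scores around zero
  yh2 <- c(-1.01, -0.99, 0.99, 1.01)
  expect_equal(lda_threshold(yh2, c(0, 0, 1, 1)), 0, tolerance = 1e-12)
  # unequal priors against the brute-force density-crossing oracle
  set.seed(4)
  for (i in 1:5) {
    n1 <- sample(10:30, 1)
    n2 <- sample(31:60, 1)
    yh <- c(rnorm(n1, 0.8, 0.15), rnorm(n2, 0.2, 0.15))
    lab <- c(rep(1, n1), rep(0, n2))
    thr <- lda_threshold(yh, lab)
    thr_oracle <- oracle_lda_threshold(yh, lab)
    expect_equal(thr, thr_oracle, tolerance = 1e-3)
  }
  expect_error(lda_threshold(c(1, 1, 1, 1), c(1, 1, 0, 0)), "degenerate")
})

test_that("classification is strict at the threshold with ties to class 2", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  X[1:10, 1] <- X[1:10, 1] + 6
  y <- factor(rep(c("up", "down"), each = 10))
  m <- fit_plsda(X, y, n_lv = 2)
  # separable training data classify perfectly
  expect_equal(as.character(classify(m, X)), as.character(y))
  # scores and hard labels are sign-consistent: score > 0 <=> class 1
  scores <- canonical_scores(m, X)
  expect_true(all((scores > 0) == (classify(m, X) == m$classes[1])))

  # exact tie at the threshold goes to class 2; epsilon above to class 1
  unit <- structure(
    list(elements = "e", classes = c("one", "two"),
         coefficients = c(e = 1), scaling = NULL, y_mean = 0,
         threshold = 0.25),
    class = "plsda")
  at <- matrix(0.25, 1, 1, dimnames = list(NULL, "e"))
  above <- matrix(0.25 + 1e-9, 1, 1, dimnames = list(NULL, "e"))
  expect_equal(as.character(classify(unit, at)), "two")
  expect_equal(as.character(classify(unit, above)), "one")
})

test_that("swapping class labels flips scores and preserves classification", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  X[1:15, 1] <- X[1:15, 1] + 2
  y1 <- factor(rep(c("A", "B"), each = 15), levels = c("A", "B"))
  y2 <- factor(y1, levels = c("B", "A"))   # swapped coding
  m1 <- fit_plsda(X, y1, n_lv = 2)
  m2 <- fit_plsda(X, y2, n_lv = 2)
  s1 <- canonical_scores(m1, X)
  s2 <- canonical_scores(m2, X)
  expect_equal(s1, -s2, tolerance = 1e-10)
  expect_equal(as.character(classify(m1, X)), as.character(classify(m2, X)))
})

test_that("training-set order does not change the model", {
  set.seed(7)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("e", 1:4)))
  y <- factor(rep(c("A", "B"), each = 10))
  perm <- sample(20)
  m1 <- fit_plsda(X, y, n_lv = 3)
  m2 <- fit_plsda(X[perm, ], y[perm], n_lv = 3)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
  expect_equal(m1$threshold, m2$threshold, tolerance = 1e-10)
})

test_that("VIP scores obey the normalisation identity and the direct formula", {
  set.seed(8)
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(NULL, paste0("e", 1:6)))
    y <- factor(rep(c("A", "B"), each = 10))
    m <- fit_plsda(X, y, n_lv = sample(1:4, 1))
    expect_equal(mean(vip(m)^2), 1, tolerance = 1e-10)
  }
  # two-variable model against a hand evaluation of the formula
  X <- matrix(c(1, 2, 3, 4, 1, 1, 2, 2), 4, 2,
              dimnames = list(NULL, c("u", "v")))
  y <- factor(c("A", "A", "B", "B"))
  m2 <- fit_plsda(X, y, n_lv = 2)
  ssy <- m2$y_loadings^2 * m2$t_sumsq
  w2 <- m2$weights^2
  by_hand <- sqrt(2 * drop(w2 %*% ssy) / sum(ssy))
  expect_equal(unname(vip(m2)), by_hand, tolerance = 1e-10)
})

test_that("explained response variance is non-decreasing in model size", {
  set.seed(9)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("e", 1:6)))
  y <- factor(rep(c("A", "B"), each = 15))
  y01 <- ifelse(y == "A", 1, 0)
  sse <- sapply(1:5, function(a) {
    m <- fit_plsda(X, y, n_lv = a)
    sum((predict(m, X) - y01)^2)
  })
  expect_true(all(diff(sse) <= 1e-10))
})

test_that("tidy and glance summarise the fitted model", {
  set.seed(10)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  X[1:10, 1] <- X[1:10, 1] + 5
  y <- factor(rep(c("A", "B"), each = 10))
  m <- fit_plsda(X, y, n_lv = 2)
  td <- tidy(m)
  expect_named(td, c("term", "coefficient", "vip"))
  expect_equal(td$term, c("a", "b"))
  g <- glance(m)
  expect_equal(g$train_accuracy, 100)
  expect_equal(g$n_lv, 2)
  # invalid sizes are refused
  expect_error(fit_plsda(X, y, n_lv = 25), "n_lv")
  expect_error(fit_plsda(X, factor(rep("A", 20))), "two classes|classes")
})
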