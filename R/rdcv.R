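# Repeated double cross-validation (rDCV) around the PLS-DA core: a
# stratified inner loop selects the number of latent variables, a stratified
# outer loop mimics an external test set, and the whole procedure is
# repeated over many random splits so that empirical confidence intervals
# can be attached to figures of merit, per-sample canonical scores, and
# model parameters (coefficients, VIP).

#' rDCV configuration
#'
#' @param n_runs Number of repetitions (random re-splits); default 50.
#' @param n_outer Outer-loop cancelation groups (folds); default 10.
#' @param n_inner Inner-loop cancelation groups; default 5.
#' @param max_lv Largest number of latent variables searched by the inner
#'   loop; `NULL` (default) means `min(10, rank bound)` at fit time.
#' @param stratified Stratify fold assignment by class (default `TRUE`), so
#'   both classes reach every training fold even when strongly unbalanced.
#' @param equal_priors Use equal LDA priors instead of training frequencies.
#' @param seed Integer seed; splits are fully determined by `(seed, run)`.
#' @return A list of class `rdcv_config`.
#' @export
rdcv_config <- function(n_runs = 50, n_outer = 10, n_inner = 5,
                        max_lv = NULL, stratified = TRUE,
                        equal_priors = FALSE, seed = 1L) {
  if (n_outer < 2) abort("n_outer must be >= 2")
  if (n_inner < 2) abort("n_inner must be >= 2")
  if (n_runs < 1) abort("n_runs must be >= 1")
  if (!is.null(max_lv) && max_lv < 1) abort("max_lv must be >= 1")
  structure(
    list(n_runs = as.integer(n_runs), n_outer = as.integer(n_outer),
         n_inner = as.integer(n_inner), max_lv = max_lv,
         stratified = isTRUE(stratified), equal_priors = isTRUE(equal_priors),
         seed = as.integer(seed)),
    class = "rdcv_config"
  )
}

# Fold assignment: per class, near-equal fold sizes in random order.
.fold_assignment <- function(labels, k, stratified) {
  n <- length(labels)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        abort(sprintf(
          paste0("class '%s' has %d sample(s), fewer than the %d folds; ",
                 "reduce the number of cancelation groups or disable ",
                 "stratification"),
          cl, length(idx), k))
      }
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  folds
}

#' Nested fold assignments for repeated double cross-validation
#'
#' For each run, draws a stratified random partition of the samples into
#' `n_outer` outer folds and, for each outer fold, a stratified partition of
#' the remaining (outer-training) samples into `n_inner` inner folds. The
#' assignments are fully determined by `(config$seed, run index)`.
#'
#' @param labels Two-class label vector.
#' @param config An [rdcv_config()].
#' @return A list with one element per run: `list(outer = <fold id per
#'   sample>, inner = <list per outer fold: fold id per outer-training
#'   sample, named by sample index>)`.
#' @export
make_splits <- function(labels, config = rdcv_config()) {
  labels <- as.character(labels)
  lapply(seq_len(config$n_runs), function(r) {
    set.seed(.substream_seed(config$seed, paste0("rdcv-run:", r)))
    outer <- .fold_assignment(labels, config$n_outer, config$stratified)
    inner <- lapply(seq_len(config$n_outer), function(j) {
      train_idx <- which(outer != j)
      fa <- .fold_assignment(labels[train_idx], config$n_inner,
                             config$stratified)
      names(fa) <- train_idx
      fa
    })
    list(outer = outer, inner = inner)
  })
}

# Fit PLS1 on scaled training data and return coefficient matrix (p x A),
# training predictions per component count, and the NIPALS pieces.
.pls1_path <- function(Xtr, y01, max_lv) {
  sds <- apply(Xtr, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant column(s) in training fold: ",
                 paste(colnames(Xtr)[sds == 0], collapse = ", ")))
  }
  ctr <- colMeans(Xtr)
  Xs <- scale(Xtr, ctr, sds)
  y_mean <- mean(y01)
  A_cap <- min(max_lv, nrow(Xtr) - 1L, ncol(Xtr))
  fit <- .pls1_nipals(Xs, y01 - y_mean, A_cap)
  B <- vapply(seq_len(fit$n_lv), function(a) .pls1_coef(fit, a),
              numeric(ncol(Xtr)))
  list(fit = fit, B = B, center = ctr, scale = sds, y_mean = y_mean,
       yhat_train = Xs %*% B + y_mean)
}

# Inner-loop selection of the number of latent variables: minimise the
# pooled inner-CV misclassification count, ties broken toward fewer
# components. The decision threshold is re-derived per inner fold by LDA on
# that fold's training predictions.
.select_n_lv <- function(X, y01, inner_folds, max_lv, equal_priors) {
  k <- max(inner_folds)
  A_avail <- max_lv
  errs <- NULL
  fold_err <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- inner_folds != f
    path <- .pls1_path(X[tr, , drop = FALSE], y01[tr], max_lv)
    A_avail <- min(A_avail, path$fit$n_lv)
    Xval <- scale(X[!tr, , drop = FALSE], path$center, path$scale)
    Yhat_val <- Xval %*% path$B + path$y_mean
    e <- vapply(seq_len(path$fit$n_lv), function(a) {
      thr <- lda_threshold(path$yhat_train[, a], y01[tr],
                           equal_priors = equal_priors)
      pred1 <- Yhat_val[, a] > thr
      sum(pred1 != (y01[!tr] == 1))
    }, numeric(1))
    fold_err[[f]] <- e
  }
  errs <- rowSums(vapply(fold_err, function(e) e[seq_len(A_avail)],
                         numeric(A_avail)))
  which.min(errs) # ties -> smallest index, i.e. fewest components
}

#' Select the number of latent variables by inner cross-validation
#'
#' Standalone access to the rDCV inner loop: stratified `n_inner`-fold CV of
#' the misclassification rate for each candidate number of latent variables
#' (1 to `max_lv`), with the LDA threshold re-derived inside every fold.
#' The minimiser is returned, ties broken toward fewer components.
#'
#' @param x Wide analysis tibble or numeric predictor matrix.
#' @param y Two-class label vector (first level = class 1).
#' @param config An [rdcv_config()]; `n_inner`, `max_lv`, `stratified`,
#'   `equal_priors` and `seed` are used.
#' @return The chosen number of latent variables (integer).
#' @export
select_n_lv <- function(x, y, config = rdcv_config()) {
  X <- .as_feature_matrix(x)
  dr <- .dummy_response(y)
  set.seed(.substream_seed(config$seed, "select-n-lv"))
  folds <- .fold_assignment(as.character(y), config$n_inner,
                            config$stratified)
  max_lv <- min(config$max_lv %||% 10L, nrow(X) - 1L, ncol(X))
  if (max_lv == 1L) return(1L)
  .select_n_lv(X, dr$y01, folds, max_lv, config$equal_priors)
}

#' Classification figures of merit
#'
#' Accuracy (% correctly classified over all samples), per-class
#' sensitivities (% correct within each class) and the mean correct
#' classification rate (the unweighted average of the two sensitivities,
#' robust to class unbalance; for balanced classes it equals the accuracy).
#' In a two-class discriminant model one class's sensitivity is the other's
#' specificity.
#'
#' @param predicted,actual Equal-length label vectors.
#' @param classes Optional length-2 class order (class 1 first); defaults to
#'   the factor levels / unique values of `actual`.
#' @return One-row tibble: `accuracy`, `mean_ccr`, `sensitivity1`,
#'   `sensitivity2` (all percentages), `class1`, `class2`.
#' @examples
#' figures_of_merit(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
#'                  classes = c("a", "b"))
#' @export
figures_of_merit <- function(predicted, actual, classes = NULL) {
  if (is.null(classes)) {
    classes <- if (is.factor(actual)) levels(droplevels(actual))
               else unique(as.character(actual))
  }
  predicted <- as.character(predicted)
  actual <- as.character(actual)
  stopifnot(length(predicted) == length(actual))
  if (!all(classes %in% actual)) {
    abort("both classes must appear in `actual`")
  }
  correct <- predicted == actual
  sens <- vapply(classes, function(cl) {
    100 * mean(correct[actual == cl])
  }, numeric(1))
  tibble::tibble(
    accuracy = 100 * mean(correct),
    mean_ccr = mean(sens),
    sensitivity1 = sens[[1]], sensitivity2 = sens[[2]],
    class1 = classes[1], class2 = classes[2]
  )
}

#' Run repeated double cross-validation for a two-class PLS-DA model
#'
#' For every run and outer fold: autoscaling is fitted on the outer-training
#' rows only; the number of latent variables is chosen by the stratified
#' inner loop ([select_n_lv()] logic); the PLS-DA model (including its LDA
#' threshold) is refitted on the full outer-training set; and the held-out
#' samples are predicted. Per-run figures of merit are computed from the
#' union of the outer-fold predictions, so every sample is predicted exactly
#' once per run. Coefficient and VIP distributions pool the models of all
#' runs x outer folds.
#'
#' The input table should already be imputed, replicate-averaged and
#' detection-filtered on the two-class subset: the element panel must be
#' constant across folds for the parameter distributions to be comparable.
#'
#' @param x Wide analysis tibble (`sample_id` plus element columns) or
#'   numeric matrix, rows restricted to the two classes being compared.
#' @param y Two-class label vector (first level = class 1).
#' @param config An [rdcv_config()].
#' @return An object of class `rdcv_result`: per-run figures of merit
#'   (`per_run`), per-sample outer-loop predictions and canonical scores for
#'   every run (`predictions`), model-parameter draws (`coefficients`,
#'   `vips`, `n_lv` per run x fold), the class coding and the configuration.
#' @export
run_rdcv <- function(x, y, config = rdcv_config()) {
  X <- .as_feature_matrix(x)
  sample_ids <- rownames(X) %||% sprintf("row%d", seq_len(nrow(X)))
  dr <- .dummy_response(y)
  y01 <- dr$y01
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(n == length(y01))
  max_lv <- min(config$max_lv %||% 10L, p)
  splits <- make_splits(as.character(y), config)

  n_models <- config$n_runs * config$n_outer
  coef_mat <- matrix(NA_real_, n_models, p, dimnames = list(NULL, colnames(X)))
  vip_mat <- matrix(NA_real_, n_models, p, dimnames = list(NULL, colnames(X)))
  model_run <- integer(n_models)
  model_fold <- integer(n_models)
  model_nlv <- integer(n_models)
  per_run <- vector("list", config$n_runs)
  preds <- vector("list", config$n_runs)

  m <- 0L
  for (r in seq_len(config$n_runs)) {
    outer <- splits[[r]]$outer
    yhat <- numeric(n)
    score <- numeric(n)
    fold_of <- integer(n)
    for (j in seq_len(config$n_outer)) {
      m <- m + 1L
      res <- tryCatch({
        tr <- outer != j
        te <- which(!tr)
        inner <- splits[[r]]$inner[[j]]
        a_star <- if (max_lv == 1L) 1L else {
          .select_n_lv(X[tr, , drop = FALSE], y01[tr], inner, max_lv,
                       config$equal_priors)
        }
        path <- .pls1_path(X[tr, , drop = FALSE], y01[tr], a_star)
        a_fit <- min(a_star, path$fit$n_lv)
        b <- path$B[, a_fit]
        thr <- lda_threshold(path$yhat_train[, a_fit], y01[tr],
                             equal_priors = config$equal_priors)
        Xte <- scale(X[te, , drop = FALSE], path$center, path$scale)
        yh <- drop(Xte %*% b) + path$y_mean
        ssy <- path$fit$q^2 * path$fit$tt
        w2 <- path$fit$W^2
        list(te = te, yh = yh, thr = thr, b = b, a = a_fit,
             vip = sqrt(p * drop(w2[, seq_len(a_fit), drop = FALSE] %*%
                                   ssy[seq_len(a_fit)]) /
                          sum(ssy[seq_len(a_fit)])))
      }, error = function(e) {
        abort(sprintf("run %d, outer fold %d: %s", r, j,
                      conditionMessage(e)))
      })
      yhat[res$te] <- res$yh
      score[res$te] <- res$yh - res$thr
      fold_of[res$te] <- j
      coef_mat[m, ] <- res$b
      vip_mat[m, ] <- res$vip
      model_run[m] <- r
      model_fold[m] <- j
      model_nlv[m] <- res$a
    }
    predicted <- ifelse(score > 0, dr$classes[1], dr$classes[2])
    fom <- figures_of_merit(predicted, as.character(y), classes = dr$classes)
    per_run[[r]] <- dplyr::bind_cols(tibble::tibble(run = r),
                                     fom[, 1:4])
    preds[[r]] <- tibble::tibble(
      run = r, fold = fold_of, sample_id = sample_ids,
      actual = as.character(y), yhat = yhat, score = score,
      predicted = predicted
    )
  }

  structure(
    list(
      per_run = dplyr::bind_rows(per_run),
      predictions = dplyr::bind_rows(preds),
      coefficients = coef_mat, vips = vip_mat,
      models = tibble::tibble(run = model_run, fold = model_fold,
                              n_lv = model_nlv),
      classes = dr$classes, elements = colnames(X), config = config,
      sample_ids = sample_ids
    ),
    class = "rdcv_result"
  )
}

#' Variables contributing significantly to the discrimination
#'
#' Identifies the elements whose autoscaled regression coefficient is
#' reliably nonzero across the rDCV models, with the sign giving the
#' direction: a positive coefficient means the element tends to be higher
#' in class 1 (coded 1).
#'
#' The default interval (`method = "jackknife"`) treats each run's outer
#' folds as delete-d jackknife replicates: the per-run grouped jackknife
#' variance `(k-1)/k * sum_j (b_j - mean(b))^2` (k = `n_outer`) estimates
#' the sampling variance of the coefficient, and the run-wise estimates are
#' averaged. This matters because the raw spread of the fold models
#' understates sampling variability by roughly `sqrt(k-1)` — the fold models
#' share ~90% of their training data — so percentile intervals of the pooled
#' model distribution (`method = "percentile"`, kept for descriptive use)
#' flag many spurious variables. The jackknife interval level is
#' Bonferroni-shared across the element panel when `adjust = "panel"`
#' (default), controlling the family-wise false-flag rate, and a flagged
#' variable must additionally carry a mean VIP score above 1 (the standard
#' VIP relevance rule) when `vip_rule = TRUE`.
#'
#' @param result An `rdcv_result`.
#' @param level Interval coverage; default 0.95.
#' @param method `"jackknife"` (calibrated, default) or `"percentile"`
#'   (raw 2.5/97.5 percentiles of the pooled run x fold models).
#' @param adjust `"panel"` (Bonferroni across the elements, default) or
#'   `"none"`.
#' @param vip_rule Additionally require a mean VIP score > 1; default
#'   `TRUE`.
#' @return A tibble per element: mean `estimate`, `lower`, `upper`,
#'   `significant`, `higher_in` (class label implied by the sign), and the
#'   mean VIP score.
#' @export
significant_variables <- function(result, level = 0.95,
                                  method = c("jackknife", "percentile"),
                                  adjust = c("panel", "none"),
                                  vip_rule = TRUE) {
  stopifnot(inherits(result, "rdcv_result"))
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (nrow(result$coefficients) == 0) abort("empty parameter distributions")
  p <- length(result$elements)
  alpha <- (1 - level) / 2
  if (adjust == "panel") alpha <- alpha / p
  est <- colMeans(result$coefficients)
  if (method == "jackknife") {
    k <- result$config$n_outer
    runs <- result$models$run
    v_runs <- vapply(unique(runs), function(r) {
      B <- result$coefficients[runs == r, , drop = FALSE]
      (k - 1) / k * colSums(sweep(B, 2, colMeans(B))^2)
    }, numeric(p))
    half <- qnorm(1 - alpha) * sqrt(rowMeans(v_runs))
    lo <- est - half
    hi <- est + half
  } else {
    lo <- apply(result$coefficients, 2, quantile, probs = alpha)
    hi <- apply(result$coefficients, 2, quantile, probs = 1 - alpha)
  }
  vip_mean <- colMeans(result$vips)
  sig <- ((lo > 0 & hi > 0) | (lo < 0 & hi < 0))
  if (vip_rule) sig <- sig & vip_mean > 1
  tibble::tibble(
    term = result$elements,
    estimate = unname(est), lower = unname(lo), upper = unname(hi),
    significant = unname(sig),
    higher_in = ifelse(est > 0, result$classes[1], result$classes[2]),
    vip_mean = unname(vip_mean)
  )
}

#' Per-sample canonical-score summaries for plotting
#'
#' For every sample: the mean canonical-variate score over the rDCV runs and
#' its empirical 95% interval (2.5 and 97.5 percentiles of the run-wise
#' scores), ordered by class and mean score — the data behind the classic
#' per-sample score-interval plot.
#'
#' @param result An `rdcv_result`.
#' @return A tibble: `sample_id`, `class`, `mean_score`, `lower`, `upper`,
#'   plot `position`.
#' @export
score_interval_plot_data <- function(result) {
  stopifnot(inherits(result, "rdcv_result"))
  out <- dplyr::summarise(
    dplyr::group_by(result$predictions, .data$sample_id),
    class = .data$actual[1],
    mean_score = mean(.data$score),
    lower = quantile(.data$score, 0.025),
    upper = quantile(.data$score, 0.975),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$class, .data$mean_score)
  out$position <- seq_len(nrow(out))
  out
}

#' @export
print.rdcv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<rdcv_result> %s vs %s: %d runs x %d outer folds\n",
           "  accuracy %.1f +/- %.1f%%, mean CCR %.1f +/- %.1f%%\n"),
    x$classes[1], x$classes[2], x$config$n_runs, x$config$n_outer,
    g$accuracy_mean, g$accuracy_sd, g$mean_ccr_mean, g$mean_ccr_sd
  ))
  invisible(x)
}

#' Tidy an rDCV result
#'
#' @param x An `rdcv_result`.
#' @param level Interval coverage for the parameter intervals; default 0.95.
#' @param ... Unused.
#' @return The per-element parameter summary of [significant_variables()].
#' @export
tidy.rdcv_result <- function(x, level = 0.95, ...) {
  significant_variables(x, level = level)
}

#' One-row rDCV summary (figures of merit as mean +/- SD over runs)
#'
#' @param x An `rdcv_result`.
#' @param ... Unused.
#' @return A one-row tibble with mean and SD over runs of the accuracy, the
#'   mean correct classification rate and the two sensitivities, plus the
#'   modal number of latent variables.
#' @export
glance.rdcv_result <- function(x, ...) {
  pr <- x$per_run
  nlv <- x$models$n_lv
  tibble::tibble(
    class1 = x$classes[1], class2 = x$classes[2],
    n_runs = x$config$n_runs,
    accuracy_mean = mean(pr$accuracy), accuracy_sd = sd(pr$accuracy),
    mean_ccr_mean = mean(pr$mean_ccr), mean_ccr_sd = sd(pr$mean_ccr),
    sensitivity1_mean = mean(pr$sensitivity1),
    sensitivity1_sd = sd(pr$sensitivity1),
    sensitivity2_mean = mean(pr$sensitivity2),
    sensitivity2_sd = sd(pr$sensitivity2),
    n_lv_mode = as.integer(names(sort(table(nlv), decreasing = TRUE))[1])
  )
}

#' Plot an rDCV result
#'
#' `type = "scores"` draws the per-sample mean canonical scores with their
#' 95% intervals, coloured by class, with the decision boundary at zero.
#' `type = "coefficients"` draws the per-element coefficient means and
#' intervals, highlighting the significant ones.
#'
#' @param object An `rdcv_result`.
#' @param type `"scores"` or `"coefficients"`.
#' @param level Interval coverage for `type = "coefficients"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdcv_result <- function(object, type = c("scores", "coefficients"),
                                 level = 0.95, ...) {
  type <- match.arg(type)
  if (type == "scores") {
    d <- score_interval_plot_data(object)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$mean_score,
                                    colour = .data$class)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                            ymax = .data$upper),
                               size = 0.3) +
      ggplot2::labs(x = "sample", y = "canonical-variate score",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    d <- significant_variables(object, level = level)
    d <- dplyr::arrange(d, .data$estimate)
    d$term <- factor(d$term, levels = d$term)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term,
                                    colour = .data$significant)) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
      ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                            xmax = .data$upper)) +
      ggplot2::labs(x = "autoscaled regression coefficient", y = NULL,
                    colour = "significant") +
      ggplot2::theme_minimal()
  }
}
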