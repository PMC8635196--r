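test_that("fold assignments partition the samples with stratification", {
  labels <- rep(c("A", "B"), each = 20)
  cfg <- rdcv_config(n_runs = 2, n_outer = 10, n_inner = 5, seed = 3)
  sp <- make_splits(labels, cfg)
  expect_length(sp, 2)
  outer <- sp[[1]]$outer
  # each sample in exactly one fold; folds of equal size
  expect_equal(sort(unique(outer)), 1:10)
  expect_true(all(table(outer) == 4))
  # stratified 30/10 into 10 folds: 3 + 1 per fold
  sp2 <- make_splits(rep(c("A", "B"), c(30, 10)),
                     rdcv_config(n_runs = 1, seed = 5))
  tab <- table(sp2[[1]]$outer, rep(c("A", "B"), c(30, 10)))
  expect_true(all(tab[, "A"] == 3))
  expect_true(all(tab[, "B"] == 1))
  # inner folds partition each outer-training set
  inner1 <- sp[[1]]$inner[[1]]
  expect_length(inner1, 36)
  expect_setequal(as.integer(names(inner1)), which(outer != 1))
  # determinism
  sp_again <- make_splits(labels, cfg)
  expect_identical(sp, sp_again)
  # a class smaller than the fold count is refused with guidance
  expect_error(make_splits(rep(c("A", "B"), c(30, 5)),
                           rdcv_config(n_runs = 1)),
               "fewer than")
})

test_that("inner-loop selection finds a single-direction signal and breaks ties low", {
  set.seed(13)
  n <- 60
  X <- cbind(sig = rep(c(3, -3), each = n / 2) + rnorm(n, 0, 0.3),
             matrix(rnorm(n * 5, 0, 1), n, 5))
  colnames(X)[2:6] <- paste0("noise", 1:5)
  y <- factor(rep(c("A", "B"), each = n / 2))
  cfg <- rdcv_config(n_inner = 5, max_lv = 6, seed = 7)
  expect_equal(select_n_lv(X, y, cfg), 1L)
  # a single candidate needs no search
  expect_equal(select_n_lv(X, y, rdcv_config(max_lv = 1, seed = 7)), 1L)
})

test_that("figures of merit follow the counting definitions", {
  # all correct
  f <- figures_of_merit(c("a", "b"), c("a", "b"), classes = c("a", "b"))
  expect_equal(f$accuracy, 100)
  expect_equal(f$mean_ccr, 100)
  # 7/10 and 27/30 correct
  actual <- rep(c("c1", "c2"), c(10, 30))
  predicted <- c(rep("c1", 7), rep("c2", 3), rep("c2", 27), rep("c1", 3))
  f2 <- figures_of_merit(predicted, actual, classes = c("c1", "c2"))
  expect_equal(f2$sensitivity1, 70)
  expect_equal(f2$sensitivity2, 90)
  expect_equal(f2$accuracy, 85)
  expect_equal(f2$mean_ccr, 80)
  # balanced classes: accuracy equals the mean CCR exactly
  set.seed(14)
  act <- rep(c("x", "y"), each = 25)
  prd <- sample(c("x", "y"), 50, replace = TRUE)
  f3 <- figures_of_merit(prd, act, classes = c("x", "y"))
  expect_equal(f3$accuracy, f3$mean_ccr)
  expect_error(figures_of_merit(prd, rep("x", 50), classes = c("x", "y")),
               "both classes")
})

test_that("rDCV covers every sample exactly once per run and reproduces", {
  ds <- generate_dataset(small_config(n_per_class = 20, p = 8, n_shift = 2,
                                      seed = 23))
  wide <- to_wide(ds)
  y <- factor(ds$metadata$region, levels = c("class1", "class2"))
  cfg <- rdcv_config(n_runs = 3, n_outer = 5, n_inner = 3, max_lv = 4,
                     seed = 11)
  r <- run_rdcv(wide, y, cfg)
  counts <- table(r$predictions$run, r$predictions$sample_id)
  expect_true(all(counts == 1))
  # per-run aggregate equals the mean of per-run accuracies by construction
  g <- glance(r)
  expect_equal(g$accuracy_mean, mean(r$per_run$accuracy))
  expect_true(all(r$per_run$accuracy >= 0 & r$per_run$accuracy <= 100))
  expect_equal(r$per_run$mean_ccr,
               (r$per_run$sensitivity1 + r$per_run$sensitivity2) / 2)
  # identical (data, config, seed) => identical result
  r2 <- run_rdcv(wide, y, cfg)
  expect_identical(r$coefficients, r2$coefficients)
  expect_identical(r$predictions, r2$predictions)
})

test_that("held-out rows never influence the fold model (no leakage)", {
  ds <- generate_dataset(small_config(n_per_class = 15, p = 6, n_shift = 1,
                                      seed = 29))
  wide <- to_wide(ds)
  y <- factor(ds$metadata$region, levels = c("class1", "class2"))
  cfg <- rdcv_config(n_runs = 1, n_outer = 5, n_inner = 3, max_lv = 3,
                     seed = 17)
  r1 <- run_rdcv(wide, y, cfg)
  # perturb the rows held out in fold 1 of the (only) run
  sp <- make_splits(as.character(y), cfg)
  held <- which(sp[[1]]$outer == 1)
  wide_pert <- wide
  for (j in setdiff(names(wide_pert), "sample_id")) {
    wide_pert[held, j] <- wide_pert[held, j] * 7 + 100
  }
  r2 <- run_rdcv(wide_pert, y, cfg)
  m1 <- r1$models$run == 1 & r1$models$fold == 1
  expect_identical(r1$coefficients[m1, ], r2$coefficients[m1, ])
  expect_identical(r1$vips[m1, ], r2$vips[m1, ])
  expect_identical(r1$models$n_lv[m1], r2$models$n_lv[m1])
  # but the held-out predictions do change
  p1 <- r1$predictions[r1$predictions$fold == 1, "yhat"]
  p2 <- r2$predictions[r2$predictions$fold == 1, "yhat"]
  expect_false(isTRUE(all.equal(p1, p2)))
})

test_that("a separable pair reaches high accuracy with sign-consistent scores", {
  ds <- generate_dataset(small_config(n_per_class = 30, p = 10, n_shift = 3,
                                      shift_sd = 3, seed = 31))
  wide <- to_wide(ds)
  y <- factor(ds$metadata$region, levels = c("class1", "class2"))
  r <- run_rdcv(wide, y, rdcv_config(n_runs = 5, seed = 19))
  expect_gte(glance(r)$accuracy_mean, 95)
  sc <- score_interval_plot_data(r)
  # class-1 samples sit at positive mean scores, class-2 at negative
  ok <- mean((sc$mean_score > 0) == (sc$class == "class1"))
  expect_gte(ok, 0.95)
  # intervals contain their own means
  expect_true(all(sc$lower <= sc$mean_score & sc$mean_score <= sc$upper))
  # the shifted elements are flagged with the correct direction
  sv <- significant_variables(r)
  expect_true(all(sv$significant[sv$term %in% sprintf("El%02d", 1:3)]))
  expect_true(all(sv$higher_in[sv$term %in% sprintf("El%02d", 1:3)] ==
                    "class1"))
  expect_equal(tidy(r), sv)
})

test_that("degenerate all-zero parameter distributions flag nothing", {
  fake <- structure(
    list(
      coefficients = matrix(0, 20, 3,
                            dimnames = list(NULL, c("a", "b", "c"))),
      vips = matrix(1, 20, 3, dimnames = list(NULL, c("a", "b", "c"))),
      models = tibble::tibble(run = rep(1:4, each = 5),
                              fold = rep(1:5, 4), n_lv = 1L),
      elements = c("a", "b", "c"), classes = c("x", "y"),
      config = rdcv_config(n_runs = 4, n_outer = 5, seed = 1)
    ),
    class = "rdcv_result")
  sv <- significant_variables(fake)
  expect_false(any(sv$significant))
  sv_pct <- significant_variables(fake, method = "percentile",
                                  vip_rule = FALSE)
  expect_false(any(sv_pct$significant))
})

test_that("autoplot returns ggplot objects for both views", {
  ds <- generate_dataset(small_config(n_per_class = 15, p = 5, n_shift = 1,
                                      seed = 37))
  wide <- to_wide(ds)
  y <- factor(ds$metadata$region, levels = c("class1", "class2"))
  r <- run_rdcv(wide, y, rdcv_config(n_runs = 2, n_outer = 5, n_inner = 3,
                                     max_lv = 3, seed = 23))
  expect_s3_class(autoplot(r, type = "scores"), "ggplot")
  expect_s3_class(autoplot(r, type = "coefficients"), "ggplot")
})
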