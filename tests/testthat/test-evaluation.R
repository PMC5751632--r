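test_that("metric arithmetic reproduces the published confusion matrix", {
  cm <- confusion_matrix(tp = 136354, fn = 42937, fp = 33949, tn = 165773)
  m <- compute_metrics(cm)
  expect_equal(round(m$accuracy, 2), 79.71)
  expect_equal(round(m$precision, 2), 80.07)
  expect_equal(round(m$sensitivity, 2), 76.05)
  expect_equal(round(m$specificity, 2), 83.00)
})

test_that("degenerate matrices yield 100% or not-applicable entries", {
  m <- compute_metrics(confusion_matrix(10, 0, 0, 10))
  expect_equal(m$accuracy, 100)
  expect_equal(m$precision, 100)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  z <- compute_metrics(confusion_matrix(0, 0, 5, 5))
  expect_true(is.na(z$sensitivity))   # no actual positives
  expect_equal(z$specificity, 50)
  expect_equal(z$precision, 0)
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("confusion matrices build from truth/decision vectors", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  dec <- c("eating", "non-eating", "eating", "non-eating", "eating")
  cm <- confusion_matrix(truth, decision = dec)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2, 1, 1, 1))
})

test_that("ROC sweep is monotone, saturates at threshold zero, and matches
          hand enumeration", {
  post <- c(0.9, 0.8, 0.65, 0.5, 0.3, 0.1)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  roc <- roc_sweep(post, truth, thresholds = c(1, 0.7, 0.55, 0.2, 0))
  # hand enumeration with the inclusive rule
  expect_equal(roc$tp, c(0, 2, 2, 3, 3))
  expect_equal(roc$fp, c(0, 0, 1, 2, 3))
  expect_equal(roc$sensitivity, c(0, 2, 2, 3, 3) / 3)
  expect_equal(roc$one_minus_specificity, c(0, 0, 1, 2, 3) / 3)
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_equal(roc$sensitivity[roc$threshold == 0], 1)

  perfect <- roc_sweep(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(perfect, "auc"), 1)
})

test_that("sweep AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  truth <- runif(300) < 0.45
  post <- plogis(2 * truth + rnorm(300) - 1)
  roc <- roc_sweep(post, truth, thresholds = sort(unique(c(0, post, 1)),
                                                  decreasing = TRUE))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, post, quiet = TRUE,
                                        direction = "<")))
  expect_equal(attr(roc, "auc"), ref, tolerance = 1e-9)
})

test_that("cross-validation folds are deterministic, balanced and stratified", {
  d <- small_dataset()
  idx <- seq_len(400)
  w <- d$windows[idx, ]; ctx <- d$contexts[idx, ]
  cv1 <- kfold_cv(w, ctx, k = 3, seed = 50)
  cv2 <- kfold_cv(w, ctx, k = 3, seed = 50)
  expect_identical(cv1$assignment, cv2$assignment)
  expect_identical(cv1$pooled_cm, cv2$pooled_cm)
  sizes <- table(cv1$assignment)
  expect_lte(max(sizes) - min(sizes), 1)
  # stratification: per-fold class share close to the global share
  share <- mean(ctx$eating)
  for (f in 1:3)
    expect_lt(abs(mean(ctx$eating[cv1$assignment == f]) - share), 0.05)
  expect_equal(nrow(cv1$folds), 3L)
  expect_true(all(is.finite(cv1$scored$posterior)))
})

test_that("a perfectly learnable dataset cross-validates at 100%", {
  # deterministic contexts and a cleanly separable feature
  set.seed(60)
  n <- 240
  eat <- rep(c(TRUE, FALSE), each = n / 2)
  s <- build_default_structure()
  hidden <- s$nodes$id[s$nodes$role != "evidence"]
  ctx <- as.data.frame(setNames(lapply(hidden, function(h) eat), hidden))
  feats <- unique(s$nodes$feature[s$nodes$role == "evidence"])
  w <- as.data.frame(setNames(lapply(feats, function(f)
    ifelse(eat, 1, 0) + runif(n, -0.2, 0.2)), feats))
  w$window_start <- seq_len(n); w$label <- ifelse(eat, 4L, 8L); w$is_eating <- eat
  cv <- kfold_cv(w, ctx, k = 2, seed = 61)
  expect_equal(cv$pooled$accuracy, 100)
})

test_that("per-activity error rates and shares match hand counts", {
  labels <- c(4, 4, 4, 4, 2, 2, 8, 8, 8, 6)
  truth <- labels %in% eating_labels
  dec <- c("eating", "eating", "non-eating", "eating",     # 1 error on 4
           "non-eating", "non-eating",                      # 0 errors on 2
           "eating", "eating", "non-eating",                # 2 errors on 8
           "non-eating")                                    # 0 errors on 6
  pa <- per_activity_error(labels, dec, truth)
  expect_equal(pa$errors[pa$label == 4], 1L)
  expect_equal(pa$errors[pa$label == 8], 2L)
  expect_equal(pa$error_rate[pa$label == 4], 1 / 4)
  expect_equal(pa$error_rate[pa$label == 8], 2 / 3)
  expect_equal(pa$error_share[pa$label == 8], 2 / 3)
  expect_equal(sum(pa$error_share), 1)
  # zero errors: rates zero, shares not applicable
  pa0 <- per_activity_error(labels, ifelse(truth, "eating", "non-eating"), truth)
  expect_true(all(pa0$errors == 0))
  expect_true(all(is.na(pa0$error_share)))
})
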