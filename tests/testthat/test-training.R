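# Loss, schedule, subject-level splitting, SGD training and evaluation.

test_that("cross-entropy equals -log of the true-class probability", {
  expect_lt(crossentropy_loss(c(1, 0), c(1, 0)), 1e-9) # floored perfect hit
  expect_equal(crossentropy_loss(c(1, 0), c(0.5, 0.5)), log(2))
  # only the target-class probability matters
  expect_equal(crossentropy_loss(c(1, 0, 0), c(0.5, 0.3, 0.2)),
               crossentropy_loss(c(1, 0, 0), c(0.5, 0.25, 0.25)))
  expect_error(crossentropy_loss(c(0.5, 0.5), c(0.5, 0.5)), "one-hot")
  # matrix form averages per-sample losses
  t2 <- rbind(c(1, 0), c(0, 1))
  p2 <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(crossentropy_loss(t2, p2), mean(c(log(2), -log(0.75))))
})

test_that("learning rate decays as a staircase", {
  cfg <- train_config("fusion")
  expect_equal(cfg$decay_rate, 0.9)
  expect_equal(lr_schedule(0, cfg), 0.01)
  expect_equal(lr_schedule(999, cfg), 0.01)
  expect_equal(lr_schedule(1000, cfg), 0.009)
  expect_equal(lr_schedule(2500, cfg), 0.01 * 0.9^2)
  cfg_eye <- train_config("eye")
  expect_equal(cfg_eye$decay_rate, 0.75)
  expect_equal(lr_schedule(1000, cfg_eye), 0.0075)
})

test_that("folds are subject-level, stratified, and leak-free", {
  manifest <- data.frame(
    subject_id = rep(1:10, each = 6),
    label = rep(rep(c("alert", "drowsy"), each = 5), each = 6))
  folds <- make_folds(manifest, seed = 3)
  expect_length(folds, 4)
  for (f in folds) {
    expect_length(f$test_subjects, 3) # 30% of 10
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
    expect_setequal(c(f$train_subjects, f$test_subjects), 1:10)
    # both classes present on both sides
    lab <- manifest$label[match(f$test_subjects, manifest$subject_id)]
    expect_setequal(unique(lab), c("alert", "drowsy"))
    # no frame of a test subject reachable from the training side
    expect_false(any(manifest$subject_id %in% f$test_subjects &
                       manifest$subject_id %in% f$train_subjects))
  }
  expect_identical(make_folds(manifest, seed = 3), folds) # deterministic
  expect_false(identical(folds[[1]]$test_subjects, folds[[2]]$test_subjects) &&
                 identical(folds[[2]]$test_subjects, folds[[3]]$test_subjects))
  expect_error(make_folds(manifest[manifest$label == "alert", ], seed = 1),
               "both classes")
  expect_error(make_folds(manifest[manifest$subject_id <= 3, ], seed = 1),
               "at least 4")
})

test_that("ROC sweep and trapezoidal AUC match the concordant-pair oracle", {
  # perfect ranking
  expect_equal(roc_curve(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  # uninformative scores
  expect_equal(roc_curve(rep(0.5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  # hand-listed four-sample set: pairs (pos 0.8 vs neg 0.6, 0.4) and
  # (pos 0.3 vs neg 0.6, 0.4) -> concordant 2 of 4 plus none tied
  s <- c(0.8, 0.3, 0.6, 0.4); pos <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_curve(s, pos)$auc, oracle_auc(s, pos))
  expect_equal(roc_curve(s, pos)$auc, 0.5)
  set.seed(22)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, TRUE) # many ties
    lab <- sample(c(TRUE, FALSE), n, TRUE)
    if (all(lab) || !any(lab)) next
    expect_equal(roc_curve(sc, lab)$auc, oracle_auc(sc, lab),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("training is deterministic, a no-op at zero steps, and learns", {
  set.seed(31)
  n <- 60
  x <- array(runif(8 * 8 * 3 * n), c(8, 8, 3, n))
  y <- rep(0:1, length.out = n)
  # separable signal: class 1 images brighter in one quadrant
  for (i in which(y == 1)) x[1:4, 1:4, , i] <- x[1:4, 1:4, , i] / 4
  spec <- build_model(c(8, 8, 3))
  w0 <- init_cnn_weights(spec, seed = 5)

  cfg0 <- train_config("eye", max_steps = 0L, batch_size = 8L, seed = 2)
  fit0 <- train_model(w0, x, y, cfg0)
  expect_identical(fit0$weights, w0)
  expect_length(fit0$loss, 0)

  cfg <- train_config("eye", max_steps = 300L, batch_size = 8L, seed = 2)
  fit1 <- train_model(w0, x, y, cfg)
  fit2 <- train_model(w0, x, y, cfg)
  expect_identical(fit1$weights, fit2$weights)
  expect_equal(fit1$loss, fit2$loss)
  expect_length(fit1$loss, 300)
  # loss at the cap is below the starting loss on separable data
  expect_lt(mean(tail(fit1$loss, 20)), fit1$loss[1])
  # and the model actually separates held-out-style data at the 0.5 point
  rep <- evaluate_model(fit1$weights, x, y)
  expect_gt(rep$auc, 0.9)
})

test_that("evaluation reports per-class accuracy and its class-mean", {
  set.seed(8)
  n <- 40
  x <- array(runif(8 * 8 * 3 * n), c(8, 8, 3, n))
  y <- rep(0:1, length.out = n)
  w <- init_cnn_weights(build_model(c(8, 8, 3)), seed = 1)
  r <- evaluate_model(w, x, y)
  expect_equal(r$average_accuracy,
               mean(r$per_class_accuracy), tolerance = 1e-12)
  rf <- evaluate_model(w, x, y, average = "frame")
  pred <- as.integer(cnn_predict(w, x)$probs[, 2] >= 0.5)
  expect_equal(rf$average_accuracy, 100 * mean(pred == y))
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_error(evaluate_model(w, x, rep(1, n)), "both classes")
})
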