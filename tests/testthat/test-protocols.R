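# Small deterministic network: one perfect detector per class direction.
detector_net <- function(n_classes, extra = 0L, v_th = 13.5) {
  d <- n_classes * 4L
  net <- build_network(cfn_config(n_classes + extra, d, v_th = v_th))
  for (j in seq_len(n_classes)) {
    w <- numeric(d)
    w[((j - 1) * 4 + 1):(j * 4)] <- 0.5
    net$weights[j, ] <- w
  }
  net
}

class_samples <- function(n_classes, per_class) {
  d <- n_classes * 4L
  x <- do.call(rbind, lapply(seq_len(n_classes), function(j) {
    v <- numeric(d); v[((j - 1) * 4 + 1):(j * 4)] <- 1
    matrix(rep(v, per_class), nrow = per_class, byrow = TRUE)
  }))
  list(x = x, y = rep(seq_len(n_classes) - 1L, each = per_class))
}

test_that("label assignment maps detectors to their classes, ties go low", {
  set.seed(51)
  net <- freeze_network(detector_net(3, extra = 1L))
  s <- class_samples(3, 2)
  labels <- assign_labels(net, s$x, s$y)
  expect_identical(labels[1:3], 0:2)
  # deterministic single-channel drive: the same sample labeled twice gives
  # an exact spike-count tie, resolved to the lowest class index
  net1 <- build_network(cfn_config(1, 2, v_th = 5))
  net1$weights[1, ] <- c(1, 0)
  net1 <- freeze_network(net1)
  x <- rbind(c(1, 0), c(1, 0))
  lab <- assign_labels(net1, x, c(0L, 1L))
  counts <- attr(lab, "counts")
  expect_identical(unname(counts[1, 1]), unname(counts[1, 2]))
  expect_identical(lab[[1]], 0L)
  expect_error(assign_labels(unfreeze_network(net1), x, c(0L, 1L)), "frozen")
})

test_that("classification is winner-take-all over assigned neurons", {
  set.seed(52)
  net <- freeze_network(detector_net(3))
  s <- class_samples(3, 3)
  labels <- assign_labels(net, s$x, s$y)
  pred <- classify_samples(net, labels, s$x)
  expect_identical(pred$prediction, s$y)
  expect_false(any(pred$fallback))
  # same frozen net and seed: identical predictions
  set.seed(99); p1 <- classify_samples(net, labels, s$x)
  set.seed(99); p2 <- classify_samples(net, labels, s$x)
  expect_identical(p1, p2)
})

test_that("disjoint schedules produce one report per task with seen classes", {
  set.seed(53)
  ds <- generate_synthetic(synthetic_config(samples_per_class = 20L))
  parts <- split_dataset(ds)
  net <- build_network(cfn_config(16, 64, v_th = 12.5))
  fit <- run_schedule(net, parts$train, parts$test, scenario = "disjoint")
  expect_length(fit$reports, 4L)
  for (k in 1:4) {
    rep_k <- fit$reports[[k]]
    expect_identical(rep_k$classes_seen, 0:(k - 1))
    expect_length(rep_k$per_class_acc, k)
    expect_true(all(rep_k$per_class_acc >= 0 & rep_k$per_class_acc <= 1))
    # combined accuracy is the evaluation-weighted mean of per-class values
    n_cl <- table(factor(parts$test$y[parts$test$y %in% rep_k$classes_seen]))
    expect_equal(rep_k$combined_acc,
                 sum(rep_k$per_class_acc * as.vector(n_cl)) / sum(n_cl))
  }
  expect_false(fit$net$frozen)
  expect_error(run_schedule(net, parts$train, parts$test,
                            class_order = c(0L, 9L)), "schedule")
})

test_that("random-weight control keeps identical weights at every stage", {
  set.seed(54)
  ds <- generate_synthetic(synthetic_config(samples_per_class = 15L))
  parts <- split_dataset(ds)
  net <- build_network(cfn_config(16, 64, variant = "random_weights",
                                  v_th = 12.5))
  fit <- run_schedule(net, parts$train, parts$test, scenario = "disjoint")
  expect_identical(fit$net$weights, net$weights)
  expect_length(fit$reports, 4L)
})

test_that("interleaved schedules evaluate once over all classes", {
  set.seed(55)
  ds <- generate_synthetic(synthetic_config(samples_per_class = 15L))
  parts <- split_dataset(ds)
  net <- build_network(cfn_config(16, 64, v_th = 12.5))
  fit <- run_schedule(net, parts$train, parts$test, scenario = "interleaved")
  expect_length(fit$reports, 1L)
  expect_identical(fit$reports[[1]]$classes_seen, 0:3)
})

test_that("trigger statistics segment dopamine activity by stage", {
  reports <- list(
    list(stage = 1L, dop_triggers = c(2, 1, 1, 0, 0, 0, 0, 0, 0, 0)),
    list(stage = 2L, dop_triggers = c(3, 2, 0, 0, 0, 0, 0, 0, 0, 0)))
  ts <- trigger_statistics(reports)
  expect_identical(nrow(ts), 2L)
  expect_equal(ts$first_decile_mean, c(2, 3))
  expect_equal(ts$last_decile_mean, c(0, 0))
  expect_equal(ts$total_triggers, c(4, 5))
  empty <- trigger_statistics(list(list(stage = 1L, dop_triggers = numeric(0))))
  expect_identical(nrow(empty), 0L)
})

test_that("the hyper-parameter sweep is shaped like its grid and reproducible", {
  set.seed(56)
  ds <- generate_synthetic(synthetic_config(samples_per_class = 10L))
  base <- cfn_config(12, 64, v_th = 12.5)
  set.seed(57)
  sw1 <- sweep_hyperparams(ds, base, v_th_grid = c(12.5, 13), epochs_grid = 1L)
  expect_identical(nrow(sw1), 2L)
  expect_identical(sum(sw1$best), 1L)
  expect_true(all(sw1$train_acc >= 0 & sw1$train_acc <= 1))
  set.seed(57)
  sw2 <- sweep_hyperparams(ds, base, v_th_grid = c(12.5, 13), epochs_grid = 1L)
  expect_identical(sw1, sw2)
})

test_that("worst accuracy drop summarizes the trajectory", {
  mk <- function(acc) lapply(seq_along(acc), function(i) {
    list(stage = i, combined_acc = acc[i])
  })
  expect_equal(worst_accuracy_drop(mk(c(1, 0.9, 0.95))), 0.1)
  expect_equal(worst_accuracy_drop(mk(c(0.5, 0.7))), 0)
  expect_equal(worst_accuracy_drop(mk(0.8)), 0)
  expect_equal(accuracy_curve(mk(c(0.2, 0.4))), c(0.2, 0.4))
})
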