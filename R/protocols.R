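#' Assign class labels to neurons by unsupervised inference
#'
#' With the network frozen, every labeled training sample is presented in
#' inference mode and each neuron's output spikes are tallied per true
#' class. A neuron is labeled with the class for which it spiked the most
#' (ties broken by the lowest class index); neurons that never fired stay
#' unassigned (`NA`) and are excluded from classification. No linear
#' combination of outputs is ever fitted — this keeps the evaluation fully
#' unsupervised.
#'
#' @param net A frozen `cfn_network`.
#' @param x Numeric matrix of raw samples (one per row).
#' @param y Integer class labels aligned with the rows of `x`.
#' @return Integer vector of length `n_neurons` with the class label per
#'   neuron (`NA` = unassigned), with attribute `counts` (neurons x
#'   classes spike tally).
#' @export
assign_labels <- function(net, x, y) {
  if (!net$frozen) stop("label assignment requires a frozen network",
                        call. = FALSE)
  classes <- sort(unique(y))
  counts <- matrix(0, nrow = net$config$n_neurons, ncol = length(classes),
                   dimnames = list(NULL, classes))
  for (s in seq_len(nrow(x))) {
    rates <- normalize_rates(x[s, ])
    res <- present_sample(net, rates, mode = "infer")$result
    col <- match(y[s], classes)
    counts[, col] <- counts[, col] + res$spike_counts
  }
  labels <- apply(counts, 1L, function(row) {
    if (all(row == 0)) NA_integer_ else classes[which.max(row)]
  })
  if (all(is.na(labels))) {
    stop("degenerate model: no neuron fired during label assignment",
         call. = FALSE)
  }
  attr(labels, "counts") <- counts
  labels
}

#' Classify samples with a frozen, labeled network
#'
#' Each sample is presented in inference mode (with rate escalation for
#' poorly recognized inputs); the prediction is the label of the assigned
#' neuron that spiked the most (winner-take-all, ties broken by lowest
#' neuron index). If no assigned neuron spiked even after maximal
#' escalation, the assigned neuron with the highest final membrane
#' potential decides, and the sample is flagged.
#'
#' @param net A frozen `cfn_network`.
#' @param labels Neuron labels from [assign_labels()].
#' @param x Numeric matrix of raw samples (one per row).
#' @return Data frame with `prediction`, `esc_steps` and `fallback` per
#'   sample.
#' @export
classify_samples <- function(net, labels, x) {
  if (!net$frozen) stop("classification requires a frozen network",
                        call. = FALSE)
  assigned <- which(!is.na(labels))
  if (length(assigned) == 0L) {
    stop("degenerate model: no assigned neurons", call. = FALSE)
  }
  n <- nrow(x)
  prediction <- integer(n)
  esc_steps <- integer(n)
  fb <- logical(n)
  for (s in seq_len(n)) {
    rates <- normalize_rates(x[s, ])
    res <- present_sample(net, rates, mode = "infer")$result
    sc <- res$spike_counts[assigned]
    if (any(sc > 0)) {
      winner <- assigned[which.max(sc)]
    } else {
      winner <- assigned[which.max(res$v_final[assigned])]
      fb[s] <- TRUE
    }
    prediction[s] <- labels[winner]
    esc_steps[s] <- res$esc_steps
  }
  data.frame(prediction = prediction, esc_steps = esc_steps, fallback = fb)
}

stage_report <- function(stage, classes_seen, truth, pred, dop_triggers,
                         variant) {
  per_class_acc <- vapply(classes_seen, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1))
  per_class_fp <- vapply(classes_seen, function(cl) {
    sum(pred == cl & truth != cl)
  }, numeric(1))
  names(per_class_acc) <- names(per_class_fp) <- classes_seen
  list(stage = stage, variant = variant, classes_seen = classes_seen,
       combined_acc = mean(pred == truth), per_class_acc = per_class_acc,
       per_class_fp = per_class_fp, n_eval = length(truth),
       dop_triggers = dop_triggers)
}

#' Run a lifelong-learning schedule
#'
#' In the `disjoint` scenario classes are presented strictly sequentially
#' (all samples of one class, then the next, never returning); after each
#' task the network is frozen, neurons are labeled by inference on the
#' training samples of every class seen so far, accuracy is measured on
#' the test samples of those same classes, and the network is unfrozen for
#' the next task. In the `interleaved` scenario the whole training set is
#' shuffled uniformly and a single evaluation is performed at the end. The
#' `random_weights` variant skips training (its weights never change).
#'
#' @param net A `cfn_network` (unfrozen).
#' @param train,test `cfn_dataset`s (see [split_dataset()]).
#' @param scenario `"disjoint"` or `"interleaved"`.
#' @param epochs_per_task Training passes over each task (disjoint) or
#'   over the full set (interleaved).
#' @param class_order Optional class presentation order; defaults to the
#'   dataset's ascending order.
#' @return List with `reports` (one per stage: combined and per-class
#'   accuracy, per-class false positives, dopamine triggers per training
#'   sample) and `net` (the trained network, unfrozen).
#' @export
run_schedule <- function(net, train, test,
                         scenario = c("disjoint", "interleaved"),
                         epochs_per_task = 1L, class_order = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(class_order)) class_order <- train$class_order
  if (!all(class_order %in% train$y)) {
    stop("schedule error: empty task in `class_order`", call. = FALSE)
  }
  variant <- net$config$variant
  train_on <- function(net, idx, epochs) {
    triggers <- numeric(0)
    if (variant != "random_weights") {
      for (ep in seq_len(epochs)) {
        for (s in sample(idx)) {
          rates <- normalize_rates(train$x[s, ])
          out <- present_sample(net, rates, mode = "train")
          net <- out$net
          triggers <- c(triggers, out$result$dop_fires)
        }
      }
    } else {
      triggers <- rep(0, length(idx) * epochs)
    }
    list(net = net, triggers = triggers)
  }
  evaluate <- function(net, classes_seen, stage, triggers) {
    net <- freeze_network(net)
    seen_train <- train$y %in% classes_seen
    labels <- assign_labels(net, train$x[seen_train, , drop = FALSE],
                            train$y[seen_train])
    seen_test <- test$y %in% classes_seen
    pred <- classify_samples(net, labels, test$x[seen_test, , drop = FALSE])
    stage_report(stage, classes_seen, test$y[seen_test], pred$prediction,
                 triggers, variant)
  }
  reports <- list()
  if (scenario == "disjoint") {
    for (k in seq_along(class_order)) {
      cls <- class_order[k]
      out <- train_on(net, which(train$y == cls), epochs_per_task)
      net <- out$net
      reports[[k]] <- evaluate(net, class_order[seq_len(k)], k, out$triggers)
      net <- unfreeze_network(net)
    }
  } else {
    out <- train_on(net, seq_along(train$y), epochs_per_task)
    net <- out$net
    reports[[1]] <- evaluate(net, sort(unique(train$y)), 1L, out$triggers)
    net <- unfreeze_network(net)
  }
  list(reports = reports, net = net)
}

#' Combined accuracy trajectory of a schedule run
#'
#' @param reports Stage reports from [run_schedule()].
#' @return Numeric vector of combined accuracies per stage.
#' @export
accuracy_curve <- function(reports) {
  vapply(reports, `[[`, numeric(1), "combined_acc")
}

#' Largest stage-to-stage accuracy drop
#'
#' The headline degradation statistic of a lifelong run: the maximum
#' decrease in combined across-task accuracy between consecutive stages.
#' Catastrophic forgetting shows up as a large drop when a new class
#' overwrites earlier representations; controlled forgetting keeps it
#' small.
#'
#' @param reports Stage reports from [run_schedule()].
#' @return The worst drop (0 if accuracy never decreased).
#' @export
worst_accuracy_drop <- function(reports) {
  acc <- accuracy_curve(reports)
  if (length(acc) < 2L) return(0)
  max(c(0, -diff(acc)))
}

#' Dopamine trigger dynamics per stage
#'
#' Summarizes how often the dopaminergic unit fired per training sample
#' within each task: the mean over the first and last decile of samples.
#' On a class-sequential curriculum the novelty signal should spike at the
#' start of every new task and die away as the class is learned, so the
#' first-decile mean should exceed the last-decile mean for every task
#' after the first.
#'
#' @param reports Stage reports from [run_schedule()].
#' @return Data frame with `stage`, `n_samples`, `first_decile_mean`,
#'   `last_decile_mean`, `total_triggers`. Zero rows if no triggers were
#'   recorded at all stages and no samples were trained.
#' @export
trigger_statistics <- function(reports) {
  rows <- lapply(reports, function(rep) {
    tg <- rep$dop_triggers
    if (length(tg) == 0L) return(NULL)
    k <- max(1L, ceiling(length(tg) / 10))
    data.frame(stage = rep$stage, n_samples = length(tg),
               first_decile_mean = mean(tg[seq_len(k)]),
               last_decile_mean = mean(tg[seq(length(tg) - k + 1L, length(tg))]),
               total_triggers = sum(tg))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(stage = integer(0), n_samples = integer(0),
                      first_decile_mean = numeric(0),
                      last_decile_mean = numeric(0),
                      total_triggers = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Hyper-parameter sweep over threshold and epochs
#'
#' Trains a fresh network for every cell of a `v_th` by epochs grid and
#' reports the training-split accuracy (parameters must be chosen from the
#' training set alone, so no test data enters the sweep). One RNG stream
#' seeds all cells identically at entry so the comparison is paired.
#'
#' @param train `cfn_dataset` used for training, label assignment and
#'   accuracy.
#' @param base_config A [cfn_config()] supplying everything but `v_th`.
#' @param v_th_grid Numeric vector of thresholds.
#' @param epochs_grid Integer vector of epochs-per-task values.
#' @param scenario Passed to [run_schedule()].
#' @return Data frame with one row per cell (`n_neurons`, `v_th`,
#'   `epochs`, `train_acc`, `best` flag for the top cell).
#' @export
sweep_hyperparams <- function(train, base_config, v_th_grid,
                              epochs_grid = 1L,
                              scenario = "disjoint") {
  grid <- expand.grid(v_th = v_th_grid, epochs = as.integer(epochs_grid))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  seed_state <- get(".Random.seed", envir = globalenv())
  acc <- mapply(function(v_th, epochs) {
    assign(".Random.seed", seed_state, envir = globalenv())
    cfg <- base_config
    cfg$v_th <- v_th
    net <- build_network(cfg)
    fit <- run_schedule(net, train, train, scenario = scenario,
                        epochs_per_task = epochs)
    fit$reports[[length(fit$reports)]]$combined_acc
  }, grid$v_th, grid$epochs)
  out <- data.frame(n_neurons = base_config$n_neurons, v_th = grid$v_th,
                    epochs = grid$epochs, train_acc = acc)
  out$best <- seq_len(nrow(out)) == which.max(out$train_acc)
  out
}

#' Lifelong-learning benchmark on synthetic data
#'
#' End-to-end study harness: for each seed it generates a clustered
#' synthetic dataset, splits it, and runs the class-sequential (disjoint)
#' schedule for the dopaminergic network and the requested baselines, plus
#' an interleaved run of the dopaminergic network as the offline
#' reference. Every run of one seed shares the same dataset.
#'
#' @param seeds Integer vector of seeds (one replicate each).
#' @param synth_cfg A [synthetic_config()].
#' @param n_neurons Output-layer size.
#' @param v_th Static threshold used by all variants.
#' @param variants Character vector of disjoint-run variants.
#' @param epochs_per_task Training epochs per task.
#' @param test_frac Held-out fraction per class.
#' @return List with `runs` (nested: per seed, per run name, the
#'   [run_schedule()] reports) and `summary` (data frame with seed, run,
#'   final combined accuracy, worst stage drop).
#' @export
lifelong_benchmark <- function(seeds = 1:5, synth_cfg = synthetic_config(),
                               n_neurons = 32L, v_th = 12.5,
                               variants = c("cfn", "no_dopamine",
                                            "no_dopamine_homeostasis",
                                            "random_weights"),
                               epochs_per_task = 3L, test_frac = 0.2) {
  runs <- list()
  rows <- list()
  for (seed in seeds) {
    set.seed(seed)
    ds <- generate_synthetic(synth_cfg)
    parts <- split_dataset(ds, test_frac)
    seed_runs <- list()
    run_one <- function(variant, scenario) {
      cfg <- cfn_config(n_neurons = n_neurons, input_dim = synth_cfg$dim,
                        variant = variant, v_th = v_th)
      net <- build_network(cfg)
      run_schedule(net, parts$train, parts$test, scenario = scenario,
                   epochs_per_task = epochs_per_task)$reports
    }
    for (variant in variants) {
      name <- paste0(variant, "_disjoint")
      seed_runs[[name]] <- run_one(variant, "disjoint")
    }
    seed_runs$cfn_interleaved <- run_one("cfn", "interleaved")
    runs[[as.character(seed)]] <- seed_runs
    for (name in names(seed_runs)) {
      reps <- seed_runs[[name]]
      rows[[paste(seed, name)]] <- data.frame(
        seed = seed, run = name,
        final_acc = reps[[length(reps)]]$combined_acc,
        worst_drop = worst_accuracy_drop(reps))
    }
  }
  list(runs = runs, summary = do.call(rbind, rows))
}
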