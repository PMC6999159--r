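test_that("network construction satisfies invariants and is deterministic", {
  cfg <- cfn_config(n_neurons = 40, input_dim = 20)
  set.seed(21)
  net <- build_network(cfg)
  expect_equal(rowSums(net$weights^2), rep(1, 40), tolerance = 1e-12)
  expect_true(all(net$weights >= 0))
  expect_equal(sum(net$dop_weights^2), 1, tolerance = 1e-12)
  expect_true(all(net$dop_weights > 0))
  set.seed(21)
  expect_identical(build_network(cfg), net)
  expect_error(cfn_config(10, 5, variant = "nope"), "variant")
  # baselines carry no dopaminergic state; homeostasis carries offsets
  set.seed(21)
  base <- build_network(cfn_config(8, 20, variant = "no_dopamine"))
  expect_null(base$dop_weights)
  homeo <- build_network(cfn_config(8, 20, variant = "no_dopamine_homeostasis"))
  expect_equal(homeo$theta, rep(0, 8))
})

test_that("a frozen network never mutates learnable state", {
  set.seed(22)
  net <- build_network(cfn_config(10, 16, v_th = 10))
  rates <- normalize_rates(runif(16))
  out <- present_sample(freeze_network(net), rates, mode = "infer")
  expect_identical(out$net$weights, net$weights)
  expect_identical(out$net$dop_weights, net$dop_weights)
  # inference mode alone is enough to freeze behaviour
  out2 <- present_sample(net, rates, mode = "infer")
  expect_identical(out2$net$weights, net$weights)
})

test_that("training a random_weights network is a no-op on its weights", {
  set.seed(23)
  net <- build_network(cfn_config(6, 12, variant = "random_weights",
                                  v_th = 10))
  rates <- normalize_rates(runif(12))
  out <- present_sample(net, rates, mode = "train")
  expect_identical(out$net$weights, net$weights)
})

test_that("novel input triggers dopamine and one-shot isolated adoption", {
  set.seed(24)
  net <- axis_network(8, 16, v_th = 13.5)
  # input lives on channels 9..16, orthogonal to every trained detector
  rates <- normalize_rates(c(rep(0, 8), rep(1, 8)))
  out <- present_sample(net, rates, mode = "train", capture = TRUE)
  r <- out$result
  expect_gte(r$dop_fires, 1)
  ev <- r$events
  expect_equal(ev$time[ev$kind == 2][1], 200, tolerance = 1e-9)
  chg <- sqrt(rowSums((out$net$weights - net$weights)^2))
  expect_identical(sum(chg > 1e-12), 1L)
  winner <- which.max(chg)
  expect_gte(cosine(out$net$weights[winner, ], rates), 0.95)
  # the sacrificed neuron's dopaminergic weight was depressed
  expect_lt(out$net$dop_weights[winner], max(out$net$dop_weights))
  # presentation ran to the recognition criterion
  expect_gte(sum(r$spike_counts), net$config$recognize_spikes)
})

test_that("event stream times are strictly increasing and typed", {
  set.seed(25)
  net <- build_network(cfn_config(5, 10, v_th = 10))
  out <- present_sample(net, normalize_rates(runif(10)), mode = "train",
                        capture = TRUE)
  ev <- out$result$events
  expect_gt(nrow(ev), 0)
  expect_true(all(diff(ev$time) >= 0))
  # output/dopamine events coincide with their causes; among distinct
  # timestamps the order is strict
  expect_true(all(ev$kind %in% 0:2))
})

test_that("silent channels leave the dopaminergic unit to drive the sample", {
  set.seed(26)
  net <- build_network(cfn_config(4, 6, v_th = 12))
  out <- present_sample(net, rep(0, 6), mode = "train", capture = TRUE)
  ev <- out$result$events
  expect_identical(ev$kind[1], 2L)
  expect_equal(ev$time[1], 200, tolerance = 1e-9)
  # with dopamine disabled the same input is a stall
  base <- build_network(cfn_config(4, 6, variant = "no_dopamine"))
  expect_error(present_sample(base, rep(0, 6), mode = "train"), "stall")
})

test_that("inference escalates rates and records the steps", {
  set.seed(27)
  net <- axis_network(4, 8, v_th = 13.5)
  net <- freeze_network(net)
  # weak input aligned with a detector: needs escalation to fire
  rates <- normalize_rates(c(1, rep(0, 7))) * 0.4
  out <- present_sample(net, rates, mode = "infer")
  expect_gte(out$result$esc_steps, 1)
  expect_false(out$result$fallback)
  # hopeless input exhausts escalation and falls back
  out2 <- present_sample(net, rep(1e-9, 8), mode = "infer")
  expect_true(out2$result$fallback)
})

test_that("lateral inhibition resets rivals; subtractive mode only subtracts", {
  mk <- function(inhibition, amount = 1) {
    cfg <- cfn_config(2, 2, v_th = 2.5, inhibition = inhibition,
                      inhibition_amount = amount, variant = "no_dopamine")
    net <- build_network(cfg)
    net$weights <- rbind(c(1, 0), c(0, 1))
    net
  }
  inj <- list(times = c(1, 2, 2.1, 2.2, 2.3), channels = c(2, 2, 1, 1, 1))
  set.seed(28)
  hard <- present_sample(mk("hard"), c(0.5, 0.5), mode = "train",
                         inject = inj)$result
  expect_identical(hard$winners, 1L)  # neuron 1 crosses on channel-1 spikes
  expect_equal(hard$v_final[2], 0)    # rival reset by winner-take-all
  set.seed(28)
  soft <- present_sample(mk("subtractive"), c(0.5, 0.5), mode = "train",
                         inject = inj)$result
  v2_before <- exp(-1.3 / 15) + exp(-0.3 / 15)  # two channel-2 spikes decayed
  expect_equal(soft$v_final[2], v2_before - 1, tolerance = 1e-9)
})

test_that("simultaneous crossings resolve to the lowest neuron index", {
  cfg <- cfn_config(3, 2, v_th = 1, variant = "no_dopamine")
  set.seed(29)
  net <- build_network(cfg)
  net$weights <- rbind(c(1, 0), c(1, 0), c(0, 1))
  out <- present_sample(net, c(1, 0), mode = "infer",
                        inject = list(times = 1, channels = 1))
  expect_identical(out$result$winners, 1L)
  expect_identical(out$result$spike_counts, c(1L, 0L, 0L))
})

test_that("event-driven and dense-time backends agree on injected schedules", {
  set.seed(30)
  cfg <- cfn_config(5, 8, v_th = 8)
  net <- build_network(cfg)
  probs <- normalize_rates(runif(8) + 0.2)
  scheds <- list(make_schedule(0.25, 210, 8, probs),
                 make_schedule(1.5, 60, 8, probs),
                 make_schedule(1.5, 60, 8, probs))
  netE <- net; netS <- net
  for (k in 1:3) {
    e <- present_sample(netE, rep(0.5, 8), mode = "train", capture = TRUE,
                        inject = scheds[[k]])
    s <- present_sample_stepped(netS, scheds[[k]], mode = "train", dt = 0.005)
    netE <- e$net; netS <- s$net
    expect_identical(e$result$winners, as.integer(s$result$winners))
    expect_identical(e$result$spike_counts, as.integer(s$result$spike_counts))
    expect_identical(e$result$dop_fires, as.integer(s$result$dop_fires))
    evE <- e$result$events; evS <- s$result$events
    expect_lt(max(abs(evE$time[evE$kind != 0] - evS$time[evS$kind != 0]), 0),
              0.05)
    expect_lt(max(abs(e$result$v_final - s$result$v_final)), 1e-2)
  }
  expect_lt(max(abs(netE$weights - netS$weights)), 1e-3)
})

test_that("identical seeds give bit-identical sample results and weights", {
  cfg <- cfn_config(6, 10, v_th = 11)
  run <- function() {
    set.seed(31)
    net <- build_network(cfg)
    res <- list()
    for (i in 1:3) {
      out <- present_sample(net, normalize_rates(runif(10)), mode = "train")
      net <- out$net
      res[[i]] <- out$result
    }
    list(net = net, res = res)
  }
  a <- run(); b <- run()
  expect_identical(a, b)
})
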