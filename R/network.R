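#' Run configuration for a spiking network
#'
#' Collects every tunable constant of the model in one validated list.
#' Defaults are the reference operating point: timing is expressed in the
#' normalized unit fixed by the input encoding (the L2 magnitude of a rate
#' vector is one spike per time unit), `tau_mem = 15` sets the membrane
#' integration horizon, the recognition window and the pre-trace constant
#' are both 200 time units, five output spikes signal recognition, the
#' learning rate is 0.01 normally and 1.0 under dopamine, weights are
#' clipped to [0, 0.2] before normalization, and the dopaminergic unit
#' (threshold 1, rest 2, `tau_d = 200/log(2)`) self-fires exactly at the
#' end of an unanswered recognition window.
#'
#' @param n_neurons Number of output-layer neurons.
#' @param input_dim Number of input channels.
#' @param variant One of `"cfn"` (dopaminergic network),
#'   `"no_dopamine"`, `"no_dopamine_homeostasis"`, `"random_weights"`.
#' @param v_th Static firing threshold (voltage units; just below
#'   `tau_mem` for unit-norm weights and inputs).
#' @param tau_mem Membrane decay constant (time units).
#' @param tau_pre Pre-synaptic trace decay constant (time units).
#' @param recognize_time Recognition window length (time units).
#' @param recognize_spikes Output spikes required to recognize a sample.
#' @param alpha_base,alpha_boost Normal and dopamine-boosted learning rates.
#' @param w_cap Per-weight clip bound.
#' @param tau_d,dopamine_v_rest,dopamine_v_th,dopamine_inhibit Dopaminergic
#'   unit rise constant, resting potential, firing threshold, and the
#'   potential subtracted per output-layer spike.
#' @param eta Dopaminergic-weight depression fraction per post-synaptic fire.
#' @param kappa Dopaminergic stimulation gain factor; the per-neuron
#'   excitatory increment is `kappa * v_th * d_j / max(d)`, so `kappa = 1`
#'   guarantees the most-targeted neuron can reach threshold.
#' @param escalation_factor,escalation_max Multiplicative rate escalation
#'   per unanswered recognition window, and the maximum number of steps.
#' @param inhibition `"hard"` (winner-take-all reset to zero) or
#'   `"subtractive"`.
#' @param inhibition_amount Potential subtracted under subtractive
#'   inhibition.
#' @param theta_plus,tau_theta Homeostasis increment and decay constant
#'   (used only by the `no_dopamine_homeostasis` baseline).
#' @return A validated `cfn_config` list.
#' @export
cfn_config <- function(n_neurons, input_dim, variant = "cfn", v_th = 13.5,
                       tau_mem = 15, tau_pre = 200, recognize_time = 200,
                       recognize_spikes = 5L, alpha_base = 0.01,
                       alpha_boost = 1.0, w_cap = 0.2, tau_d = 200 / log(2),
                       dopamine_v_rest = 2, dopamine_v_th = 1,
                       dopamine_inhibit = 2, eta = 0.1, kappa = 1,
                       escalation_factor = 1.5, escalation_max = 10L,
                       inhibition = c("hard", "subtractive"),
                       inhibition_amount = 5, theta_plus = 0.05,
                       tau_theta = 1e5) {
  inhibition <- match.arg(inhibition)
  variants <- c("cfn", "no_dopamine", "no_dopamine_homeostasis",
                "random_weights")
  if (!variant %in% variants) {
    stop("invalid `variant`; must be one of: ",
         paste(variants, collapse = ", "), call. = FALSE)
  }
  if (n_neurons < 1L || input_dim < 1L) {
    stop("`n_neurons` and `input_dim` must be positive", call. = FALSE)
  }
  if (v_th <= 0 || tau_mem <= 0 || tau_pre <= 0) {
    stop("`v_th`, `tau_mem`, `tau_pre` must be positive", call. = FALSE)
  }
  if (dopamine_v_rest <= dopamine_v_th) {
    stop("dopaminergic unit must be self-firing: v_rest > v_th",
         call. = FALSE)
  }
  structure(list(
    n_neurons = as.integer(n_neurons), input_dim = as.integer(input_dim),
    variant = variant, v_th = v_th, tau_mem = tau_mem, tau_pre = tau_pre,
    recognize_time = recognize_time,
    recognize_spikes = as.integer(recognize_spikes),
    alpha_base = alpha_base, alpha_boost = alpha_boost, w_cap = w_cap,
    tau_d = tau_d, dopamine_v_rest = dopamine_v_rest,
    dopamine_v_th = dopamine_v_th, dopamine_inhibit = dopamine_inhibit,
    eta = eta, kappa = kappa, escalation_factor = escalation_factor,
    escalation_max = as.integer(escalation_max),
    inhibition_hard = inhibition == "hard",
    inhibition_amount = inhibition_amount, theta_plus = theta_plus,
    tau_theta = tau_theta), class = "cfn_config")
}

#' Build a spiking network
#'
#' Synaptic weights are initialized uniform-random in `[0, w_cap]` and
#' clipped/normalized row-wise; dopaminergic fan-out weights start equal up
#' to a tiny seeded jitter (so ties are broken reproducibly) and are
#' L2-normalized. Baseline variants carry no dopaminergic unit; the
#' homeostasis baseline adds per-neuron adaptive threshold offsets. All
#' randomness comes from the R RNG, so the construction is deterministic
#' under [set.seed()].
#'
#' @param config A [cfn_config()].
#' @return A `cfn_network` list with `weights` (n_neurons x input_dim,
#'   each row unit-norm), `dop_weights` (or `NULL`), `theta` (or `NULL`),
#'   `frozen` flag and the configuration.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "cfn_config"))
  n <- config$n_neurons
  d <- config$input_dim
  W <- matrix(stats::runif(n * d) * config$w_cap, nrow = n)
  W <- t(apply(W, 1L, cap_and_normalize, w_cap = config$w_cap))
  has_dopamine <- config$variant == "cfn"
  dopw <- NULL
  if (has_dopamine) {
    dopw <- rep(1, n) + stats::runif(n) * 1e-6
    dopw <- dopw / sqrt(sum(dopw^2))
  }
  theta <- if (config$variant == "no_dopamine_homeostasis") rep(0, n) else NULL
  structure(list(weights = W, dop_weights = dopw, theta = theta,
                 frozen = FALSE, config = config),
            class = "cfn_network")
}

#' @export
print.cfn_network <- function(x, ...) {
  cat(sprintf(
    "<cfn_network> variant=%s, %d neurons x %d channels, v_th=%.2f%s%s\n",
    x$config$variant, x$config$n_neurons, x$config$input_dim, x$config$v_th,
    if (!is.null(x$dop_weights)) ", dopaminergic" else "",
    if (x$frozen) ", FROZEN" else ""))
  invisible(x)
}

#' Freeze or unfreeze network parameters
#'
#' A frozen network performs inference only: synaptic weights,
#' dopaminergic weights and homeostasis offsets are immutable and the
#' dopaminergic unit is disabled. Label assignment and evaluation are only
#' valid on a frozen network.
#'
#' @param net A `cfn_network`.
#' @return The network with the `frozen` flag set/cleared.
#' @export
freeze_network <- function(net) { net$frozen <- TRUE; net }

#' @rdname freeze_network
#' @export
unfreeze_network <- function(net) { net$frozen <- FALSE; net }

sim_flags <- function(net, mode) {
  frozen <- net$frozen || mode == "infer"
  variant <- net$config$variant
  list(
    frozen = frozen,
    plastic = !frozen && variant != "random_weights",
    use_dopamine = !frozen && variant == "cfn",
    use_theta = variant == "no_dopamine_homeostasis",
    escalate = mode == "infer" || (mode == "train" && variant != "cfn")
  )
}

#' Present one sample to the network (event-driven)
#'
#' Runs the purely event-driven loop for a single sample: input channels
#' fire as independent Poisson processes at the given rates until the
#' network registers `recognize_spikes` output spikes. In training mode a
#' dopaminergic network never escalates its input rates (the dopaminergic
#' unit handles unrecognized samples); in inference mode, and in training
#' of the non-dopaminergic baselines, the rates are multiplied by the
#' escalation factor after every unanswered recognition window, up to the
#' configured maximum, after which the presentation gives up (`fallback`).
#' Membrane potentials, pre-traces and the dopaminergic potential start
#' from zero (the between-sample reset); synaptic weights, dopaminergic
#' weights and homeostasis offsets persist and are returned updated
#' (unchanged when frozen).
#'
#' @param net A `cfn_network`.
#' @param rates Non-negative input rate vector (normally L2 norm 1, see
#'   [normalize_rates()]).
#' @param mode `"train"` or `"infer"`. Inference always behaves as frozen.
#' @param capture If `TRUE`, record the full event stream.
#' @param inject Optional list with `times` (strictly increasing absolute
#'   spike times) and `channels` (1-based) replacing the Poisson draw;
#'   used for validation against the dense-time reference integrator.
#' @return List with `net` (updated network) and `result`: spike counts
#'   per neuron, dopamine fire count, presentation `duration`, escalation
#'   steps, ordered winner sequence, `fallback` flag, final membrane
#'   potentials and traces, and (if captured) the event stream.
#' @export
present_sample <- function(net, rates, mode = c("train", "infer"),
                           capture = FALSE, inject = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "cfn_network"))
  cfg <- net$config
  if (length(rates) != cfg$input_dim) {
    stop("rate vector length does not match the network input dimension",
         call. = FALSE)
  }
  fl <- sim_flags(net, mode)
  inj_t <- if (is.null(inject)) numeric(0) else as.numeric(inject$times)
  inj_c <- if (is.null(inject)) integer(0) else as.integer(inject$channels)
  res <- cpp_present(net$weights,
                     if (is.null(net$dop_weights)) numeric(0) else net$dop_weights,
                     if (is.null(net$theta)) numeric(0) else net$theta,
                     rates, unclass(cfg), fl$frozen, fl$plastic,
                     fl$use_dopamine, fl$use_theta, fl$escalate, capture,
                     inj_t, inj_c)
  if (!fl$frozen) {
    net$weights <- res$weights
    if (!is.null(net$dop_weights)) net$dop_weights <- res$dop_weights
    if (!is.null(net$theta)) net$theta <- res$theta
  }
  result <- res[c("spike_counts", "dop_fires", "duration", "esc_steps",
                  "winners", "fallback", "v_final", "traces_final",
                  "dop_v_final")]
  if (capture) result$events <- as.data.frame(res$events)
  list(net = net, result = result)
}

#' Present one sample with a dense-time reference integrator
#'
#' Re-implements the sample presentation on a fixed time grid: every step
#' decays membranes, traces and the dopaminergic potential by the exact
#' per-step exponential factors, then processes the injected input spikes
#' that fall inside the step and checks threshold crossings. This is the
#' independent reference against which the event-driven loop is validated:
#' both must produce identical spike sets and matching event times up to
#' the grid resolution. Only injected spike schedules are supported (a
#' dense-time Poisson draw would not be comparable event-for-event).
#'
#' @param net A `cfn_network`.
#' @param inject List with `times` and `channels` as in [present_sample()].
#' @param mode `"train"` or `"infer"` (no escalation either way).
#' @param dt Grid step (time units).
#' @param t_end End of simulated time; defaults to just past the last
#'   injected spike.
#' @return List with `net` and `result` (spike counts, winners, event
#'   stream, final potentials/traces, dopamine fire count).
#' @export
present_sample_stepped <- function(net, inject, mode = c("train", "infer"),
                                   dt = 0.005, t_end = NULL) {
  mode <- match.arg(mode)
  cfg <- net$config
  fl <- sim_flags(net, mode)
  n <- cfg$n_neurons
  d <- cfg$input_dim
  W <- net$weights
  dopw <- net$dop_weights
  theta <- if (is.null(net$theta)) rep(0, n) else net$theta
  use_theta <- fl$use_theta
  v <- rep(0, n)
  tr <- rep(0, d)
  dop_v <- 0
  boosted <- rep(FALSE, n)
  times <- inject$times
  chans <- inject$channels
  if (is.null(t_end)) t_end <- max(times) + dt
  fm <- exp(-dt / cfg$tau_mem)
  fp <- exp(-dt / cfg$tau_pre)
  fd <- exp(-dt / cfg$tau_d)
  ft <- exp(-dt / cfg$tau_theta)
  n_steps <- ceiling(t_end / dt)
  ev_t <- numeric(0); ev_kind <- integer(0); ev_id <- integer(0)
  spike_counts <- integer(n)
  winners <- integer(0)
  dop_fires <- 0L
  nxt <- 1L

  fire <- function(j, t_now) {
    ev_t <<- c(ev_t, t_now); ev_kind <<- c(ev_kind, 1L); ev_id <<- c(ev_id, j)
    spike_counts[j] <<- spike_counts[j] + 1L
    winners <<- c(winners, j)
    if (fl$plastic && sum(tr) > 0) {
      a <- if (boosted[j]) cfg$alpha_boost else cfg$alpha_base
      W[j, ] <<- cap_and_normalize(W[j, ] + a * (tr / cfg$tau_pre - W[j, ]),
                                   cfg$w_cap)
    }
    boosted[j] <<- FALSE
    if (cfg$inhibition_hard) v[-j] <<- 0 else v[-j] <<- v[-j] - cfg$inhibition_amount
    boosted[-j] <<- FALSE
    v[j] <<- 0
    if (fl$use_dopamine) dop_v <<- dop_v - cfg$dopamine_inhibit
    if (!is.null(dopw) && !fl$frozen) {
      dopw[j] <<- dopw[j] * (1 - cfg$eta)
      dopw <<- dopw / sqrt(sum(dopw^2))
    }
    if (use_theta && !fl$frozen) theta[j] <<- theta[j] + cfg$theta_plus
  }

  for (k in seq_len(n_steps)) {
    t_now <- k * dt
    v <- v * fm
    tr <- tr * fp
    if (fl$use_dopamine) dop_v <- cfg$dopamine_v_rest -
        (cfg$dopamine_v_rest - dop_v) * fd
    if (use_theta && !fl$frozen) theta <- theta * ft
    if (fl$use_dopamine && dop_v >= cfg$dopamine_v_th) {
      dop_fires <- dop_fires + 1L
      ev_t <- c(ev_t, t_now); ev_kind <- c(ev_kind, 2L); ev_id <- c(ev_id, 0L)
      dop_v <- 0
      boosted[] <- TRUE
      gain <- cfg$kappa * cfg$v_th / max(dopw)
      th_eff <- cfg$v_th + if (use_theta) theta else 0
      need <- (th_eff - v) / (gain * dopw)
      v <- v + gain * dopw
      if (any(need <= 1 + 1e-12)) {
        fire(which.min(need), t_now)
      }
    }
    while (nxt <= length(times) && times[nxt] <= t_now) {
      ch <- chans[nxt]
      tr[ch] <- tr[ch] + 1
      ev_t <- c(ev_t, t_now); ev_kind <- c(ev_kind, 0L); ev_id <- c(ev_id, ch)
      v <- v + W[, ch]
      th_eff <- cfg$v_th + if (use_theta) theta else 0
      crossed <- which(v >= th_eff)
      if (length(crossed)) fire(crossed[1], t_now)
      nxt <- nxt + 1L
    }
  }
  if (!fl$frozen) {
    net$weights <- W
    if (!is.null(net$dop_weights)) net$dop_weights <- dopw
    if (!is.null(net$theta)) net$theta <- theta
  }
  list(net = net,
       result = list(spike_counts = spike_counts, dop_fires = dop_fires,
                     winners = winners, v_final = v, traces_final = tr,
                     events = data.frame(time = ev_t, kind = ev_kind,
                                         id = ev_id)))
}
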