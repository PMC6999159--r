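#' Decay pre-synaptic traces and register an input spike
#'
#' Each input channel keeps a trace of its recent firing: the trace decays
#' exponentially with constant `tau_pre` and is incremented by exactly one
#' at each spike on that channel. Under stationary Poisson drive at rate
#' `lambda` the trace's expected value is `lambda * tau_pre`, which is what
#' makes the scaled trace `trace / tau_pre` an unbiased estimate of the
#' input rate and hence a usable Hebbian target.
#'
#' @param traces Numeric vector of per-channel traces (`>= 0`).
#' @param dt Time elapsed since the last trace update, `>= 0`.
#' @param spiked_channel Optional 1-based index of the channel that spiked
#'   at the end of the interval; `NULL` for a pure decay.
#' @param tau_pre Trace decay constant (time units).
#' @return Updated trace vector.
#' @export
update_pre_traces <- function(traces, dt, spiked_channel = NULL,
                              tau_pre = 200) {
  if (length(dt) != 1L || is.na(dt) || dt < 0) {
    stop("temporal-order error: `dt` must be a single non-negative time",
         call. = FALSE)
  }
  traces <- traces * exp(-dt / tau_pre)
  if (!is.null(spiked_channel)) {
    traces[spiked_channel] <- traces[spiked_channel] + 1
  }
  traces
}

#' Clip weights to bounds and L2-normalize
#'
#' Each weight is clipped to `[0, w_cap]` and the vector is then rescaled
#' to unit L2 norm. Capping before normalization keeps stochastic trace
#' outliers (which matter most during one-shot boosted updates) from
#' distorting the normalization; after rescaling individual entries may
#' exceed the cap slightly.
#'
#' @param w Numeric weight vector.
#' @param w_cap Upper clip bound per weight.
#' @return Unit-norm clipped weight vector.
#' @export
cap_and_normalize <- function(w, w_cap = 0.2) {
  if (any(!is.finite(w))) stop("weights must be finite", call. = FALSE)
  w <- pmin(pmax(w, 0), w_cap)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) {
    stop("degenerate weights: all entries clipped to zero", call. = FALSE)
  }
  w / nrm
}

#' Stabilized one-sided STDP update (Oja-style offset)
#'
#' Evaluated at a post-synaptic firing event. The offset is tied to the
#' current weight so the update direction points exactly at the scaled
#' pre-trace: `dw_i = alpha * (trace_i / tau_pre - w_i)`. The fixed point
#' is `w = trace / tau_pre` (in expectation, the input rate direction), so
#' the rule is stable without adaptive thresholds; with `alpha = 1` the
#' update adopts the trace direction outright in a single shot. The result
#' is clipped and L2-normalized by [cap_and_normalize()].
#'
#' @param w Weight vector (unit norm on entry).
#' @param traces Pre-synaptic trace vector at the firing time.
#' @param alpha Learning rate.
#' @param tau_pre Trace decay constant used to scale the trace.
#' @param w_cap Per-weight clip bound.
#' @return List with `delta` (the raw per-channel update) and `w` (the
#'   capped, normalized post-update weights).
#' @export
stdp_stabilized <- function(w, traces, alpha, tau_pre = 200, w_cap = 0.2) {
  delta <- alpha * (traces / tau_pre - w)
  list(delta = delta, w = cap_and_normalize(w + delta, w_cap))
}

#' Static-offset one-sided STDP update (unstabilized reference rule)
#'
#' The classical rule subtracts a constant offset identical in every
#' dimension: `dw_i = alpha * (trace_i - offset)`. The update direction is
#' not tied to the current weights, so repeated application drifts weight
#' vectors toward the axes; entries pin at the clip bounds and the
#' representation binarizes. Kept as the instability reference against
#' which [stdp_stabilized()] is compared; weights are clipped to
#' `[0, w_cap]` but not normalized (no stabilization).
#'
#' @param w Weight vector.
#' @param traces Pre-synaptic trace vector.
#' @param alpha Learning rate.
#' @param offset Constant anti-Hebbian offset.
#' @param w_cap Per-weight clip bound.
#' @return List with `delta` and clipped `w`.
#' @export
stdp_static_offset <- function(w, traces, alpha, offset, w_cap = 0.2) {
  delta <- alpha * (traces - offset)
  list(delta = delta, w = pmin(pmax(w + delta, 0), w_cap))
}

#' Depress and renormalize dopaminergic fan-out weights
#'
#' A dopaminergic weight depresses multiplicatively each time its
#' post-synaptic neuron fires (`d_j <- d_j * (1 - eta)`), and the whole
#' fan-out vector is then L2-renormalized. The renormalization is the
#' gradual potentiation of all other weights: only the relative order of
#' the dopaminergic weights matters, because stimulation continues until
#' some neuron fires. The result is that frequently firing neurons carry
#' small dopaminergic weights and are protected from reassignment, while
#' rarely used neurons carry large weights and are targeted first.
#'
#' @param d Positive fan-out weight vector (unit norm on entry).
#' @param j Index of the output neuron that fired.
#' @param eta Depression fraction per post-synaptic fire.
#' @return Renormalized fan-out vector.
#' @export
depress_dopaminergic <- function(d, j, eta = 0.1) {
  d[j] <- d[j] * (1 - eta)
  d / sqrt(sum(d^2))
}

#' Adaptive-threshold homeostasis update (baseline mechanism)
#'
#' In the non-dopaminergic homeostasis baseline each neuron carries a
#' threshold offset `theta_j` that grows by `theta_plus` every time the
#' neuron fires and decays exponentially otherwise; the effective firing
#' threshold is `v_th + theta_j`. This spreads activity across the layer
#' under stationary input but redistributes learning globally when the
#' input distribution shifts, which is exactly the failure mode the
#' dopaminergic mechanism replaces.
#'
#' @param theta Per-neuron threshold offsets (`>= 0`).
#' @param fired Optional index of the neuron that just fired.
#' @param dt Optional elapsed time over which all offsets decay.
#' @param theta_plus Increment per fire.
#' @param tau_theta Offset decay constant (time units).
#' @return Updated offsets.
#' @export
homeostasis_update <- function(theta, fired = NULL, dt = NULL,
                               theta_plus = 0.05, tau_theta = 1e5) {
  if (!is.null(dt)) {
    if (dt < 0) stop("temporal-order error: `dt` must be non-negative",
                     call. = FALSE)
    theta <- theta * exp(-dt / tau_theta)
  }
  if (!is.null(fired)) theta[fired] <- theta[fired] + theta_plus
  theta
}

#' Learning-rate (alpha) state helpers
#'
#' The learning rate of every output neuron sits at `base` (0.01) during
#' normal operation. When the dopaminergic unit fires, all neurons are
#' boosted to `boost` (1.0); a boosted neuron returns to base after its
#' next own firing event (its one boosted update is applied first) or upon
#' receiving lateral inhibition, so only the first neuron to respond
#' undergoes the one-shot update.
#'
#' @param n Number of output neurons.
#' @param base,boost Base and boosted learning rates.
#' @return `alpha_state()`: a list with `alpha` (numeric vector) and
#'   `boosted` (logical vector).
#' @export
alpha_state <- function(n, base = 0.01, boost = 1.0) {
  structure(list(alpha = rep(base, n), boosted = rep(FALSE, n),
                 base = base, boost = boost), class = "cfn_alpha_state")
}

#' @rdname alpha_state
#' @param state An `alpha_state()`.
#' @export
boost_alpha <- function(state) {
  state$alpha[] <- state$boost
  state$boosted[] <- TRUE
  state
}

#' @rdname alpha_state
#' @param i Neuron index whose boost is cleared.
#' @param cause Either `"own-fire"` (the boosted update has just been
#'   applied) or `"lateral-inhibition"` (a neighbour fired first; the
#'   boost is cancelled unused).
#' @export
reset_alpha <- function(state, i, cause = c("own-fire", "lateral-inhibition")) {
  match.arg(cause)
  state$alpha[i] <- state$base
  state$boosted[i] <- FALSE
  state
}

#' Simulate repeated STDP updates under stationary Poisson drive
#'
#' Drives the pre-synaptic traces with a fixed-direction Poisson spike
#' train and applies one STDP update every `fire_interval` time units,
#' emulating a post-synaptic neuron locked onto the input. Used to study
#' the convergence of the stabilized rule versus the drift of the
#' static-offset rule.
#'
#' @param w0 Initial weight vector.
#' @param rates Input rate vector (the target direction).
#' @param rule `"stabilized"` or `"static"`.
#' @param n_fires Number of post-synaptic firing events to simulate.
#' @param fire_interval Time between post-synaptic fires.
#' @param alpha Learning rate.
#' @param offset Static offset (ignored for the stabilized rule); defaults
#'   to the stationary mean trace so the static rule is centred.
#' @param tau_pre Trace decay constant.
#' @param w_cap Per-weight clip bound.
#' @return List with `w` (final weights), `cosines` (cosine similarity of
#'   the weights to `rates` after every update) and `pinned_fraction`
#'   (final fraction of weights at a clip bound, within 1e-9).
#' @export
stdp_drive_experiment <- function(w0, rates, rule = c("stabilized", "static"),
                                  n_fires = 500L, fire_interval = 40,
                                  alpha = 0.01, offset = NULL,
                                  tau_pre = 200, w_cap = 0.2) {
  rule <- match.arg(rule)
  if (is.null(offset)) offset <- mean(rates) * tau_pre
  w <- w0
  traces <- rep(0, length(rates))
  total <- sum(rates)
  cosines <- numeric(n_fires)
  t_now <- 0
  t_next_fire <- fire_interval
  for (f in seq_len(n_fires)) {
    while (TRUE) {
      ev <- next_input_event(rates)
      if (t_now + ev$dt >= t_next_fire) {
        traces <- update_pre_traces(traces, t_next_fire - t_now,
                                    tau_pre = tau_pre)
        t_now <- t_next_fire
        break
      }
      traces <- update_pre_traces(traces, ev$dt, ev$channel, tau_pre = tau_pre)
      t_now <- t_now + ev$dt
    }
    upd <- if (rule == "stabilized") {
      stdp_stabilized(w, traces, alpha, tau_pre, w_cap)
    } else {
      stdp_static_offset(w, traces, alpha, offset, w_cap)
    }
    w <- upd$w
    cosines[f] <- sum(w * rates) / sqrt(sum(w^2) * sum(rates^2))
    t_next_fire <- t_next_fire + fire_interval
  }
  pinned <- mean(abs(w) < 1e-9 | abs(w - w_cap) < 1e-9)
  list(w = w, cosines = cosines, pinned_fraction = pinned)
}
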