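#' Exponential decay of a leaky integrate-and-fire membrane potential
#'
#' Between events the membrane obeys dv/dt = -(v - v_rest)/tau_mem with the
#' resting potential fixed at zero as the reference voltage, so the decay
#' over an interval `dt` is `v * exp(-dt / tau_mem)`.
#'
#' @param v Membrane potential(s), numeric.
#' @param dt Elapsed time, `>= 0`.
#' @param tau_mem Membrane decay constant (time units), `> 0`.
#' @return Decayed potential(s).
#' @export
decay_potential <- function(v, dt, tau_mem = 15) {
  if (length(dt) != 1L || is.na(dt) || dt < 0) {
    stop("temporal-order error: `dt` must be a single non-negative time",
         call. = FALSE)
  }
  if (tau_mem <= 0) stop("`tau_mem` must be positive", call. = FALSE)
  v * exp(-dt / tau_mem)
}

#' Integrate one weighted input spike into a membrane potential
#'
#' Spikes are delta functions scaled by the synaptic weight and added
#' instantaneously to the membrane potential. The neuron fires when the
#' potential reaches or surpasses the threshold (inclusive), in which case
#' it resets to zero (v_reset = v_rest = 0; no refractory period).
#'
#' @param v Current membrane potential (already decayed to the spike time).
#' @param weight Synaptic efficacy applied to the spike.
#' @param v_th Firing threshold, `> 0`.
#' @return List with `v` (post-event potential) and `fired` (logical).
#' @export
integrate_spike <- function(v, weight, v_th) {
  v2 <- v + weight
  fired <- v2 >= v_th
  list(v = ifelse(fired, 0, v2), fired = fired)
}

#' Parameters of the self-firing dopaminergic unit
#'
#' The dopaminergic unit has a resting potential above its firing
#' threshold, so left alone its membrane rises toward rest and crosses
#' threshold: it is self-firing. Output-layer spikes inhibit it, pushing
#' its potential down (possibly far below zero) and postponing the next
#' dopamine fire. With `v_rest = 2`, `v_th = 1` and
#' `tau = 200 / log(2)` the unit fires exactly 200 time units after a
#' reset, matching the recognition window.
#'
#' @param v_rest Resting potential (above threshold).
#' @param v_th Firing threshold.
#' @param tau Rise time constant (time units).
#' @param inhibit_amount Potential subtracted per output-layer spike.
#' @return A `cfn_dopamine_unit` list.
#' @export
dopamine_unit <- function(v_rest = 2, v_th = 1, tau = 200 / log(2),
                          inhibit_amount = 2) {
  if (v_rest <= v_th) {
    stop("self-firing requires `v_rest` > `v_th`", call. = FALSE)
  }
  structure(list(v_rest = v_rest, v_th = v_th, tau = tau,
                 inhibit_amount = inhibit_amount),
            class = "cfn_dopamine_unit")
}

#' Dopaminergic membrane potential after an interval
#'
#' Closed-form relaxation toward the resting potential:
#' `v(dt) = v_rest - (v_rest - v0) * exp(-dt / tau)`.
#'
#' @param unit A [dopamine_unit()].
#' @param v0 Potential at the start of the interval (may be negative).
#' @param dt Elapsed time, `>= 0`.
#' @return Potential at the end of the interval.
#' @export
dopamine_potential <- function(unit, v0, dt) {
  if (any(dt < 0)) {
    stop("temporal-order error: `dt` must be non-negative", call. = FALSE)
  }
  unit$v_rest - (unit$v_rest - v0) * exp(-dt / unit$tau)
}

#' Time until the dopaminergic unit would fire
#'
#' Solving the relaxation for the threshold crossing gives
#' `t* = tau * log((v_rest - v0) / (v_rest - v_th))` for `v0 < v_th`, well
#' defined because `v_rest > v_th`. At or above threshold the unit fires
#' immediately (`t* = 0`). From a reset (`v0 = 0`) with the default
#' parameters `t* = 200` time units.
#'
#' @param unit A [dopamine_unit()].
#' @param v0 Current potential.
#' @return Time to the next self-fire.
#' @export
dopamine_time_to_fire <- function(unit, v0) {
  ifelse(v0 >= unit$v_th, 0,
         unit$tau * log((unit$v_rest - v0) / (unit$v_rest - unit$v_th)))
}

#' Inhibit the dopaminergic unit after an output-layer spike
#'
#' Subtractive inhibition; the potential may go negative, which is how
#' bursts of output activity silence the novelty signal for long spans.
#'
#' @param unit A [dopamine_unit()].
#' @param v0 Current potential.
#' @return `v0 - inhibit_amount`.
#' @export
inhibit_dopamine <- function(unit, v0) {
  v0 - unit$inhibit_amount
}

#' Dense-time (Euler) crossing time of the dopaminergic membrane
#'
#' Integrates dv/dt = (v_rest - v) / tau on a fixed grid and reports the
#' first grid time at which the potential reaches threshold. Serves as a
#' numerically independent check on the closed-form
#' [dopamine_time_to_fire()].
#'
#' @param unit A [dopamine_unit()].
#' @param v0 Starting potential (below threshold).
#' @param dt Integration step (time units).
#' @param t_max Give-up horizon.
#' @return First grid time with `v >= v_th`, or `NA` if not reached by
#'   `t_max`.
#' @export
dopamine_crossing_stepped <- function(unit, v0, dt = 0.005, t_max = 5000) {
  # The Euler update v <- v + (v_rest - v) * dt / tau is linear, so the
  # whole trajectory can be evaluated in vectorized chunks without changing
  # the discretization: v_k = v_rest - (v_rest - v0) * (1 - dt/tau)^k.
  r <- 1 - dt / unit$tau
  n <- ceiling(t_max / dt)
  chunk <- 100000L
  done <- 0L
  rk_done <- 1
  while (done < n) {
    k <- seq_len(min(chunk, n - done))
    rk <- rk_done * r^k
    v <- unit$v_rest - (unit$v_rest - v0) * rk
    hit <- which(v >= unit$v_th)
    if (length(hit)) return((done + hit[1]) * dt)
    done <- done + length(k)
    rk_done <- rk[length(rk)]
  }
  NA_real_
}
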