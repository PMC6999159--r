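#' Mean pre-firing membrane potential under Poisson drive
#'
#' Before any firing event, the membrane of an LIF neuron driven by
#' independent Poisson channels is a shot-noise process with exponential
#' kernel `w_i * exp(-t / tau_mem)`. Its mean is
#' `E[V(t)] = tau_mem * (w . lambda) * (1 - exp(-t / tau_mem))`,
#' converging to `tau_mem * (w . lambda)` in steady state. For unit-norm
#' aligned weight and rate vectors the steady-state mean equals `tau_mem`,
#' which is why static firing thresholds sit just below `tau_mem` in
#' voltage units.
#'
#' @param w Weight vector.
#' @param rates Non-negative rate vector.
#' @param tau_mem Membrane decay constant, `> 0`.
#' @param t Evaluation time, `>= 0`; `Inf` (default) gives the exact
#'   steady-state limit.
#' @return Expected pre-firing potential.
#' @export
mean_potential <- function(w, rates, tau_mem = 15, t = Inf) {
  check_moment_inputs(w, rates, tau_mem, t)
  sat <- if (is.infinite(t)) 1 else 1 - exp(-t / tau_mem)
  tau_mem * sum(w * rates) * sat
}

#' Variance of the pre-firing membrane potential
#'
#' Second shot-noise moment:
#' `Var(V(t)) = tau_mem / 2 * (lambda . w^2) * (1 - exp(-2 t / tau_mem))`,
#' where `w^2` is the elementwise (Hadamard) square of the weight vector.
#' Scaling the weights by `c` scales the variance by `c^2` but the mean
#' only by `c`, which is why equal-norm weight vectors can still differ in
#' firing behaviour.
#'
#' @inheritParams mean_potential
#' @return Variance of the pre-firing potential.
#' @export
var_potential <- function(w, rates, tau_mem = 15, t = Inf) {
  check_moment_inputs(w, rates, tau_mem, t)
  sat <- if (is.infinite(t)) 1 else 1 - exp(-2 * t / tau_mem)
  0.5 * tau_mem * sum(rates * w^2) * sat
}

#' Steady-state squared coefficient of variation of the potential
#'
#' `CV^2 = Var(V) / E[V]^2 = (lambda . w^2) / (2 * tau_mem * (w . lambda)^2)`,
#' strictly decreasing in `tau_mem`: a slower membrane averages over more
#' input spikes, sharpening the potential distribution relative to its
#' mean and improving discrimination between angularly close inputs (at
#' the cost of more computation per recognition). Note the ratio `Var/E`
#' itself is independent of `tau_mem`; it is the squared coefficient of
#' variation that carries the `1/tau_mem` scaling.
#'
#' @inheritParams mean_potential
#' @return `Var/E^2` at steady state.
#' @export
cv_squared <- function(w, rates, tau_mem = 15) {
  check_moment_inputs(w, rates, tau_mem, Inf)
  dot <- sum(w * rates)
  if (dot == 0) {
    stop("undefined ratio: w . rates must be positive", call. = FALSE)
  }
  0.5 * sum(rates * w^2) / (tau_mem * dot^2)
}

check_moment_inputs <- function(w, rates, tau_mem, t) {
  if (length(w) != length(rates)) {
    stop("`w` and `rates` must have the same length", call. = FALSE)
  }
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (tau_mem <= 0) stop("`tau_mem` must be positive", call. = FALSE)
  if (length(t) != 1L || is.na(t) || t < 0) {
    stop("`t` must be a single non-negative time", call. = FALSE)
  }
  invisible(NULL)
}

#' Monte-Carlo estimate of the pre-firing potential moments
#'
#' Independent oracle for [mean_potential()] and [var_potential()]: each
#' trial draws the Poisson spike counts of every channel over `[0, t]`,
#' places the spikes uniformly (the conditional law of a Poisson process
#' given its count), and sums the exponential-kernel contributions
#' `w_i * exp(-(t - s) / tau_mem)` directly. No thresholding is applied
#' (pre-firing regime). Standard errors are the sample standard error of
#' the mean and the asymptotic standard error of the sample variance
#' computed from the empirical fourth central moment.
#'
#' @inheritParams mean_potential
#' @param t Evaluation time (finite).
#' @param n_trials Number of independent trajectories, `>= 100`.
#' @return List with `mean`, `var`, `se_mean`, `se_var`, `n`.
#' @export
monte_carlo_potential <- function(w, rates, tau_mem = 15, t = 30,
                                  n_trials = 1e4) {
  check_moment_inputs(w, rates, tau_mem, t)
  if (!is.finite(t)) stop("`t` must be finite for simulation", call. = FALSE)
  if (n_trials < 100) stop("`n_trials` must be at least 100", call. = FALSE)
  n_trials <- as.integer(n_trials)
  d <- length(rates)
  V <- numeric(n_trials)
  for (i in seq_len(d)) {
    if (rates[i] == 0 || w[i] == 0) next
    counts <- stats::rpois(n_trials, rates[i] * t)
    total <- sum(counts)
    if (total == 0) next
    s <- stats::runif(total, 0, t)
    contrib <- w[i] * exp(-(t - s) / tau_mem)
    trial <- rep.int(seq_len(n_trials), counts)
    sums <- rowsum(contrib, trial)
    V[as.integer(rownames(sums))] <- V[as.integer(rownames(sums))] + sums[, 1]
  }
  m <- mean(V)
  vv <- stats::var(V)
  m4 <- mean((V - m)^4)
  list(mean = m, var = vv,
       se_mean = stats::sd(V) / sqrt(n_trials),
       se_var = sqrt(max(m4 - vv^2, 0) / n_trials),
       n = n_trials)
}
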