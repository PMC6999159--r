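# Shared fixtures: all built in code at test time.

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Poisson spike schedule for injection into both simulator backends.
make_schedule <- function(rate_total, t_len, n_channels, probs = NULL) {
  if (is.null(probs)) probs <- rep(1 / n_channels, n_channels)
  ts <- cumsum(stats::rexp(ceiling(rate_total * t_len * 2 + 20), rate_total))
  ts <- ts[ts < t_len]
  list(times = ts,
       channels = sample(n_channels, length(ts), replace = TRUE, prob = probs))
}

# Small network whose first `k` neurons are axis detectors on channels
# 1..k; remaining neurons keep their random initialization.
axis_network <- function(n_neurons, input_dim, k = n_neurons, ...) {
  net <- build_network(cfn_config(n_neurons = n_neurons,
                                  input_dim = input_dim, ...))
  for (j in seq_len(k)) {
    w <- numeric(input_dim)
    w[j] <- 1
    net$weights[j, ] <- w
  }
  net
}

# Number of spikes of a unit-rate Poisson channel in a window of length T.
poisson_window_count <- function(rate, T) {
  n <- 0L
  t <- sample_interarrival(rate)
  while (t < T) {
    n <- n + 1L
    t <- t + sample_interarrival(rate)
  }
  n
}
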