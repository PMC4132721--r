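# Independent oracles. These deliberately avoid the package code paths they
# are used to check: the stochastic chain walk below draws per-step branch
# and dwell variates molecule by molecule, whereas simulate_progress() is a
# deterministic matrix exponential and simulate_gel() uses aggregated
# Bernoulli/Gamma draws.

oracle_gillespie <- function(scheme, times, n_mol, seed) {
  set.seed(seed)
  n <- length(scheme$k_U)
  competent <- runif(n_mol) < scheme$baseline_amplitude
  t_acc <- rexp(n_mol, scheme$k_act)
  alive <- competent
  for (s in seq_len(n)) {
    r <- scheme$k_U[s] + scheme$k_D[s]
    t_acc <- t_acc + rexp(n_mol, r)
    alive <- alive & (runif(n_mol) < scheme$k_U[s] / r)
  }
  tt <- ifelse(alive, t_acc, Inf)
  vapply(times, function(t) mean(tt <= t), numeric(1))
}

# Band-noise observation model applied directly to a true progress curve:
# two lognormal band intensities (mean 1) per time point, F = I1/(I1+I2).
# Used as the Monte-Carlo oracle for fit dispersion and parameter recovery.
oracle_noisy_trace <- function(times, f_true, band_cv, n_total = 1e5) {
  sdlog <- sqrt(log(1 + band_cv^2))
  vapply(seq_along(times), function(i) {
    i1 <- n_total * f_true[i] *
      rlnorm(1, -sdlog^2 / 2, sdlog)
    i2 <- n_total * (1 - f_true[i]) *
      rlnorm(1, -sdlog^2 / 2, sdlog)
    i1 / (i1 + i2)
  }, numeric(1))
}

default_times <- c(5, 10, 20, 40, 60, 90, 120, 180, 240, 360, 480, 720)

# A small lambda profile with a planted impulse train, for periodicity
# tests: spikes of the given height every `period` positions on a quiet
# baseline.
impulse_profile <- function(length_nt, period, height = 5, offset = 1,
                            noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(length_nt, 0, max(noise_sd, 1e-6))
  x[seq(offset, length_nt, by = period)] <- height
  x
}

make_profile <- function(position, lambda, threshold = 2.5) {
  structure(
    data.frame(position = as.integer(position), kappa = 2^lambda,
               lambda = lambda,
               significant = is.finite(lambda) & abs(lambda) > threshold),
    class = c("interference_profile", "data.frame"), threshold = threshold)
}
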