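# shared fixtures, built once per test run

blood40 <- blood_config(M = 40)
sir31 <- sir_config()

noiseless_obs <- function(config) {
  traj <- simulate_model(config$model, config$times)
  apply_noise(traj$observed, config$times,
              noise_spec("additive_gaussian", 0, 1L))
}

# independent fixed-step RK4 integrator used as a simulation oracle
rk4 <- function(rhs, y0, times, nsub = 20L) {
  out <- matrix(NA_real_, length(times), length(y0))
  out[1L, ] <- y0
  y <- y0
  for (i in seq_len(length(times) - 1L)) {
    h <- (times[i + 1L] - times[i]) / nsub
    for (s in seq_len(nsub)) {
      k1 <- rhs(y)
      k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2)
      k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1L, ] <- y
  }
  out
}

# synthetic wendy_fit with prescribed estimate and CI half-width
fake_fit <- function(w_hat, half = rep(1, length(w_hat))) {
  structure(list(w_hat = w_hat, covariance = diag((half / 1.96)^2,
                                                  length(w_hat)),
                 ci_low = w_hat - half, ci_high = w_hat + half,
                 iterations = 1L, converged = TRUE,
                 rank_G = length(w_hat)),
            class = "wendy_fit")
}
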