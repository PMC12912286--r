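# Shared fixtures: small problem sizes keep the default run fast while
# exercising the same code paths as the full study conditions.

small_spec <- function(n_subjects = 4) {
  session_spec(n_trials_per_condition = 3, n_subjects = n_subjects)
}

# All stochastic components off: the forward model is purely the neural
# response.
zero_noise <- function() {
  noise_spec(mayer = list(freq = 0.1, amplitude = 0),
             cardiac = list(freq = 1.2, amplitude = 0),
             respiratory = list(freq = 0.25, amplitude = 0),
             lfo = list(freqs = c(0.02, 0.04), amplitude = 0),
             drift_amplitude = 0, local_amplitude = 0,
             sc_local_scale = 0, sc_quality_spread = 0,
             white_sd = 0, loading_spread = 0, superficial_share = 0,
             motion = list(rate_per_min = 0, spike_amplitude = 0,
                           step_rate_per_min = 0, step_amplitude = 0))
}

# Mild noise: scaled-down systemics for fast qualitative tests.
mild_noise <- function(share = 0.7, motion_rate = 0) {
  ns <- noise_spec(superficial_share = share)
  ns$motion$rate_per_min <- motion_rate
  ns$motion$step_rate_per_min <- 0
  ns
}

# Default noise with all systemic/local amplitudes scaled by `f`.
scaled_noise <- function(f, motion_rate = 0) {
  ns <- mild_noise(motion_rate = motion_rate)
  ns$mayer$amplitude <- ns$mayer$amplitude * f
  ns$lfo$amplitude <- ns$lfo$amplitude * f
  ns$drift_amplitude <- ns$drift_amplitude * f
  ns$local_amplitude <- ns$local_amplitude * f
  ns$cardiac$amplitude <- ns$cardiac$amplitude * f
  ns$respiratory$amplitude <- ns$respiratory$amplitude * f
  ns
}

# Preprocess a simulated session and return (hemo, schedule).
sim_and_preprocess <- function(spec = small_spec(), truth = ground_truth(),
                               noise = zero_noise(), seed = 1) {
  sim <- simulate_session(spec, truth, noise, seed = seed)
  list(hemo = preprocess_session(sim$session), schedule = sim$schedule)
}

# Independent fine-grid oracle for the JZS Bayes factor, using the
# Zellner-Siow g-mixture representation (a different integral than the
# implementation's effect-size route): BF10 =
# int (1+Ng)^(-1/2) (1+t^2/((1+Ng)df))^(-(df+1)/2) p(g) dg /
# (1+t^2/df)^(-(df+1)/2), with g ~ InverseGamma(1/2, r^2/2).
bf_jzs_grid_oracle <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2) {
  if (is.null(n2)) { df <- n1 - 1; neff <- n1 }
  else { df <- n1 + n2 - 2; neff <- n1 * n2 / (n1 + n2) }
  # substitute g = u/(1-u) to map (0, Inf) onto (0, 1)
  u <- seq(1e-9, 1 - 1e-9, length.out = 200000)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  pg <- (rscale^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) *
    exp(-rscale^2 / (2 * g))
  integrand <- (1 + neff * g)^(-1 / 2) *
    (1 + t^2 / ((1 + neff * g) * df))^(-(df + 1) / 2) * pg * jac
  num <- sum((integrand[-1] + integrand[-length(integrand)]) / 2 * diff(u))
  num / (1 + t^2 / df)^(-(df + 1) / 2)
}

# Brute-force fine-grid oracle for the directional (half-Cauchy) variant.
bf_dir_grid_oracle <- function(t, n1, n2 = NULL, direction = "positive",
                               rscale = sqrt(2) / 2) {
  if (is.null(n2)) { df <- n1 - 1; neff <- n1 }
  else { df <- n1 + n2 - 2; neff <- n1 * n2 / (n1 + n2) }
  d <- seq(0, 60, length.out = 400000)
  sgn <- if (direction == "positive") 1 else -1
  f <- suppressWarnings(stats::dt(t, df, ncp = sgn * d * sqrt(neff))) *
    2 * stats::dcauchy(d, 0, rscale)
  num <- sum((f[-1] + f[-length(f)]) / 2 * diff(d))
  num / stats::dt(t, df)
}
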