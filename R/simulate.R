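# Forward model: neural responses + shared systemic physiology + artifacts,
# mapped to two-wavelength intensities through the same Beer-Lambert
# constants the inverse chain uses.

# Narrow-band stochastic oscillator: unit-SD sinusoid with slowly drifting
# phase and amplitude (a pure tone would be trivially removable and would
# understate the confound).
narrowband_oscillator <- function(freq, n, fs, phase_sd = 0.13, amp_sd = 0.3) {
  phase <- 2 * pi * freq * seq_len(n) / fs + cumsum(stats::rnorm(n, 0, phase_sd))
  lp <- signal::butter(2, min(0.9, 0.02 * 2 / fs))
  env <- 1 + amp_sd * pad_filtfilt(lp, stats::rnorm(n))
  x <- env * sin(phase)
  x / stats::sd(x)
}

# 1/f-like slow drift: integrated white noise, unit SD.
drift_process <- function(n) {
  x <- cumsum(stats::rnorm(n))
  x <- x - mean(x)
  x / stats::sd(x)
}

# Channel-local slow physiological noise: low-passed white noise, unit SD.
local_slow_noise <- function(n, fs, cutoff = 0.15) {
  lp <- signal::butter(2, min(0.9, cutoff * 2 / fs))
  x <- pad_filtfilt(lp, stats::rnorm(n))
  x / stats::sd(x)
}

#' Simulate shared systemic hemoglobin fluctuations
#'
#' Generates the four global physiological components (Mayer wave, cardiac,
#' respiratory, slow drift), a positive per-channel loading on each, and the
#' per-channel systemic HbO/HbR traces: loading-weighted sums of the global
#' components plus channel-local slow noise. The HbR trace is the same
#' vascular signal scaled by `noise$hbr_systemic_ratio`, with its own local
#' noise and slightly perturbed loadings (HbO and HbR systemics are strongly
#' but not perfectly coupled).
#'
#' @param spec A [session_spec()] (supplies `fs`).
#' @param noise A [noise_spec()].
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param n_channels Number of channels to generate (defaults to the 24
#'   series of the standard montage).
#' @param local_scale Per-channel multiplier on `noise$local_amplitude`
#'   (length `n_channels` or 1); used to model heterogeneous short-channel
#'   signal quality.
#' @param spread_scale Per-channel multiplier on `noise$loading_spread`
#'   (length `n_channels` or 1); long channels average superficial
#'   physiology over a large patch and get a reduced spread.
#' @return List with `hbo`, `hbr` (matrices `n_samples` x `n_channels`, uM),
#'   `global` (matrix of the unit-SD components), `loadings`.
#' @export
simulate_systemics <- function(spec, noise, n_samples, seed = 1L,
                               n_channels = 24L, local_scale = 1,
                               spread_scale = 1) {
  local_scale <- rep_len(local_scale, n_channels)
  spread_scale <- rep_len(spread_scale, n_channels)
  local_seed(seed, {
    fs <- spec$fs
    lfo_freqs <- noise$lfo$freqs %||% numeric(0)
    amps <- c(mayer = noise$mayer$amplitude,
              cardiac = noise$cardiac$amplitude,
              respiratory = noise$respiratory$amplitude,
              drift = noise$drift_amplitude,
              rep(noise$lfo$amplitude %||% 0, length(lfo_freqs)))
    G <- cbind(
      mayer = narrowband_oscillator(noise$mayer$freq, n_samples, fs),
      cardiac = narrowband_oscillator(noise$cardiac$freq, n_samples, fs,
                                      phase_sd = 0.05),
      respiratory = narrowband_oscillator(noise$respiratory$freq, n_samples,
                                          fs, phase_sd = 0.08),
      drift = drift_process(n_samples)
    )
    for (f in lfo_freqs)
      G <- cbind(G, narrowband_oscillator(f, n_samples, fs, phase_sd = 0.1))
    n_comp <- ncol(G)
    spread <- noise$loading_spread * spread_scale   # per-channel
    S <- matrix(rep(spread, n_comp), n_channels, n_comp)
    L <- matrix(exp(stats::rnorm(n_channels * n_comp) * S - S^2 / 2),
                n_channels, n_comp)
    L_hbr <- L * matrix(exp(stats::rnorm(n_channels * n_comp) * S / 2 -
                              (S / 2)^2 / 2), n_channels, n_comp)
    hbo <- matrix(0, n_samples, n_channels)
    hbr <- matrix(0, n_samples, n_channels)
    for (c_i in seq_len(n_channels)) {
      hbo[, c_i] <- G %*% (amps * L[c_i, ])
      hbr[, c_i] <- noise$hbr_systemic_ratio * (G %*% (amps * L_hbr[c_i, ]))
      la <- noise$local_amplitude * local_scale[c_i]
      if (la > 0) {
        hbo[, c_i] <- hbo[, c_i] + la * local_slow_noise(n_samples, fs)
        hbr[, c_i] <- hbr[, c_i] + noise$hbr_systemic_ratio *
          la * local_slow_noise(n_samples, fs)
      }
    }
    list(hbo = hbo, hbr = hbr, global = G, loadings = L)
  })
}

# Sparse motion artifacts: exponential-decay spikes plus occasional step
# changes, random sign, in uM on the HbO scale.
motion_trace <- function(noise, n, fs) {
  out <- numeric(n)
  dur_min <- n / fs / 60
  n_spike <- stats::rpois(1, noise$motion$rate_per_min * dur_min)
  if (n_spike > 0) {
    kernel_len <- max(2L, as.integer(round(0.6 * fs)))
    kernel <- exp(-(seq_len(kernel_len) - 1) / (0.2 * fs))
    for (k in seq_len(n_spike)) {
      pos <- sample.int(n - kernel_len, 1)
      amp <- noise$motion$spike_amplitude * sample(c(-1, 1), 1) *
        (0.5 + stats::rexp(1, 2))
      idx <- pos:(pos + kernel_len - 1L)
      out[idx] <- out[idx] + amp * kernel
    }
  }
  n_step <- stats::rpois(1, noise$motion$step_rate_per_min * dur_min)
  if (n_step > 0) {
    for (k in seq_len(n_step)) {
      pos <- sample.int(n - 1L, 1)
      amp <- noise$motion$step_amplitude * sample(c(-1, 1), 1)
      out[(pos + 1L):n] <- out[(pos + 1L):n] + amp
    }
  }
  out
}

#' Simulate one raw two-wavelength session
#'
#' Composes the forward model for every long and short channel:
#' hemoglobin = neural response (HRF-convolved boxcars scaled by the true
#' betas; long channels only) + `superficial_share` x systemic (full
#' systemic on short channels) + broadband sensor noise + motion artifacts.
#' The hemoglobin pair is mapped to optical density at 760/850 nm through
#' the same Beer-Lambert constants used by [preprocess_session()], and to
#' intensity as `I = I0 * exp(-dOD)` with `I0 = 1`.
#'
#' @param spec A [session_spec()].
#' @param truth A [ground_truth()] or a data frame as returned by
#'   [true_betas()].
#' @param noise A [noise_spec()].
#' @param montage The montage.
#' @param seed Integer seed.
#' @param constants [mbll_constants()] shared with the inverse chain.
#' @return List with `session` (a `raw_session`: `intensity[time, series,
#'   wavelength]`, `fs`, `montage`, `schedule`) and `schedule`.
#' @export
simulate_session <- function(spec = session_spec(), truth = ground_truth(),
                             noise = noise_spec(),
                             montage = build_standard_montage(), seed = 1L,
                             constants = mbll_constants()) {
  if (inherits(truth, "ground_truth")) truth <- true_betas(truth, montage)
  schedule <- generate_schedule(spec, seed = seed)
  fs <- spec$fs
  n_t <- session_n_samples(schedule, fs)
  sn <- series_names(montage)
  n_series <- length(sn)
  n_long <- nrow(montage$channels)

  task <- build_task_design(schedule, fs, n_t)
  seeds <- child_seeds(seed, 4L, stream = 11L)
  n_sc <- nrow(montage$short_channels)
  # heterogeneous short-channel signal quality, redrawn per session
  sc_mult <- local_seed(seeds[4], {
    noise$sc_local_scale *
      exp(stats::rnorm(n_sc, 0, noise$sc_quality_spread) -
            noise$sc_quality_spread^2 / 2)
  })
  sys <- simulate_systemics(spec, noise, n_t, seed = seeds[1],
                            n_channels = n_series,
                            local_scale = c(rep(1, n_long), sc_mult),
                            spread_scale = c(rep(noise$lc_loading_frac %||% 1,
                                                 n_long),
                                             rep(1, n_series - n_long)))

  hbo <- matrix(0, n_t, n_series, dimnames = list(NULL, sn))
  hbr <- matrix(0, n_t, n_series, dimnames = list(NULL, sn))
  share <- c(rep(noise$superficial_share, n_long),
             rep(1, n_series - n_long))
  for (j in seq_len(n_series)) {
    hbo[, j] <- share[j] * sys$hbo[, j]
    hbr[, j] <- share[j] * sys$hbr[, j]
  }
  # neural responses on long channels only
  for (j in seq_len(n_long)) {
    ch <- montage$channels$id[j]
    tb <- truth[truth$channel == ch, , drop = FALSE]
    for (cond in task$conditions) {
      b_o <- tb$beta[tb$condition == cond & tb$chromophore == "hbo"]
      b_r <- tb$beta[tb$condition == cond & tb$chromophore == "hbr"]
      if (length(b_o) && b_o != 0) hbo[, j] <- hbo[, j] + b_o * task$X[, cond]
      if (length(b_r) && b_r != 0) hbr[, j] <- hbr[, j] + b_r * task$X[, cond]
    }
  }
  local_seed(seeds[2], {
    if (noise$white_sd > 0) {
      hbo <- hbo + matrix(stats::rnorm(n_t * n_series, 0, noise$white_sd),
                          n_t, n_series)
      hbr <- hbr + matrix(stats::rnorm(n_t * n_series, 0, noise$white_sd),
                          n_t, n_series)
    }
  })
  local_seed(seeds[3], {
    if (noise$motion$rate_per_min > 0 || noise$motion$step_rate_per_min > 0) {
      for (j in seq_len(n_series)) {
        mt <- motion_trace(noise, n_t, fs)
        hbo[, j] <- hbo[, j] + mt
        hbr[, j] <- hbr[, j] + mt / 3
      }
    }
  })

  # forward Beer-Lambert: hemoglobin -> dOD -> intensity
  E <- constants$extinction * 1e-6
  dists <- series_distances_cm(montage)
  intensity <- array(NA_real_, dim = c(n_t, n_series, 2),
                     dimnames = list(NULL, sn, c("760", "850")))
  for (j in seq_len(n_series)) {
    d <- dists[[sn[j]]]
    od <- cbind(hbo[, j], hbr[, j]) %*% t(E) * (d * constants$ppf)
    if (any(!is.finite(od)) || any(abs(od) > 500))
      stop("unphysical forward model: optical density overflow ",
           "(non-positive intensity)")
    intensity[, j, 1] <- exp(-od[, 1])
    intensity[, j, 2] <- exp(-od[, 2])
  }
  if (any(intensity <= 0)) stop("unphysical forward model: non-positive intensity")
  session <- structure(list(intensity = intensity, fs = fs,
                            time = (seq_len(n_t) - 1) / fs,
                            montage = montage, schedule = schedule),
                       class = "raw_session")
  list(session = session, schedule = schedule)
}

#' @export
print.raw_session <- function(x, ...) {
  cat("raw_session: ", dim(x$intensity)[1], " samples x ",
      dim(x$intensity)[2], " series x 2 wavelengths @ ", x$fs, " Hz (",
      round(dim(x$intensity)[1] / x$fs / 60, 1), " min)\n", sep = "")
  invisible(x)
}

#' Simulate a cohort of sessions
#'
#' Each subject gets an independent child seed (schedule, systemics, noise
#' and artifacts all differ) and, when `truth$between_subject_sd > 0`, a
#' per-subject HbO amplitude drawn from a normal distribution truncated at
#' zero; the subject's HbR amplitudes follow through `hbr_ratio`.
#'
#' @param spec,truth,noise,montage,constants As in [simulate_session()].
#' @param seed Master seed; the whole cohort is deterministic given it.
#' @return List with `sessions` (list of `raw_session`), `schedules`,
#'   `subject_truths` (list of per-subject beta tables).
#' @export
make_cohort <- function(spec = session_spec(), truth = ground_truth(),
                        noise = noise_spec(),
                        montage = build_standard_montage(), seed = 1L,
                        constants = mbll_constants()) {
  n_sub <- spec$n_subjects
  seeds <- child_seeds(seed, n_sub, stream = 1L)
  amp_draw <- local_seed(seed, {
    pmax(0, truth$hbo_amplitude +
           stats::rnorm(n_sub, 0, truth$between_subject_sd))
  })
  sessions <- vector("list", n_sub)
  schedules <- vector("list", n_sub)
  truths <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    t_s <- ground_truth(hbo_amplitude = amp_draw[s],
                        hbr_ratio = truth$hbr_ratio,
                        between_subject_sd = 0)
    tb <- true_betas(t_s, montage)
    sim <- simulate_session(spec, tb, noise, montage, seed = seeds[s],
                            constants = constants)
    sessions[[s]] <- sim$session
    schedules[[s]] <- sim$schedule
    truths[[s]] <- tb
  }
  list(sessions = sessions, schedules = schedules, subject_truths = truths)
}
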