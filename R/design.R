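# Task regressors: canonical HRF convolved with stimulus boxcars.

#' Canonical double-gamma hemodynamic response function
#'
#' Standard double-gamma kernel: a positive gamma response (shape 6, scale
#' 1 s, peak near 5 s) minus an undershoot gamma (shape 16, scale 1 s)
#' weighted 1/6, sampled at `fs` over `length_s` seconds and normalized to a
#' peak of 1.
#'
#' @param fs Sampling rate in Hz.
#' @param peak_delay,undershoot_delay Gamma shape parameters (s, with unit
#'   scale these equal the distribution means).
#' @param dispersion,undershoot_dispersion Gamma scale parameters (s).
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @param length_s Kernel support in seconds.
#' @return Numeric kernel sampled at `fs`, starting at t = 0.
#' @export
canonical_hrf <- function(fs, peak_delay = 6, undershoot_delay = 16,
                          dispersion = 1, undershoot_dispersion = 1,
                          undershoot_ratio = 1 / 6, length_s = 32) {
  stopifnot(fs > 0)
  t <- seq(0, length_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = peak_delay, scale = dispersion) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay, scale = undershoot_dispersion)
  h / max(h)
}

#' Build the task design matrix
#'
#' One column per condition: the stimulus boxcar convolved with the
#' canonical HRF (discrete convolution scaled by `1/fs`), plus an intercept.
#' All condition columns share a fixed normalization such that a single
#' trial of the default 10 s duration peaks at 1, making betas interpretable
#' as peak single-trial response amplitudes in the units of the data.
#'
#' @param schedule An `event_schedule`.
#' @param fs Sampling rate in Hz.
#' @param n_samples Length of the recording in samples; events must end
#'   within it.
#' @param hrf Optional kernel (defaults to [canonical_hrf()] at `fs`).
#' @return A `task_design`: list with `X` (matrix `n_samples` x 4, columns
#'   `A`, `V`, `AV`, `intercept`), `fs`, `conditions`.
#' @export
build_task_design <- function(schedule, fs, n_samples, hrf = NULL) {
  stopifnot(fs > 0, n_samples > 0)
  if (nrow(schedule) > 0 &&
      any(schedule$onset + schedule$duration > n_samples / fs))
    stop("schedule contains events beyond the end of the series")
  if (is.null(hrf)) hrf <- canonical_hrf(fs)
  conditions <- c("A", "V", "AV")
  X <- matrix(0, n_samples, length(conditions) + 1L,
              dimnames = list(NULL, c(conditions, "intercept")))
  X[, "intercept"] <- 1
  scl <- single_trial_peak(fs, hrf)
  for (cond in conditions) {
    ev <- schedule[schedule$condition == cond, , drop = FALSE]
    if (nrow(ev) == 0) next
    box <- numeric(n_samples)
    for (k in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset[k] * fs) + 1L
      i1 <- min(n_samples, floor((ev$onset[k] + ev$duration[k]) * fs))
      box[i0:i1] <- 1
    }
    X[, cond] <- convolve_truncate(box, hrf) / fs / scl
  }
  structure(list(X = X, fs = fs, conditions = conditions, hrf = hrf),
            class = "task_design")
}

# Peak of the response to one 10-s trial; fixed reference normalization.
single_trial_peak <- function(fs, hrf) {
  box <- rep(1, max(1L, floor(10 * fs)))
  max(convolve_truncate(c(box, numeric(length(hrf))), hrf)) / fs
}

# Causal discrete convolution truncated to length(x).
convolve_truncate <- function(x, k) {
  n <- length(x)
  y <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  y[seq_len(n)]
}
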