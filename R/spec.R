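# Study-design and simulator parameter objects.

#' Session design specification
#'
#' Parameters of the block design emulated by the simulator: a continuous
#' pseudorandomized sequence of auditory (A), visual (V) and audiovisual
#' (AV) trials recorded at two wavelengths.
#'
#' @param fs Sampling frequency in Hz.
#' @param n_trials_per_condition Trials per condition (45 trials total at the
#'   default of 15).
#' @param stim_duration Stimulus duration in seconds.
#' @param isi_range Two-element numeric, uniform jitter bounds of the silent
#'   inter-stimulus interval in seconds.
#' @param baseline_duration Initial rest period in seconds before the first
#'   trial.
#' @param n_subjects Number of subjects in a simulated cohort.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(fs = 7.81, n_trials_per_condition = 15,
                         stim_duration = 10, isi_range = c(8, 12),
                         baseline_duration = 60, n_subjects = 16) {
  stopifnot(fs > 0, n_trials_per_condition >= 1, stim_duration > 0,
            length(isi_range) == 2, isi_range[1] <= isi_range[2],
            isi_range[1] >= 0, baseline_duration > 0, n_subjects >= 1)
  structure(list(fs = fs,
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 stim_duration = stim_duration,
                 isi_range = isi_range,
                 baseline_duration = baseline_duration,
                 n_subjects = as.integer(n_subjects)),
            class = "session_spec")
}

#' Systemic physiology and artifact specification
#'
#' Amplitudes are hemoglobin concentration changes in micromolar, on the HbO
#' trace; the HbR systemic trace is the same source signal scaled by
#' `hbr_systemic_ratio` (systemic interference affects HbR much less than
#' HbO). Oscillatory components are narrow-band stochastic oscillators
#' (slowly drifting phase and amplitude), not pure tones; `drift` is a
#' 1/f-like random walk; `local_amplitude` is channel-specific slow
#' physiological noise shared by no other channel and therefore irreducible
#' by short-channel regression; `white_sd` is broadband sensor noise.
#'
#' `superficial_share` scales how much of a long channel's co-located
#' superficial systemic signal reaches the long channel; short channels
#' always carry the full superficial signal.
#'
#' @param mayer,cardiac,respiratory Lists with elements `freq` (Hz) and
#'   `amplitude` (uM).
#' @param lfo List with `freqs` (Hz) and `amplitude` (uM): additional
#'   independent low-frequency blood-pressure/vasomotion oscillators, each
#'   a global component with its own per-channel loadings. Together with
#'   the Mayer wave they span a multi-dimensional in-band systemic
#'   subspace, which is why a single short-channel regressor cannot remove
#'   them all.
#' @param drift_amplitude 1/f-like slow drift amplitude (uM).
#' @param local_amplitude Channel-local slow noise amplitude (uM).
#' @param sc_local_scale Mean multiplier of `local_amplitude` on short
#'   channels. Short channels sit on the scalp surface where contact
#'   quality varies (hair, coupling), so their channel-specific noise is
#'   typically larger than on long channels; this is what makes pooling
#'   across short channels more robust than relying on a single one.
#' @param sc_quality_spread Log-scale SD of the per-short-channel,
#'   per-session draw of that multiplier (0 makes all SCs equally noisy).
#' @param white_sd Broadband sensor noise SD (uM).
#' @param loading_spread Log-scale SD of per-channel loadings on the global
#'   components (0 makes all channels load identically). Applies to short
#'   channels; an 8-mm channel samples a small, idiosyncratic scalp patch.
#' @param lc_loading_frac Fraction of `loading_spread` applied to long
#'   channels, whose 25--40 mm photon paths average superficial physiology
#'   over a much larger patch and therefore sit close to the population
#'   mean loading.
#' @param superficial_share Fraction in `[0, 1]`.
#' @param hbr_systemic_ratio Scale of HbR systemic relative to HbO.
#' @param motion List with `rate_per_min` (spikes), `spike_amplitude` (uM),
#'   `step_rate_per_min`, `step_amplitude` (uM).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mayer = list(freq = 0.1, amplitude = 45),
                       cardiac = list(freq = 1.2, amplitude = 0.4),
                       respiratory = list(freq = 0.25, amplitude = 0.5),
                       lfo = list(freqs = c(0.015, 0.03, 0.045, 0.06, 0.08),
                                  amplitude = 6),
                       drift_amplitude = 10,
                       local_amplitude = 0.8,
                       sc_local_scale = 3,
                       sc_quality_spread = 0.8,
                       white_sd = 0.2,
                       loading_spread = 0.5,
                       lc_loading_frac = 0.25,
                       superficial_share = 0.7,
                       hbr_systemic_ratio = 1 / 20,
                       motion = list(rate_per_min = 0.5,
                                     spike_amplitude = 30,
                                     step_rate_per_min = 0.1,
                                     step_amplitude = 5)) {
  amps <- c(mayer$amplitude, cardiac$amplitude, respiratory$amplitude,
            lfo$amplitude, drift_amplitude, local_amplitude, white_sd,
            motion$spike_amplitude, motion$step_amplitude)
  stopifnot(all(amps >= 0), superficial_share >= 0, superficial_share <= 1,
            loading_spread >= 0, lc_loading_frac >= 0, lc_loading_frac <= 1,
            hbr_systemic_ratio >= 0,
            sc_local_scale >= 0, sc_quality_spread >= 0,
            motion$rate_per_min >= 0, motion$step_rate_per_min >= 0)
  structure(list(mayer = mayer, cardiac = cardiac, respiratory = respiratory,
                 lfo = lfo,
                 drift_amplitude = drift_amplitude,
                 local_amplitude = local_amplitude,
                 sc_local_scale = sc_local_scale,
                 sc_quality_spread = sc_quality_spread,
                 white_sd = white_sd,
                 loading_spread = loading_spread,
                 lc_loading_frac = lc_loading_frac,
                 superficial_share = superficial_share,
                 hbr_systemic_ratio = hbr_systemic_ratio,
                 motion = motion),
            class = "noise_spec")
}

#' Ground-truth neural amplitudes
#'
#' Defines the true condition amplitudes used by the forward model: occipital
#' channels respond to V and AV, temporal channels to A and AV, short
#' channels never respond. HbO amplitudes are non-negative; HbR amplitudes
#' are `hbr_ratio` times the HbO amplitude with `hbr_ratio < 0`
#' (deoxygenated hemoglobin decreases during activation).
#'
#' Amplitudes are in micromolar at the peak of a single-trial response (the
#' task regressors are scaled so that one default-duration trial peaks at 1).
#'
#' @param hbo_amplitude Peak HbO response amplitude (uM).
#' @param hbr_ratio Negative scale linking HbR to HbO amplitudes.
#' @param between_subject_sd SD of the per-subject amplitude draw in
#'   [make_cohort()] (uM; 0 gives identical subjects).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(hbo_amplitude = 0.5, hbr_ratio = -1 / 3,
                         between_subject_sd = 0.1) {
  stopifnot(hbo_amplitude >= 0, hbr_ratio < 0, between_subject_sd >= 0)
  structure(list(hbo_amplitude = hbo_amplitude, hbr_ratio = hbr_ratio,
                 between_subject_sd = between_subject_sd),
            class = "ground_truth")
}

#' True beta table for a montage
#'
#' Expands a [ground_truth()] into the per-channel, per-condition,
#' per-chromophore amplitude table the forward model and recovery tests use.
#' Modality mapping: temporal ROIs respond to A and AV, the occipital ROI to
#' V and AV; the excluded channel is treated like its (temporal) neighbours
#' so that it contains realistic signal even though it is never analyzed.
#'
#' @param truth A `ground_truth`.
#' @param montage An `fnirs_montage`.
#' @return Data frame with columns `channel`, `roi`, `condition`,
#'   `chromophore`, `beta`.
#' @export
true_betas <- function(truth, montage) {
  ch <- montage$channels
  grid <- expand.grid(channel = ch$id, condition = c("A", "V", "AV"),
                      chromophore = c("hbo", "hbr"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$roi <- ch$roi[match(grid$channel, ch$id)]
  is_temporal <- grid$roi %in% c("left_temporal", "right_temporal", "excluded")
  responds <- ifelse(is_temporal, grid$condition %in% c("A", "AV"),
                     grid$condition %in% c("V", "AV"))
  amp <- ifelse(responds, truth$hbo_amplitude, 0)
  grid$beta <- ifelse(grid$chromophore == "hbo", amp, truth$hbr_ratio * amp)
  grid[, c("channel", "roi", "condition", "chromophore", "beta")]
}
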