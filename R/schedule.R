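# Pseudorandomized trial schedule.

#' Generate a pseudorandomized event schedule
#'
#' Produces the continuous trial sequence of the block design: one trial per
#' condition inside every consecutive triplet (condition order permuted
#' independently within each triplet), stimulus onsets separated by the
#' stimulus duration plus an inter-stimulus interval drawn uniformly from
#' `spec$isi_range`, and the first onset at the end of the initial baseline.
#'
#' @param spec A [session_spec()].
#' @param seed Integer seed; the schedule is a deterministic function of
#'   `(spec, seed)`.
#' @return An `event_schedule`: data frame with columns `onset` (s),
#'   `duration` (s) and `condition` (`"A"`, `"V"`, `"AV"`), with the
#'   generating `spec` attached as an attribute.
#' @export
generate_schedule <- function(spec = session_spec(), seed = 1L) {
  n_trip <- spec$n_trials_per_condition
  conditions <- local_seed(seed, {
    unlist(lapply(seq_len(n_trip), function(i) sample(c("A", "V", "AV"))))
  })
  n_ev <- 3L * n_trip
  isi <- local_seed(seed + 1L, {
    stats::runif(n_ev - 1L, spec$isi_range[1], spec$isi_range[2])
  })
  onsets <- spec$baseline_duration +
    c(0, cumsum(spec$stim_duration + isi))
  out <- data.frame(onset = onsets,
                    duration = rep(spec$stim_duration, n_ev),
                    condition = conditions,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  class(out) <- c("event_schedule", "data.frame")
  out
}

# Total recording duration implied by a schedule: last offset plus a tail
# long enough for the hemodynamic response and the block-average window.
session_duration <- function(schedule, tail = 35) {
  max(schedule$onset + schedule$duration) + tail
}

session_n_samples <- function(schedule, fs, tail = 35) {
  as.integer(ceiling(session_duration(schedule, tail) * fs))
}
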