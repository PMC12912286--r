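# Event-locked block averaging for descriptive validation of the GLM.

#' Epoch and average preprocessed hemoglobin signals
#'
#' Extracts, for every event, a window relative to stimulus onset, subtracts
#' the mean of the baseline interval from each epoch, and averages epochs
#' within condition, then channels within ROI, then subjects. Standard
#' errors are computed across subjects. Epochs extending beyond the
#' recording are dropped (their count is reported in the `dropped`
#' attribute).
#'
#' @param hemo A `hemo_series` or list of them (one per subject).
#' @param schedule An `event_schedule` or list aligned with `hemo`.
#' @param montage The montage.
#' @param window Epoch window in seconds relative to onset.
#' @param baseline Baseline-centering interval in seconds relative to onset.
#' @return An `epoch_average` data frame: `time`, `condition`, `roi`,
#'   `chromophore`, `mean`, `se`, `n_subjects`.
#' @export
epoch_and_average <- function(hemo, schedule, montage,
                              window = c(-5, 25), baseline = c(-5, 0)) {
  if (inherits(hemo, "hemo_series")) {
    hemo <- list(hemo); schedule <- list(schedule)
  }
  stopifnot(length(hemo) == length(schedule),
            window[1] < window[2],
            baseline[1] >= window[1], baseline[2] <= window[2])
  fs <- hemo[[1]]$fs
  rel_start <- round(window[1] * fs)
  n_win <- floor((window[2] - window[1]) * fs) + 1L
  rel <- rel_start + seq_len(n_win) - 1L
  t_rel <- rel / fs
  base_idx <- which(t_rel >= baseline[1] & t_rel <= baseline[2])
  rois <- c("left_temporal", "occipital", "right_temporal")
  conds <- c("A", "V", "AV")
  n_dropped <- 0L
  # per-subject mean curve for each (condition, roi, chromophore)
  per_sub <- array(NA_real_, dim = c(n_win, 3, 3, 2, length(hemo)))
  for (s in seq_along(hemo)) {
    v <- hemo[[s]]$values
    n_t <- dim(v)[1]
    sch <- schedule[[s]]
    for (ci in seq_along(conds)) {
      onsets <- sch$onset[sch$condition == conds[ci]]
      idx0 <- round(onsets * fs) + 1L
      ok <- idx0 + rel[1] >= 1L & idx0 + rel[n_win] <= n_t
      n_dropped <- n_dropped + sum(!ok)
      idx0 <- idx0[ok]
      if (!length(idx0)) next
      for (ri in seq_along(rois)) {
        chs <- paste0("ch", roi_channels(montage, rois[ri])$id)
        for (hi in 1:2) {
          acc <- matrix(0, n_win, length(idx0) * length(chs))
          k <- 0L
          for (chn in chs) {
            x <- v[, chn, hi]
            for (i0 in idx0) {
              k <- k + 1L
              ep <- x[i0 + rel]
              acc[, k] <- ep - mean(ep[base_idx])
            }
          }
          per_sub[, ci, ri, hi, s] <- rowMeans(acc)
        }
      }
    }
  }
  out <- expand.grid(time = t_rel, condition = conds, roi = rois,
                     chromophore = c("hbo", "hbr"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- apply(per_sub, 1:4, mean, na.rm = TRUE)
  n_s <- length(hemo)
  se <- if (n_s > 1) apply(per_sub, 1:4, stats::sd, na.rm = TRUE) / sqrt(n_s)
        else array(NA_real_, dim = dim(per_sub)[1:4])
  out$mean <- as.vector(mu)
  out$se <- as.vector(se)
  out$n_subjects <- n_s
  attr(out, "dropped") <- n_dropped
  class(out) <- c("epoch_average", "data.frame")
  out
}

#' Short-channel-corrected block average
#'
#' Residualizes every long channel on the pipeline's nuisance regressors
#' (plus an intercept) before epoching, so the averaged time courses
#' reflect the corrected signals; then proceeds as [epoch_and_average()].
#' With the no-SC configuration this equals the plain block average.
#'
#' @param hemo,schedule,montage,window,baseline As in [epoch_and_average()].
#' @param config A `pipeline_config` (or pipeline id).
#' @return An `epoch_average`.
#' @export
corrected_block_average <- function(hemo, schedule, config, montage,
                                    window = c(-5, 25), baseline = c(-5, 0)) {
  if (is.numeric(config)) config <- pipeline_by_id(config)
  if (inherits(hemo, "hemo_series")) {
    hemo <- list(hemo); schedule <- list(schedule)
  }
  corrected <- lapply(hemo, function(h) residualize_on_nuisance(h, config, montage))
  epoch_and_average(corrected, schedule, montage, window, baseline)
}

# Project each long channel onto the orthogonal complement of the nuisance
# span (plus intercept); idempotent by construction.
residualize_on_nuisance <- function(hemo, config, montage) {
  out <- hemo
  if (config$scope == "none") return(out)
  pca <- NULL
  if (config$method == "pooled_pca")
    pca <- sc_pca(hemo, scope_sc_ids(config$scope, montage))
  for (chrom in c("hbo", "hbr")) {
    for (ch in montage$channels$id[montage$channels$roi != "excluded"]) {
      nuis <- build_nuisance(config, hemo, ch, chrom, montage, pca = pca)
      X <- cbind(intercept = 1, nuis$X)
      y <- hemo$values[, paste0("ch", ch), chrom]
      out$values[, paste0("ch", ch), chrom] <- stats::lsfit(X, y,
                                                            intercept = FALSE)$residuals
    }
  }
  out
}
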